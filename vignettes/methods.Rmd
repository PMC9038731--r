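---
title: "Models and methods: linking EMF communities to tree growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: linking EMF communities to tree growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycogrowth)
```

# The scientific question and the shape of the pipeline

Ectomycorrhizal fungi (EMF) mediate tree access to soil nitrogen, and
mesocosm work shows EMF species differ strongly in their effect on
seedling growth. The question this pipeline addresses is whether such
effects are visible at stand scale: does EMF community composition, or
the functional gene content it implies, explain variation in forest tree
growth beyond climate, nitrogen deposition, soil chemistry, and stand
structure?

The analysis chain is: (1) two-census tree inventories are converted to
per-tree and stand-level carbon growth through species-group allometric
equations; (2) reference fungal genomes provide gene-category counts
that are screened for phylogenetic signal and imputed onto the OTUs of a
molecular community survey, giving community-weighted mean (CWM) trait
values per plot; (3) the community itself is rarefied, ordinated
(Bray–Curtis / PCoA / db-RDA) and clustered, with clusters classified as
slow- or fast-growth by analysis of means; (4) additive models of ln
growth quantify what a fungal predictor adds over the abiotic
covariates. The real forest-monitoring inventory is access-restricted,
so a synthetic generator reproduces the statistical structure of all
inputs and provides ground truth for every recovery test.

# Inventory growth accounting

Growth is accounted between the first and last periodic DBH measurement
of each tree. Records are removed, in this order and with the reason
logged, when the tree is dead, when either DBH is below the 5 cm
measurement threshold, or when the tree shrank (occasional measurement
artifacts). Aboveground biomass (kg) uses the four species-group
equations (a quadratic for Scots pine, power laws for beech, spruce,
oak), all monotone increasing above 5 cm; carbon is 50 % of biomass, and
the per-tree rate is the annual carbon difference, kg C yr⁻¹, over the
integer census interval — no day-level proration, matching how census
years are recorded.

Only a subset of plot trees carries paired measurements, so plot totals
cannot be summed directly. Stand growth resamples measured trees with
replacement up to `ceiling(stem_density)` stems, sums the carbon gain,
and converts to Mg C ha⁻¹ yr⁻¹; the default 1000 replicates give the
mean and a 95 % percentile interval. The bootstrap expectation equals
density × mean tree growth (unit-converted), which the tests assert
within three Monte-Carlo standard errors.

# Phylogenetic signal and the trait decision tree

Gene numbers per category are tested on the reference species tree with
two complementary statistics. Blomberg's K is the ratio of the observed
trait variance ratio (raw versus phylogenetically corrected, using the
GLS mean under the tree covariance C) to its Brownian-motion
expectation; K ≈ 1 indicates Brownian-like signal. Its permutation test
shuffles tip labels, with the observed statistic included in the null
set, so p ∈ (0, 1]. Pagel's λ rescales the off-diagonal of C; the GLS
mean and rate σ² are profiled analytically, λ is maximized over [0, 1]
by golden-section search (tolerance 1e-6, endpoints checked), and the
p-value is a likelihood-ratio test against λ = 0 on χ²₁. Because λ = 0
lies on the boundary, the χ²₁ reference is conservative, which only
makes the screen stricter. A star tree makes λ unidentifiable; the
function warns and reports 0.

**Gating rule (a documented choice).** The analysis this package
implements reports both statistics without stating which one gated
genus-level imputation, nor the level used. We flag a category when
*either* test is significant at α = 0.05. The union rule errs toward
imputing — consistent with the screen's purpose of justifying genus
means rather than protecting a familywise error rate — and its combined
false-flag rate on truly signal-free categories stays below 10 %, which
the acceptance suite verifies by simulation.

The decision tree then is: an OTU whose species matches a reference
genome receives that genome's proportions (counts divided by total gene
models) for *all* categories — direct matches are not gated; a
genus-only OTU (or one whose species lacks a genome but whose genus has
members) receives the unweighted mean across the genus's reference
species, but only for flagged categories; OTUs without a genus, or with
a genus absent from the reference, stay unassigned. Genome-size
normalization precedes averaging, and organic-N cycling is the sum of
the peptidase, protease, multicopper-oxidase, and peroxidase
proportions, identical to the count-level sum because the denominators
agree.

**CWM renormalization (a documented choice).** CWMs are computed over
the OTUs carrying a value for the trait, with the plot's relative
abundances renormalized over those OTUs. Treating unassigned abundance
as zero-trait would bias every CWM toward zero by the (often large)
unassigned share; renormalization instead estimates the mean trait of
the *assignable* community. Each plot's coverage — the unrenormalized
abundance share of assigned OTUs — is reported so users can filter
low-coverage plots; the non-renormalized mode is available as an
argument.

# Community analyses

Counts are rarefied once, to 115 sequences per plot by default, by
uniform subsampling without replacement (single recorded draw, not an
average over draws); shallower plots are dropped with a warning.
Bray–Curtis dissimilarity uses the count form
d = 1 − 2Σmin(aᵢ,bᵢ)/Σ(aᵢ+bᵢ), identical to the relative-abundance form
on rarefied tables. PCoA eigen-decomposes the double-centred squared
dissimilarities; coordinates use positive eigenvalues only, negative
eigenvalues (Bray–Curtis is a semimetric) are reported without Cailliez
or Lingoes correction, and axis signs are fixed by making the
largest-magnitude score positive. db-RDA regresses the PCoA coordinates
on the centred explanatory matrix and eigen-decomposes the fitted
values; the constrained share is the projection's fraction of total
positive-eigenvalue inertia.

Clustering is complete-linkage on the dissimilarity matrix. The
within-cluster sum of squared dissimilarities, WSS(k) =
Σ_clusters Σ_{i<j} d²(i,j)/n_cluster, is evaluated for k = 1..k_max, and
k is selected where the curve bends most: the maximizer of the second
difference WSS(k−1) − 2WSS(k) + WSS(k+1) — an operational elbow rule
chosen because "the elbow method" alone does not define one.

Analysis of means compares each cluster's mean growth to the grand mean
with decision limits ȳ ± h·s·√((N−nᵢ)/(N·nᵢ)), s being the pooled
within-cluster standard deviation. For h we use the Bonferroni-adjusted
two-sided t quantile t(1 − α/(2g), N − g): conservative, closed-form,
and reproducible without tabulated exact ANOM constants. The pipeline
classifies on ln stand growth — growth is strongly right-skewed, and the
log scale is also the models' fitting scale. Classification can run
globally or within leaf types; per-leaf-type is the pipeline default
(mirroring how slow/fast balance is reported within needle- and
broadleaf forests in the motivating analysis), but the acceptance
harness uses the global mode because the synthetic truth plants no
leaf-type structure and the global test uses the full sample.

Indicator analysis computes, per OTU and group, specificity A
(group-equalized mean-abundance share) and fidelity B (occurrence
fraction), takes stat = √(A·B) for the best group, and permutes group
labels for significance with the observed statistic included in the
null set.

# Growth models

The plot-level response is ln(mean tree growth, kg C yr⁻¹). Stand age
class and stem density enter as penalized regression splines (basis
dimension 5 — conservative for 70–140 plots; smoothness by REML); MAT,
MAP, N deposition, soil pH, inorganic N, and the broadleaf/needleleaf
indicator enter linearly; the fungal predictor (PCoA axis 1, a CWM
trait, or an exploration-type abundance) enters linearly, never
smoothed. R² is 1 − RSS/TSS on the ln scale, and ΔR² is the difference
between the full and the nested reduced fit on identical plots.
Complete cases only are fitted; drops are counted, never imputed.
Variance inflation factors come from the closed form 1/(1 − R²ⱼ) over
the linear predictors.

Partial residuals for a focal term are yᵢ = f(xᵢ) + Σ_{j≠focal} fⱼ(x̄ⱼ) +
εᵢ on the link scale — the focal contribution at each observation plus
all other terms at their covariate means plus the residual — and
exponentiation returns them to kg C yr⁻¹ so effects read on the
original growth scale. On a single-predictor model the equation
collapses to the observed response exactly, which the tests assert.
Slow/fast stand-growth contrasts use Welch's heteroscedastic t-test
with Satterthwaite degrees of freedom; leaf types missing a class are
reported untestable rather than erroring.

# The synthetic study and what it does (and does not) emulate

The generator's defaults are the study conditions every recovery test
runs under; they were fixed once, from the structure the analysis
assumes, and are not tuned per test.

* **Phylogeny**: pure-birth (Yule) tree rescaled to unit height — the
  simplest ultrametric stand-in for a reference species tree.
* **Reference genomes**: log gene proportions of *signal* categories
  evolve by Brownian motion (σ = 0.6 per unit height) on the tree;
  *noise* categories draw the same marginal spread independently of it.
  Species group into genera of 2–4 consecutive cladewise tips, so
  genera are near-clades; genome totals are log-normal around 15,000
  gene models, slightly larger for medium/long-distance exploration
  types.
* **Latent community axis**: a balanced two-state mixture, exactly half
  the plots at +1 and half at −1 with 0.15 jitter, centred to zero
  mean. A continuous Gaussian axis was considered and rejected: the
  downstream method is hierarchical clustering plus ANOM, which
  presupposes discrete community states — a continuous gradient has no
  stable two-cluster cut, and the planted fast:slow contrast is defined
  on the axis-sign classes. The slow/fast ground-truth labels are the
  axis signs.
* **OTU table**: per-OTU baseline log-abundances N(0, 1.2), per-OTU
  gradient slopes N(0, 1); per-plot compositions are
  Dirichlet-multinomial with concentration 50 (moderate overdispersion
  typical of EMF root-tip surveys) at depths uniform on 120–400.
  Taxonomy coverage follows the observed incompleteness of continental
  EMF surveys: 41 % of OTUs genus-unassigned, and half of the assigned
  OTUs exact species matches, allocated deterministically by OTU index
  (floor rule) for reproducibility.
* **Environment**: covariates drawn independently at field-realistic
  scales (MAT 8 ± 2.5 °C, MAP 800 ± 150 mm, N deposition 12 ± 4 kg N
  ha⁻¹ yr⁻¹, pH 5 ± 0.7, log-normal inorganic N, age classes 1–7, stem
  density 600 ± 120 ha⁻¹, leaf type with consistent dominant species),
  redrawn under the seed until every pairwise |r| < 0.71 so the
  models' independence screen (r² < 0.5) holds by construction.
* **Growth**: per-tree target ln growth = intercept (0.8, ≈ 2.2 kg C
  yr⁻¹ median) + effects of the z-scored covariates (MAT 0.40, MAP
  0.12, N deposition 0.28, pH 0.10, inorganic N 0.10, leaf ± 0.15) + a
  half-sine stand-age effect (amplitude 1.0, peaking mid-rotation) − a
  quadratic density effect (0.30) + γ·axis + plot residual + tree
  noise. γ = ln(3)/2 plants a three-fold fast:slow contrast between
  axis classes. The residual sd is split into a plot-level component
  (0.92) — the variance the plot-level models actually see — and a
  within-plot tree-level component (0.30); putting all noise at tree
  level would average away across the ~20 trees of a plot and leave the
  response variance share of the community effect undefined. With this
  budget the community term carries ≈ 17 % of plot-level ln-growth
  variance and the abiotic terms ≈ 35 %, mimicking a 54 % → 37 % R²
  contrast. The within-plot DBH distribution, unreported in forest
  terms, is right-skewed 5 + Gamma(2, 7) cm.
* **Census construction**: the final DBH solves the species' allometric
  equation for the target carbon gain by bisection on [DBH₀, DBH₀ + 50]
  cm (tolerance 1e-8 cm; all four equations are monotone there).
  Targets are clamped to ln growth ∈ [−4.6, 4.4] (0.01–80 kg C yr⁻¹) so
  every draw is invertible within the bracket; the clamp binds on well
  under 1 % of trees. Dead, shrinking, and sub-5-cm records are
  injected at floor(fraction × total) counts, allocated by within-plot
  tree position so every plot keeps measured trees. Recomputing growth
  from the written census through the inventory module reproduces the
  targets to 1e-6 relative, which the tests assert.

What the generator does **not** emulate: raw ITS sequences and their
error structure, spatial autocorrelation among plots, tree mortality
dynamics, host-specific fungal assemblages, and any causal pathway from
*traits* to growth — only composition affects growth, so CWM trait
models on synthetic data estimate an attenuated, indirect association.
Passing recovery tests therefore demonstrate the estimators' internal
correctness and calibration, not that real forests behave this way.

# Numerical choices and degenerate inputs

Every stochastic function takes an explicit seed and restores the
caller's RNG state; pipeline stages derive substreams by hashing (seed,
stage name), so adding a stage never perturbs earlier ones. Constant
traits, singular covariances, star trees, singleton clusters, empty
plots, collinear model matrices, unbracketable allometric inversions,
and abundance rows that do not normalize all raise typed errors or
documented warnings rather than propagating NaN. Clustering ties are
broken by R's deterministic merge order; the degenerate all-identical
matrix selects k = 2 with a warning. The K permutation test counts ties
as exceedances (≥ with a 1e-12 slack), keeping p conservative.

# Problem sizes used in validation

The validation suite runs at sizes chosen to make the statistics
informative yet quick: calibration of K and λ uses a 50-tip tree with
200 Brownian and 200 independent replicates (1000 permutations for the
type-I check); end-to-end recovery uses 50 replicate studies of 90
plots, 150 OTUs, and 1800 trees each, with 200-replicate bootstraps and
99-permutation screens inside the loop; oracle-equivalence checks use
100 random small instances. The acceptance script runs one full-size
study (1000 bootstrap replicates, 10,000 permutations) plus the
calibration summaries.

# Known limitations

Genus-mean imputation ignores within-genus trait variance and
phylogenetic distance within the genus; ancestral-state methods could
refine it but are out of scope. The ANOM h uses a Bonferroni bound, not
exact multivariate-t constants, so limits are slightly wide. ΔR² from
an estimated ordination axis is attenuated relative to the latent
community effect (errors-in-variables), which the recovery tolerances
acknowledge. The fast:slow stand-growth *ratio* of class means is an
intrinsically noisy estimator under a log-normal growth distribution:
with the planted 17 % variance share fixing the total variance, the
within-class spread alone puts the single-study ratio outside ±25 % of
truth in a substantial minority of replicates, which the end-to-end
tests surface honestly rather than averaging away.
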