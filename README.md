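# mycogrowth

Forests are among the largest terrestrial carbon sinks, and most temperate
and boreal trees depend on ectomycorrhizal fungi (EMF) for soil nutrient
acquisition. `mycogrowth` implements, as a tested R pipeline, a
continental-scale analysis linking EMF community composition and
genome-derived functional gene traits to forest tree growth: from
two-census tree inventories and plot × OTU tables, through
phylogenetic-signal-gated trait imputation and community ordination, to
additive growth models that partition the variance a fungal predictor adds
over climate, nitrogen deposition, soil, and stand structure.

The original analysis of this kind joins restricted-access forest
monitoring inventories to a molecular EMF survey; neither can be
redistributed. The package therefore ships a first-class synthetic-data
generator that emulates all five inputs — census, environment, OTU table
with realistically incomplete taxonomy, reference genomes with controlled
phylogenetic signal, and a species tree — with a ground-truth record, so
every stage is testable end to end for parameter recovery.

## What it computes

**Inventory carbon accounting.** Trees that died, shrank, or fall below
the 5 cm DBH measurement threshold are filtered (and logged). Aboveground
biomass comes from species-group allometric equations
(e.g. Scots pine `12.91 − 2.8035·DBH + 0.3535·DBH²`, European beech
`0.19465·DBH^2.418775`, kg), carbon is 50 % of biomass, and per-tree
growth is the annual biomass-C difference between censuses
(kg C yr⁻¹). Stand growth (Mg C ha⁻¹ yr⁻¹) resamples measured trees with
replacement to the in-situ stem density, 1000 times.

**Trait engine.** Gene-count categories (peptidases, proteases,
multicopper oxidases, peroxidases, inorganic-N metabolism, …) are screened
for phylogenetic signal on the reference species tree with Blomberg's K
(tip-permutation test, K = observed/expected variance ratio under Brownian
motion) and Pagel's λ (profile likelihood over [0,1], likelihood-ratio
test). A decision tree then assigns genome-size-normalized gene
proportions to OTUs: exact species matches always, genus means only for
categories with signal, nothing for genus-unassigned OTUs. Plot-level
community-weighted means (CWM) weight trait values by relative abundance,
with per-plot coverage reported; organic-N cycling aggregates the four
constituent enzyme families. Hyphal exploration-type relative abundances
are tabulated the same way.

**Community module.** Rarefaction to 115 sequences per plot, richness and
Shannon diversity, Bray–Curtis dissimilarity, PCoA, db-RDA against the
environment, complete-linkage hierarchical clustering with elbow-rule k
selection, analysis-of-means (ANOM) classification of clusters into slow /
fast / neutral growth, and IndVal indicator-species analysis with a
permutation test.

**Growth models.** Plot-level GAMs of ln growth with penalized-spline
smooths for stand age and density (REML smoothness selection), linear
terms for the remaining covariates, and the fungal predictor (PCoA axis 1,
a CWM trait, or an exploration-type abundance) entering linearly. The
package reports ΔR² from adding the fungal term, variance inflation
factors, back-transformed partial residuals, and Welch-t slow/fast stand
growth contrasts.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_growth.R
Rscript analysis/03_traits.R
Rscript analysis/04_community.R
Rscript analysis/05_models.R
```

writes every intermediate table under `results/` and prints, for the
default simulated study of 90 plots (output of the run above):

```
Filtered census: 1530 valid trees; 270 removed ( dbh_below_5cm 90, dead 90, shrank 90 )
Per-tree growth: median 2.51 kg C yr^-1 (IQR 1.18-6.09 )
Signal screen: 8 of 12 categories flagged ( peptidases, proteases, ... )
CWM coverage: median 0.46 of relative abundance carried by assigned OTUs
Hierarchical clustering: elbow selects k = 2
Full model R^2 = 0.63; without the fungal predictor 0.56; community composition adds 0.07
VIF range: 1.01-1.3
```

Read: the elbow rule finds the two planted community states, and low VIFs
confirm the fungal and abiotic predictors are separable. The generator
plants a ~17-percentage-point community share of ln-growth variance; a
single simulated study estimates it with considerable spread (7 points on
this seed — the acceptance suite measures the median across 50 replicate
studies). The ANOM table classifies the two clusters as fast and slow,
and `compare_growth_classes()` contrasts their stand growth per leaf
type.

Equivalent single-call form:

```r
library(mycogrowth)
sim <- simulate_forest(sim_config(), seed = 1)
res <- run_pipeline(sim, seed = 1)
res$report
```

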