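# Synthetic data generator: emulates the five study inputs (tree census,
# plot environment, OTU table + taxonomy, reference genomes, species tree)
# with the statistical structure the downstream analysis assumes, plus a
# ground-truth record so every stage is testable for parameter recovery.

#' Simulation configuration
#'
#' Defaults define the study conditions the pipeline is validated against:
#' a balanced two-state community axis whose effect on ln tree growth gives
#' a three-fold fast:slow contrast between axis classes, contributing about
#' 17 percentage points of plot-level response variance, on top of
#' log-linear environmental effects (~35 percent of variance, dominated by
#' MAT, N deposition and leaf type), smooth stand-age and density effects,
#' and a plot-level residual. Taxonomic incompleteness mirrors continental
#' EMF surveys: 41 percent of OTUs genus-unassigned and half of the
#' assigned OTUs exact reference-species matches.
#'
#' @param n_plots number of plots (default 90).
#' @param n_otus number of OTUs (default 150).
#' @param n_ref_species reference genomes / tree tips (default 50, >= 4).
#' @param n_trees_per_plot trees per plot including injected invalid
#'   records (default 20).
#' @param depth_range min/max sequencing depth per plot; min must reach the
#'   intended rarefaction depth (default c(120, 400)).
#' @param frac_genus_unassigned share of OTUs with no genus label
#'   (default 0.41).
#' @param frac_species_match_of_assigned share of assigned OTUs that match
#'   a reference species exactly (default 0.5).
#' @param env_betas effects of the z-scored covariates (MAT, MAP,
#'   N_deposition, soil_pH, inorganic_N) and the leaf-type contrast on ln
#'   growth.
#' @param age_amplitude,density_curvature amplitudes of the smooth stand
#'   age (half-sine over classes 1..7) and density (negative quadratic in
#'   the z-score) effects.
#' @param gamma community-axis effect on ln growth; the default ln(3)/2
#'   plants a three-fold fast:slow growth contrast.
#' @param axis_jitter_sd within-class spread of the latent axis around
#'   +/- 1 (default 0.15).
#' @param gradient_sd sd of per-OTU log-abundance slopes along the axis
#'   (default 1).
#' @param dm_concentration Dirichlet-multinomial concentration (default 50,
#'   moderate overdispersion typical of EMF root-tip surveys).
#' @param intercept baseline ln growth, kg C yr^-1 (default 0.8).
#' @param noise_sd plot-level residual sd of ln growth (default 0.92).
#' @param tree_noise_sd within-plot tree-level sd of ln growth
#'   (default 0.3).
#' @param frac_dead,frac_shrinking,frac_sub5cm shares of injected invalid
#'   trees (defaults 0.05 each).
#' @param signal_categories,noise_categories trait categories evolved by
#'   Brownian motion on the tree versus drawn independently of it.
#' @param census_interval_yr years between censuses (default 5).
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_plots = 90,
                       n_otus = 150,
                       n_ref_species = 50,
                       n_trees_per_plot = 20,
                       depth_range = c(120, 400),
                       frac_genus_unassigned = 0.41,
                       frac_species_match_of_assigned = 0.5,
                       env_betas = c(MAT = 0.40, MAP = 0.12,
                                     N_deposition = 0.28, soil_pH = 0.10,
                                     inorganic_N = 0.10, leaf_type = 0.30),
                       age_amplitude = 1.0,
                       density_curvature = 0.30,
                       gamma = log(3) / 2,
                       axis_jitter_sd = 0.15,
                       gradient_sd = 1.0,
                       dm_concentration = 50,
                       intercept = 0.8,
                       noise_sd = 0.92,
                       tree_noise_sd = 0.30,
                       frac_dead = 0.05,
                       frac_shrinking = 0.05,
                       frac_sub5cm = 0.05,
                       signal_categories = c(
                         "peptidases", "proteases", "multicopper_oxidases",
                         "peroxidases", "energy_nutrient_metabolism",
                         "inorganic_N_metabolism", "N_permeases",
                         "chitin_biosynthesis"),
                       noise_categories = c(
                         "amino_acid_metabolism", "carbohydrate_metabolism",
                         "ammonium_sensing", "glucan_biosynthesis"),
                       census_interval_yr = 5,
                       seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(frac_genus_unassigned, frac_species_match_of_assigned,
             frac_dead, frac_shrinking, frac_sub5cm)
  assert_that(all(fracs >= 0 & fracs <= 1), "proportions must lie in [0,1]")
  assert_that(n_ref_species >= 4, "need at least 4 reference species")
  assert_that(length(depth_range) == 2 && depth_range[1] >= 1 &&
                depth_range[1] <= depth_range[2],
              "depth_range must be an increasing positive pair")
  assert_that(length(intersect(signal_categories, noise_categories)) == 0,
              "signal and noise categories must be disjoint")
  unknown <- setdiff(c(signal_categories, noise_categories),
                     trait_categories)
  assert_that(length(unknown) == 0,
              "unknown trait categories: ", paste(unknown, collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree rescaled to unit height, standing in for the
#' reference all-fungi species tree.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return a rooted ultrametric `phylo` object, tips `sp01`, `sp02`, ...
#' @export
simulate_phylogeny <- function(n_tips, seed = 1) {
  assert_that(n_tips >= 2, "need at least 2 tips")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

# Base (log) gene proportions per category; small shares of the genome.
category_base_prop <- c(
  peptidases = 0.010, proteases = 0.006, multicopper_oxidases = 0.003,
  peroxidases = 0.002, energy_nutrient_metabolism = 0.030,
  amino_acid_metabolism = 0.020, carbohydrate_metabolism = 0.025,
  inorganic_N_metabolism = 0.004, N_permeases = 0.002,
  ammonium_sensing = 0.001, chitin_biosynthesis = 0.003,
  glucan_biosynthesis = 0.003
)

#' Simulate reference genomes with controlled phylogenetic signal
#'
#' For categories in `signal_categories` the log gene proportion evolves by
#' Brownian motion along the tree; `noise_categories` are drawn
#' independently of it with the same marginal spread. Species are grouped
#' into genera of 2-4 consecutive tips (tips ordered cladewise, so genera
#' are near-clades) and each genus draws a hyphal exploration type, with
#' medium/long types carrying somewhat larger genomes.
#'
#' @param phylo tree from [simulate_phylogeny()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `reference` (data.frame: `species`, `genus`,
#'   `total_gene_models`, `exploration_type`, one count column per
#'   category) and `signal_flags` (named logical).
#' @export
simulate_reference_traits <- function(phylo, config, seed = 1) {
  n <- length(phylo$tip.label)
  cats <- c(config$signal_categories, config$noise_categories)
  with_seed(seed, {
    # genera: consecutive tips in cladewise order, sizes 2-4
    sizes <- integer(0)
    left <- n
    while (left > 0) {
      s <- min(left, sample(2:4, 1))
      if (left - s == 1) s <- s + 1  # avoid a trailing singleton genus
      sizes <- c(sizes, s)
      left <- left - s
    }
    genus <- rep(sprintf("genus%02d", seq_along(sizes)), sizes)
    type_by_genus <- sample(exploration_types, length(sizes), replace = TRUE,
                            prob = c(0.30, 0.20, 0.20, 0.15, 0.15))
    etype <- rep(type_by_genus, sizes)
    size_mult <- c(contact = 0.90, `short-distance` = 0.95,
                   `medium-distance fringe` = 1.20,
                   `medium-distance smooth` = 1.05,
                   `long-distance` = 1.15)[etype]
    total <- round(stats::rlnorm(n, log(15000), 0.20) * size_mult)
    logp <- matrix(NA_real_, n, length(cats),
                   dimnames = list(phylo$tip.label, cats))
    for (cc in cats) {
      base <- log(category_base_prop[[cc]])
      if (cc %in% config$signal_categories) {
        logp[, cc] <- base +
          ape::rTraitCont(phylo, model = "BM", sigma = 0.6)[phylo$tip.label]
      } else {
        logp[, cc] <- base + stats::rnorm(n, 0, 0.6)
      }
    }
    prop <- exp(logp)
    # keep category counts within the genome total
    scale <- pmin(1, 0.5 / rowSums(prop))
    counts <- round(prop * scale * total)
    ref <- data.frame(species = phylo$tip.label, genus = genus,
                      total_gene_models = as.integer(total),
                      exploration_type = etype,
                      stringsAsFactors = FALSE)
    ref <- cbind(ref, as.data.frame(counts))
    flags <- stats::setNames(cats %in% config$signal_categories, cats)
    list(reference = ref, signal_flags = flags)
  })
}

#' Simulate the plot-by-OTU count table, taxonomy, and latent axis
#'
#' The latent community axis is a balanced two-state mixture: exactly half
#' the plots (lowest plot indices) sit at +1 and half at -1, each jittered
#' by `axis_jitter_sd`, giving a zero-mean axis with genuine two-cluster
#' community structure. Each OTU's expected share varies log-linearly along
#' the axis (slope sd `gradient_sd`); per-plot compositions are
#' Dirichlet-multinomial with concentration `dm_concentration` and depth
#' uniform over `depth_range`. Taxonomy coverage follows the configured
#' fractions with deterministic floor counts allocated by OTU index:
#' species-matched OTUs first, then genus-only, then unassigned.
#'
#' @param config a [sim_config()].
#' @param reference reference table from [simulate_reference_traits()].
#' @param seed integer seed.
#' @return list with `otu_table` (plot x OTU integer matrix), `taxonomy`
#'   (`otu_id`, `genus`, `species`), `latent_axis` (named by plot).
#' @export
simulate_otu_table <- function(config, reference, seed = 1) {
  assert_that(config$depth_range[1] > 0, "depth_range min must be positive")
  n_p <- config$n_plots
  n_o <- config$n_otus
  plots <- sprintf("plot%03d", seq_len(n_p))
  otus <- sprintf("otu%04d", seq_len(n_o))

  n_half <- floor_count(0.5, n_p)
  axis_sign <- rep(c(1, -1), c(n_half, n_p - n_half))

  n_un <- floor_count(config$frac_genus_unassigned, n_o)
  n_assigned <- n_o - n_un
  n_sp <- floor_count(config$frac_species_match_of_assigned, n_assigned)

  with_seed(seed, {
    axis <- axis_sign + stats::rnorm(n_p, 0, config$axis_jitter_sd)
    axis <- axis - mean(axis)
    names(axis) <- plots

    base <- stats::rnorm(n_o, 0, 1.2)
    slope <- stats::rnorm(n_o, 0, config$gradient_sd)
    counts <- matrix(0L, n_p, n_o, dimnames = list(plots, otus))
    depths <- sample(seq(config$depth_range[1], config$depth_range[2]),
                     n_p, replace = TRUE)
    for (p in seq_len(n_p)) {
      share <- exp(base + slope * axis[p])
      share <- share / sum(share)
      alpha <- config$dm_concentration * share
      g <- stats::rgamma(n_o, shape = alpha, rate = 1)
      g[!is.finite(g)] <- 0
      if (sum(g) <= 0) g <- share
      counts[p, ] <- stats::rmultinom(1, depths[p], g / sum(g))[, 1]
    }

    sp_pick <- sample(reference$species, n_sp, replace = n_sp > nrow(reference))
    gen_pick <- sample(unique(reference$genus), n_assigned - n_sp,
                       replace = TRUE)
    taxonomy <- data.frame(
      otu_id = otus,
      genus = c(reference$genus[match(sp_pick, reference$species)],
                gen_pick, rep(NA_character_, n_un)),
      species = c(sp_pick, rep(NA_character_, n_assigned - n_sp + n_un)),
      stringsAsFactors = FALSE
    )
    list(otu_table = counts, taxonomy = taxonomy, latent_axis = axis)
  })
}

#' Simulate the plot environment table
#'
#' Covariates are drawn independently (MAT, MAP, N deposition, soil pH,
#' inorganic N, stand age class 1-7, stem density, leaf type with a
#' consistent dominant species); draws are repeated, deterministically under
#' the seed, until every numeric covariate pair satisfies |r| < 0.71
#' (r^2 < 0.5), the independence screen the growth models assume.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame with one row per plot.
#' @export
simulate_plot_environment <- function(config, seed = 1) {
  n <- config$n_plots
  assert_that(n >= 2, "need at least 2 plots")
  with_seed(seed, {
    for (attempt in 1:100) {
      env <- data.frame(
        plot_id = sprintf("plot%03d", seq_len(n)),
        MAT = stats::rnorm(n, 8, 2.5),
        MAP = stats::rnorm(n, 800, 150),
        N_deposition = pmax(1, stats::rnorm(n, 12, 4)),
        soil_pH = pmin(7.5, pmax(3.5, stats::rnorm(n, 5, 0.7))),
        inorganic_N = stats::rlnorm(n, log(8), 0.5),
        stand_age_class = sample(1:7, n, replace = TRUE),
        stem_density = pmin(1200, pmax(200, round(stats::rnorm(n, 600, 120)))),
        stringsAsFactors = FALSE
      )
      num <- c("MAT", "MAP", "N_deposition", "soil_pH", "inorganic_N",
               "stand_age_class", "stem_density")
      r <- stats::cor(env[num])
      if (max(abs(r[upper.tri(r)])) < 0.707) break
    }
    env$leaf_type <- sample(c("broadleaf", "needleleaf"), n, replace = TRUE)
    env$dominant_species <- ifelse(
      env$leaf_type == "broadleaf",
      sample(c("european_beech", "mixed_oak"), n, replace = TRUE),
      sample(c("scots_pine", "norway_spruce"), n, replace = TRUE)
    )
    env
  })
}

# Plot-level expected ln growth (kg C yr^-1) from environment and axis.
plot_ln_growth_mean <- function(env, latent_axis, config) {
  z <- function(x) as.vector(scale(x))
  b <- config$env_betas
  leaf <- ifelse(env$leaf_type == "broadleaf", 0.5, -0.5)
  config$intercept +
    b[["MAT"]] * z(env$MAT) + b[["MAP"]] * z(env$MAP) +
    b[["N_deposition"]] * z(env$N_deposition) +
    b[["soil_pH"]] * z(env$soil_pH) +
    b[["inorganic_N"]] * z(env$inorganic_N) +
    b[["leaf_type"]] * leaf +
    config$age_amplitude * sin(pi * (env$stand_age_class - 1) / 6) +
    -config$density_curvature * z(env$stem_density)^2 +
    config$gamma * latent_axis[env$plot_id]
}

# Vectorized bisection inverting biomass_final = target on
# [dbh_initial, dbh_initial + 50] cm, tolerance 1e-8 cm.
invert_allometry <- function(species_group, dbh_initial, biomass_target) {
  lo <- dbh_initial
  hi <- dbh_initial + 50
  b_hi <- vapply(seq_along(hi), function(i)
    allometric_biomass(species_group[i], hi[i]), numeric(1))
  bad <- b_hi < biomass_target
  if (any(bad)) {
    stop(errorCondition(
      paste0("allometric inversion failed to bracket a root for ",
             sum(bad), " tree(s), first at index ", which(bad)[1]),
      class = c("mycogrowth_simfail", "error")))
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    b_mid <- vapply(seq_along(mid), function(i)
      allometric_biomass(species_group[i], mid[i]), numeric(1))
    up <- b_mid < biomass_target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(hi - lo) < 1e-8) break
  }
  (lo + hi) / 2
}

#' Simulate the two-census tree table from the growth model
#'
#' Valid trees draw an initial DBH from a right-skewed distribution
#' (5 + gamma(shape 2, scale 7) cm), receive a target ln growth =
#' plot-level mean (environment, smooth age/density, community axis, plot
#' residual) + tree-level noise, clamped to [-4.6, 4.4] so every target is
#' invertible within the 50 cm bisection bracket, and the final DBH solving
#' the species' allometric equation for that annual carbon gain over the
#' census interval. Dead, shrinking, and sub-5-cm records are injected at
#' the configured fractions, allocated deterministically by within-plot
#' tree position so each plot keeps measured valid trees.
#'
#' @param env environment table from [simulate_plot_environment()].
#' @param latent_axis named axis from [simulate_otu_table()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `census` (TreeCensusRecord table), `targets` (true
#'   per-tree growth rates, kg C yr^-1, NA for invalid records) and
#'   `ground_truth` (list: `latent_axis`, `true_gamma`, `true_env_betas`,
#'   `signal_flags`, `slow_fast_truth`, `plot_ln_growth`).
#' @export
simulate_tree_census <- function(env, latent_axis, config, seed = 1) {
  assert_that(all(env$plot_id %in% names(latent_axis)),
              "environment and latent axis must share plot ids")
  n_p <- nrow(env)
  ntpp <- config$n_trees_per_plot
  n_total <- n_p * ntpp

  n_dead <- floor_count(config$frac_dead, n_total)
  n_shrink <- floor_count(config$frac_shrinking, n_total)
  n_sub5 <- floor_count(config$frac_sub5cm, n_total)
  # allocation order: within-plot position major, plot minor (census rows
  # are plot-major, position j of plot p sits at (p-1)*ntpp + j)
  ord <- order(rep(seq_len(ntpp), times = n_p))
  status_code <- rep("valid", n_total)
  status_code[ord[seq_len(n_dead)]] <- "dead"
  status_code[ord[n_dead + seq_len(n_shrink)]] <- "shrink"
  status_code[ord[n_dead + n_shrink + seq_len(n_sub5)]] <- "sub5"

  plot_idx <- rep(seq_len(n_p), each = ntpp)
  mu_plot <- plot_ln_growth_mean(env, latent_axis, config)

  with_seed(seed, {
    plot_resid <- stats::rnorm(n_p, 0, config$noise_sd)
    dbh0 <- 5 + stats::rgamma(n_total, shape = 2, scale = 7)
    ln_target <- mu_plot[plot_idx] + plot_resid[plot_idx] +
      stats::rnorm(n_total, 0, config$tree_noise_sd)
    ln_target <- pmin(pmax(ln_target, -4.6), 4.4)
    target <- exp(ln_target)
    sp <- env$dominant_species[plot_idx]
    yr0 <- 2005
    yr1 <- yr0 + config$census_interval_yr

    valid <- status_code == "valid"
    b0 <- numeric(n_total)
    for (s in unique(sp)) {
      i <- sp == s
      b0[i] <- allometric_biomass(s, dbh0[i])
    }
    dbh1 <- dbh0
    b_target <- b0 + target * config$census_interval_yr / carbon_fraction
    dbh1[valid] <- invert_allometry(sp[valid], dbh0[valid], b_target[valid])

    status <- ifelse(status_code == "dead", "dead", "alive")
    dbh1[status_code == "dead"] <- dbh0[status_code == "dead"] * 1.02
    shrinkers <- status_code == "shrink"
    dbh1[shrinkers] <- pmax(5, dbh0[shrinkers] - 0.5)
    sub5 <- status_code == "sub5"
    dbh0[sub5] <- stats::runif(sum(sub5), 3, 4.9)
    dbh1[sub5] <- dbh0[sub5] + 0.3

    census <- data.frame(
      tree_id = sprintf("%s_t%02d", env$plot_id[plot_idx],
                        rep(seq_len(ntpp), n_p)),
      plot_id = env$plot_id[plot_idx],
      species_group = sp,
      dbh_initial = dbh0,
      dbh_final = dbh1,
      year_initial = yr0,
      year_final = yr1,
      status = status,
      stringsAsFactors = FALSE
    )
    target[!valid] <- NA_real_
    axis <- latent_axis[env$plot_id]
    truth <- list(
      latent_axis = axis,
      true_gamma = config$gamma,
      true_env_betas = config$env_betas,
      signal_flags = stats::setNames(
        c(config$signal_categories, config$noise_categories) %in%
          config$signal_categories,
        c(config$signal_categories, config$noise_categories)),
      slow_fast_truth = stats::setNames(
        ifelse(axis > 0, "fast", "slow"), env$plot_id),
      plot_ln_growth = stats::setNames(mu_plot + plot_resid, env$plot_id)
    )
    list(census = census, targets = target, ground_truth = truth)
  })
}

#' Simulate the complete study
#'
#' Generates all five inputs plus ground truth, with per-stage RNG
#' substreams derived from the master seed so stages can be regenerated
#' independently.
#'
#' @param config a [sim_config()].
#' @param seed master seed (default: the config's seed).
#' @return list with `phylogeny`, `reference`, `signal_flags`, `otu_table`,
#'   `taxonomy`, `latent_axis`, `env`, `census`, `targets`, `ground_truth`,
#'   `config`.
#' @export
simulate_forest <- function(config = sim_config(), seed = config$seed) {
  phy <- simulate_phylogeny(config$n_ref_species,
                            seed = stage_seed(seed, "phylogeny"))
  rt <- simulate_reference_traits(phy, config,
                                  seed = stage_seed(seed, "reference"))
  ot <- simulate_otu_table(config, rt$reference,
                           seed = stage_seed(seed, "otu_table"))
  env <- simulate_plot_environment(config,
                                   seed = stage_seed(seed, "environment"))
  cen <- simulate_tree_census(env, ot$latent_axis, config,
                              seed = stage_seed(seed, "census"))
  list(phylogeny = phy, reference = rt$reference,
       signal_flags = rt$signal_flags, otu_table = ot$otu_table,
       taxonomy = ot$taxonomy, latent_axis = ot$latent_axis, env = env,
       census = cen$census, targets = cen$targets,
       ground_truth = cen$ground_truth, config = config)
}
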