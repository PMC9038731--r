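# Forest-inventory growth accounting: census filters, species-specific
# allometric biomass, per-tree carbon growth, and the stand-level bootstrap.

#' Species-specific allometric equations
#'
#' Coefficients of the published aboveground-biomass equations for the four
#' dominant species groups. Scots pine uses a quadratic in DBH; the other
#' three are power laws. Biomass is in kg, DBH in cm; equations apply from
#' 5 cm DBH upwards, the inventory's minimum measured size.
#'
#' @format A list keyed by species group, each entry holding `form`
#'   (`"quadratic"` or `"power"`) and `coef`.
#' @export
allometric_models <- list(
  scots_pine     = list(form = "quadratic", coef = c(12.91, -2.8035, 0.3535)),
  european_beech = list(form = "power",     coef = c(0.19465, 2.418775)),
  norway_spruce  = list(form = "power",     coef = c(0.4626, 2.133)),
  mixed_oak      = list(form = "power",     coef = c(0.23095, 2.27265))
)

#' Fraction of tree dry biomass that is carbon
#' @export
carbon_fraction <- 0.5

#' Aboveground biomass from DBH
#'
#' Evaluates the species group's allometric equation. All four equations are
#' monotone increasing for DBH >= 5 cm (the pine quadratic's vertex lies
#' below 4 cm), so biomass differences are valid growth measures over the
#' inventory's size range.
#'
#' @param species_group one of `"scots_pine"`, `"european_beech"`,
#'   `"norway_spruce"`, `"mixed_oak"`.
#' @param dbh diameter at breast height in cm, `>= 5`; vectorized.
#' @return aboveground biomass in kg.
#' @examples
#' allometric_biomass("scots_pine", 10) # 20.225 kg
#' @export
allometric_biomass <- function(species_group, dbh) {
  species_group <- match.arg(species_group, names(allometric_models))
  assert_that(all(is.finite(dbh)) && all(dbh >= 5),
              "allometric equations apply only to DBH >= 5 cm")
  m <- allometric_models[[species_group]]
  if (m$form == "quadratic") {
    m$coef[1] + m$coef[2] * dbh + m$coef[3] * dbh^2
  } else {
    m$coef[1] * dbh^m$coef[2]
  }
}

#' Filter a two-census tree table to valid growth records
#'
#' Removes dead trees, trees below the 5 cm DBH measurement threshold at
#' either census, and trees that shrank over the growth period. Each removed
#' record is logged with the first matching reason, checked in the order
#' dead, size, shrink.
#'
#' @param records data.frame with columns `tree_id`, `plot_id`,
#'   `species_group`, `dbh_initial`, `dbh_final`, `year_initial`,
#'   `year_final`, `status`.
#' @return list with `retained` (valid records, input order preserved) and
#'   `rejected` (removed records plus a `reason` column).
#' @export
filter_census <- function(records) {
  needed <- c("tree_id", "plot_id", "species_group", "dbh_initial",
              "dbh_final", "year_initial", "year_final", "status")
  assert_that(all(needed %in% names(records)),
              "census table is missing columns: ",
              paste(setdiff(needed, names(records)), collapse = ", "))
  reason <- rep(NA_character_, nrow(records))
  dead <- records$status != "alive"
  small <- records$dbh_initial < 5 | records$dbh_final < 5
  shrink <- records$dbh_final < records$dbh_initial
  reason[!dead & !small & shrink] <- "shrank"
  reason[!dead & small] <- "dbh_below_5cm"
  reason[dead] <- "dead"
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}

#' Per-tree annual carbon growth rate
#'
#' Converts the paired DBH observations of filtered records into an annual
#' biomass-carbon gain: half the aboveground biomass difference (carbon
#' fraction 0.5) divided by the census interval in whole years.
#'
#' @param records filtered census records (see [filter_census()]).
#' @return data.frame with `tree_id`, `plot_id`, `species_group`,
#'   `biomass_initial`, `biomass_final` (kg), `interval` (yr) and
#'   `growth_rate` (kg C yr^-1).
#' @export
tree_growth_rate <- function(records) {
  interval <- records$year_final - records$year_initial
  assert_that(all(interval > 0), "census interval must be positive")
  b0 <- b1 <- numeric(nrow(records))
  for (sp in unique(records$species_group)) {
    i <- records$species_group == sp
    b0[i] <- allometric_biomass(sp, records$dbh_initial[i])
    b1[i] <- allometric_biomass(sp, records$dbh_final[i])
  }
  data.frame(
    tree_id = records$tree_id,
    plot_id = records$plot_id,
    species_group = records$species_group,
    biomass_initial = b0,
    biomass_final = b1,
    interval = interval,
    growth_rate = carbon_fraction * (b1 - b0) / interval,
    stringsAsFactors = FALSE
  )
}

#' Stand-level growth by resampling trees to the in-situ stem density
#'
#' Only a subset of trees on a monitoring plot carries paired growth
#' measurements, so plot totals cannot be summed directly. Each bootstrap
#' replicate draws `ceiling(stem_density)` measured trees with replacement,
#' sums their annual carbon gain and converts to Mg C ha^-1 yr^-1. The
#' replicate distribution gives the stand mean and a 95 percent percentile
#' interval.
#'
#' @param growth per-tree growth table for one plot (see
#'   [tree_growth_rate()]); only `growth_rate` is used.
#' @param stem_density live stems per hectare (>= 1).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return one-row data.frame with `n_trees`, `stem_density`, `n_reps`,
#'   `mean_growth`, `ci_low`, `ci_high` (Mg C ha^-1 yr^-1).
#' @export
stand_growth_bootstrap <- function(growth, stem_density, n_reps = 1000,
                                   seed = 1) {
  g <- growth$growth_rate
  assert_that(length(g) >= 1, "no trees with growth measurements")
  assert_that(stem_density >= 1, "stem density must be >= 1")
  assert_that(n_reps >= 1, "n_reps must be >= 1")
  d <- as.integer(ceiling(stem_density))
  totals <- with_seed(seed, {
    idx <- sample.int(length(g), d * n_reps, replace = TRUE)
    colSums(matrix(g[idx], nrow = d)) / 1000  # kg -> Mg
  })
  ci <- unname(stats::quantile(totals, c(0.025, 0.975), type = 7))
  data.frame(
    n_trees = length(g), stem_density = stem_density, n_reps = n_reps,
    mean_growth = mean(totals), ci_low = ci[1], ci_high = ci[2]
  )
}

#' Stand growth for every plot of a growth table
#'
#' @param growth per-tree growth table (all plots).
#' @param env environment table with `plot_id` and `stem_density`.
#' @param n_reps bootstrap replicates per plot.
#' @param seed integer seed; each plot uses an offset substream.
#' @return data.frame with one row per plot that has measured trees.
#' @export
stand_growth_all <- function(growth, env, n_reps = 1000, seed = 1) {
  plots <- intersect(env$plot_id, unique(growth$plot_id))
  out <- lapply(seq_along(plots), function(i) {
    p <- plots[i]
    res <- stand_growth_bootstrap(
      growth[growth$plot_id == p, , drop = FALSE],
      env$stem_density[env$plot_id == p][1],
      n_reps = n_reps,
      seed = stage_seed(seed + i, "stand_bootstrap")
    )
    cbind(plot_id = p, res)
  })
  do.call(rbind, out)
}
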