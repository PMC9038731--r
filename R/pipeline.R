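# File interchange (TSV/CSV/Newick/JSON) and the orchestrating pipeline
# that chains simulate -> growth -> traits -> community -> models.

#' Read / write a plot-by-OTU count table
#'
#' TSV with OTU ids as the header row and plot ids in the first column.
#' Counts must parse as non-negative integers; violations are reported with
#' their line number.
#'
#' @param path file path.
#' @return integer matrix with dimnames.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  assert_that(nrow(df) > 0 && ncol(df) > 1, "empty OTU table: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_invalid("invalid count at line ", bad[1, 1] + 1L,
                 " (plot ", df[[1]][bad[1, 1]], ", OTU ",
                 colnames(m)[bad[1, 2]], ")")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_otu_table
#' @param table plot x OTU matrix.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(plot_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted Newick phylogeny
#'
#' @param path Newick file.
#' @return a rooted `phylo` with branch lengths.
#' @export
read_phylogeny <- function(path) {
  tr <- ape::read.tree(path)
  assert_that(inherits(tr, "phylo"), "could not parse Newick tree: ", path)
  assert_that(!is.null(tr$edge.length), "tree has no branch lengths")
  assert_that(ape::is.rooted(tr), "tree must be rooted")
  tr
}

#' Write all simulated artifacts to a directory
#'
#' Census CSV, environment TSV, OTU table TSV, taxonomy TSV, reference TSV,
#' Newick tree, and ground-truth JSON.
#'
#' @param sim output of [simulate_forest()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$census, file.path(dir, "census.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(sim$env, file.path(dir, "environment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_otu_table(sim$otu_table, file.path(dir, "otu_table.tsv"))
  utils::write.table(sim$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$reference, file.path(dir, "reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$phylogeny, file.path(dir, "species_tree.nwk"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(latent_axis = as.list(gt$latent_axis),
         true_gamma = gt$true_gamma,
         true_env_betas = as.list(gt$true_env_betas),
         signal_flags = as.list(gt$signal_flags),
         slow_fast_truth = as.list(gt$slow_fast_truth)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build the plot-level model frame
#'
#' Joins per-plot mean tree growth (ln kg C yr^-1) with the environmental
#' covariates and any fungal predictors.
#'
#' @param growth per-tree growth table (see [tree_growth_rate()]).
#' @param env environment table.
#' @param fungal optional data.frame of fungal predictors with `plot_id`.
#' @return model frame data.frame, one row per plot with measured trees.
#' @export
build_model_frame <- function(growth, env, fungal = NULL) {
  mg <- tapply(growth$growth_rate, growth$plot_id, mean)
  frame <- env[env$plot_id %in% names(mg), , drop = FALSE]
  frame$mean_growth <- as.vector(mg[frame$plot_id])
  frame$ln_growth <- ifelse(frame$mean_growth > 0, log(frame$mean_growth),
                            NA_real_)
  if (!is.null(fungal)) {
    frame <- merge(frame, fungal, by = "plot_id", all.x = TRUE,
                   sort = FALSE)
  }
  frame[order(frame$plot_id), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Chains the whole analysis: census filtering and per-tree growth,
#' stand-level bootstrap, phylogenetic-signal screening and trait
#' assignment, CWM and exploration-type computation, rarefaction,
#' Bray-Curtis, PCoA, db-RDA, hierarchical clustering with elbow selection,
#' analysis-of-means slow/fast classification (per leaf type by default, on
#' ln stand growth), indicator species analysis, and the additive growth
#' models with and without the fungal community predictor (PCoA axis 1).
#'
#' @param sim simulated study from [simulate_forest()] (or a list with the
#'   same elements read from files).
#' @param depth rarefaction depth (default 115).
#' @param n_boot stand bootstrap replicates (default 1000).
#' @param n_perm permutations for signal screening and indicator analysis
#'   (defaults 1000 / 999; the signal screen's published default is 10000,
#'   reducible for speed).
#' @param alpha significance level (default 0.05).
#' @param k_max maximum clusters examined (default 10).
#' @param per_leaf_type run the ANOM classification within leaf types
#'   (default TRUE) or globally.
#' @param seed master seed for all stochastic stages.
#' @return list of stage outputs plus `report`, a summary with headline
#'   quantities (delta R^2, slow/fast stand growth means and ratio, flagged
#'   categories, selected k, indicator OTU count).
#' @export
run_pipeline <- function(sim, depth = 115, n_boot = 1000, n_perm = 1000,
                         alpha = 0.05, k_max = 10, per_leaf_type = TRUE,
                         seed = 1) {
  ## inventory: filters, per-tree growth, stand bootstrap
  filt <- filter_census(sim$census)
  growth <- tree_growth_rate(filt$retained)
  stand <- stand_growth_all(growth, sim$env, n_reps = n_boot,
                            seed = stage_seed(seed, "bootstrap"))

  ## traits: signal screen, decision-tree assignment, CWM
  cats <- intersect(trait_categories, names(sim$reference))
  signals <- screen_signal(sim$reference, sim$phylogeny, cats,
                           alpha = alpha, n_perm = n_perm,
                           seed = stage_seed(seed, "signal"))
  assignment <- aggregate_organic_n(
    assign_traits(sim$taxonomy, sim$reference, signals, categories = cats))

  ## community: rarefy, relative abundance, ordination, clustering
  rare <- rarefy_table(sim$otu_table, depth = depth,
                       seed = stage_seed(seed, "rarefy"))
  rel <- rare / rowSums(rare)
  alpha_div <- alpha_diversity(rare)
  cwm <- community_weighted_mean(rel, assignment)
  etype <- exploration_type_abundance(rel, sim$taxonomy, sim$reference)
  d <- bray_curtis(rare)
  ord <- pcoa_ordination(d)
  clus <- hierarchical_cluster(d, k_max = k_max)

  plots <- rownames(rare)
  stand_g <- stats::setNames(stand$mean_growth, stand$plot_id)[plots]
  ln_stand <- stats::setNames(log(stand_g), plots)
  leaf <- stats::setNames(sim$env$leaf_type, sim$env$plot_id)[plots]

  classification <- if (per_leaf_type) {
    out <- lapply(split(plots, leaf), function(pp) {
      tryCatch(anom_classify(clus$labels[pp], ln_stand[pp], alpha = alpha),
               error = function(e) NULL)
    })
    out[!vapply(out, is.null, logical(1))]
  } else {
    anom_classify(clus$labels, ln_stand, alpha = alpha)
  }

  indic <- indicator_species(rare, clus$labels[plots],
                             n_perm = min(n_perm, 999),
                             seed = stage_seed(seed, "indicator"))

  ## models: additive growth models with/without the community predictor
  fungal <- data.frame(plot_id = plots,
                       PCoA1 = ord$coordinates[plots, 1],
                       stringsAsFactors = FALSE)
  fungal <- merge(fungal, cwm, by = "plot_id", all.x = TRUE, sort = FALSE)
  frame <- build_model_frame(growth, sim$env, fungal)
  full <- fit_growth_model(frame, fungal = "PCoA1")
  reduced <- fit_growth_model(frame, fungal = NULL)
  dr2 <- delta_r_squared(full, reduced)
  vifs <- vif_report(frame)
  contrast <- compare_growth_classes(stand, classification, clus$labels,
                                     leaf)

  ## pool slow/fast plot-level stand growth across leaf types
  pooled <- {
    pieces <- if (is.data.frame(classification)) {
      list(all = list(cls = classification, plots = plots))
    } else {
      lapply(stats::setNames(nm = names(classification)), function(l)
        list(cls = classification[[l]], plots = plots[leaf == l]))
    }
    slow <- fast <- numeric(0)
    for (pc in pieces) {
      m <- stats::setNames(pc$cls$class, as.character(pc$cls$cluster))
      cl <- m[as.character(clus$labels[pc$plots])]
      slow <- c(slow, stand_g[pc$plots][cl == "slow" & !is.na(cl)])
      fast <- c(fast, stand_g[pc$plots][cl == "fast" & !is.na(cl)])
    }
    list(slow_mean = if (length(slow)) mean(slow) else NA_real_,
         fast_mean = if (length(fast)) mean(fast) else NA_real_,
         n_slow = length(slow), n_fast = length(fast))
  }

  report <- list(
    n_plots = length(plots),
    n_trees_retained = nrow(growth),
    n_trees_rejected = nrow(filt$rejected),
    r2_full = full$r_squared,
    r2_reduced = reduced$r_squared,
    delta_r2 = dr2,
    vif_range = range(vifs),
    flagged_categories = signals$category[signals$flagged],
    k_selected = clus$k,
    slow_mean = pooled$slow_mean,
    fast_mean = pooled$fast_mean,
    n_slow = pooled$n_slow,
    n_fast = pooled$n_fast,
    fast_slow_ratio = pooled$fast_mean / pooled$slow_mean,
    n_indicator_otus = sum(indic$p <= alpha)
  )
  list(filtered = filt, growth = growth, stand = stand, signals = signals,
       assignment = assignment, rarefied = rare, alpha_diversity = alpha_div,
       cwm = cwm, exploration = etype, distance = d, ordination = ord,
       clustering = clus, classification = classification,
       indicators = indic, frame = frame, model_full = full,
       model_reduced = reduced, vif = vifs, contrast = contrast,
       report = report)
}
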