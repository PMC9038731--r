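# Community analyses: rarefaction, alpha diversity, Bray-Curtis, PCoA,
# db-RDA, hierarchical clustering with elbow selection, analysis-of-means
# growth classification, and indicator species analysis.

#' Rarefy an OTU count table to a common depth
#'
#' Each retained plot's counts are a uniform random subsample of its
#' sequences without replacement, totalling exactly `depth`. Plots with
#' fewer than `depth` sequences are dropped with a warning. Rarefaction is
#' done once with a recorded seed, not averaged over draws.
#'
#' @param table plot x OTU matrix of non-negative integer counts with
#'   dimnames.
#' @param depth target depth (default 115 sequences per plot).
#' @param seed integer seed.
#' @return rarefied count matrix.
#' @export
rarefy_table <- function(table, depth = 115, seed = 1) {
  table <- as.matrix(table)
  assert_that(depth >= 1, "depth must be >= 1")
  keep <- rowSums(table) >= depth
  if (!any(keep)) stop_invalid("no plot reaches the rarefaction depth")
  if (any(!keep)) {
    warning(sum(!keep), " plot(s) below depth ", depth, " dropped: ",
            paste(rownames(table)[!keep], collapse = ", "))
  }
  out <- with_seed(seed, vegan::rrarefy(table[keep, , drop = FALSE], depth))
  storage.mode(out) <- "integer"
  out
}

#' Richness and Shannon diversity per plot
#'
#' Richness is the number of OTUs with positive count; Shannon H is
#' -sum p log p over positive relative abundances (natural log). An empty
#' row gets richness 0 and H reported as 0 with a warning.
#'
#' @param table plot x OTU count matrix (normally rarefied).
#' @return data.frame with `plot_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  table <- as.matrix(table)
  empty <- rowSums(table) == 0
  if (any(empty)) warning("empty plot row(s): Shannon reported as 0")
  H <- suppressWarnings(vegan::diversity(table, index = "shannon"))
  H[empty] <- 0
  data.frame(plot_id = rownames(table),
             richness = as.vector(vegan::specnumber(table)),
             shannon = as.vector(H),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(a, b) = 1 - 2 sum_i min(a_i, b_i) / sum_i (a_i + b_i). Accepts counts
#' or relative abundances; on rarefied tables (equal row sums) the two give
#' identical results.
#'
#' @param abund plot x OTU abundance matrix.
#' @return symmetric plot x plot matrix with zero diagonal, values in
#'   [0, 1].
#' @export
bray_curtis <- function(abund) {
  abund <- as.matrix(abund)
  assert_that(all(abund >= 0), "abundances must be non-negative")
  as.matrix(vegan::vegdist(abund, method = "bray"))
}

#' Principal coordinates analysis
#'
#' Eigen-decomposition of the double-centred squared dissimilarity matrix
#' -1/2 J D^2 J. Coordinates are returned for positive eigenvalues, scaled
#' by their square roots; negative eigenvalues (Bray-Curtis is a semimetric)
#' are reported but excluded from coordinates, with no Cailliez/Lingoes
#' correction. Axis signs are fixed by making each axis's largest-magnitude
#' score positive.
#'
#' @param d symmetric dissimilarity matrix (zero diagonal, n >= 3).
#' @return list with `coordinates` (plot x axis matrix), `eigenvalues`
#'   (all, non-increasing), `proportion_explained` (relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  assert_that(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
              "dissimilarity matrix must be symmetric")
  n <- nrow(d)
  assert_that(n >= 3, "need at least 3 plots")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  dimnames(coords) <- list(rownames(d), paste0("PCoA", seq_len(ncol(coords))))
  list(coordinates = coords,
       eigenvalues = e$values,
       proportion_explained = e$values[pos] / sum(e$values[pos]))
}

#' Distance-based redundancy analysis
#'
#' PCoA coordinates on positive eigenvalues are regressed on the centred
#' explanatory matrix; the eigen-decomposition of the fitted values gives
#' the constrained axes. Reports constrained and residual variance shares
#' and explanatory-variable scores (correlations with constrained axes).
#'
#' @param d dissimilarity matrix.
#' @param explanatory data.frame of explanatory variables, rows aligned with
#'   `d` (factors are expanded to indicators). May have zero columns, giving
#'   the intercept-only model with constrained variance 0.
#' @return list with `constrained_variance`, `residual_variance`,
#'   `total_variance`, `proportion_constrained`, `eigenvalues` (constrained),
#'   `site_scores`, `variable_scores`.
#' @export
db_rda <- function(d, explanatory) {
  ord <- pcoa_ordination(d)
  Y <- ord$coordinates
  total <- sum(Y^2)
  if (is.null(explanatory) || ncol(as.data.frame(explanatory)) == 0) {
    return(list(constrained_variance = 0, residual_variance = total,
                total_variance = total, proportion_constrained = 0,
                eigenvalues = numeric(0), site_scores = NULL,
                variable_scores = NULL))
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(explanatory))[, -1,
                                                                   drop = FALSE]
  assert_that(nrow(X) == nrow(Y), "explanatory rows must match plots")
  assert_that(nrow(X) > ncol(X), "more variables than plots")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  q <- qr(Xc)
  if (q$rank < ncol(Xc)) {
    stop_invalid("collinear explanatory variables: ",
                 paste(colnames(Xc)[-seq_len(q$rank)], collapse = ", "))
  }
  fitted <- qr.fitted(q, Y)
  e <- eigen(crossprod(fitted), symmetric = TRUE)
  pos <- e$values > max(total * 1e-12, 0)
  axes <- fitted %*% e$vectors[, pos, drop = FALSE]
  constrained <- sum(fitted^2)
  vs <- if (any(pos)) {
    suppressWarnings(stats::cor(Xc, axes))
  } else NULL
  list(constrained_variance = constrained,
       residual_variance = total - constrained,
       total_variance = total,
       proportion_constrained = constrained / total,
       eigenvalues = e$values[pos],
       site_scores = axes,
       variable_scores = vs)
}

# Within-cluster sum of squared dissimilarities for a label vector:
# sum over clusters of sum_{i<j} d^2(i,j)/n_cluster.
cluster_wss <- function(d, labels) {
  sum(vapply(split(seq_along(labels), labels), function(i) {
    if (length(i) < 2) return(0)
    sum(d[i, i]^2) / 2 / length(i)
  }, numeric(1)))
}

#' Hierarchical clustering with elbow selection
#'
#' Complete-linkage agglomerative clustering of the dissimilarity matrix.
#' The within-cluster sum of squared dissimilarities (WSS) is computed for
#' k = 1..k_max and k is chosen where the curve bends most: the k in
#' 2..(k_max - 1) maximizing the second difference
#' WSS(k-1) - 2 WSS(k) + WSS(k+1). Degenerate inputs (all WSS ~ 0) default
#' to k = 2 with a warning.
#'
#' @param d dissimilarity matrix.
#' @param k_max largest number of clusters examined (default 10).
#' @return list with `labels` (named integer vector), `k`, `wss_curve`,
#'   `hclust` (the dendrogram object).
#' @export
hierarchical_cluster <- function(d, k_max = 10) {
  d <- as.matrix(d)
  n <- nrow(d)
  assert_that(n >= 3, "need at least 3 plots")
  k_max <- min(k_max, n - 1)
  assert_that(k_max >= 2, "k_max must be >= 2")
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cuts <- stats::cutree(hc, k = 1:k_max)
  wss <- vapply(1:k_max, function(k) cluster_wss(d, cuts[, k]), numeric(1))
  if (max(wss) <= 1e-12) {
    warning("all points identical: defaulting to k = 2")
    k <- 2
  } else if (k_max < 3) {
    k <- 2
  } else {
    ks <- 2:(k_max - 1)
    curv <- wss[ks - 1] - 2 * wss[ks] + wss[ks + 1]
    k <- ks[which.max(curv)]
  }
  labels <- cuts[, k]
  names(labels) <- rownames(d)
  list(labels = labels, k = k,
       wss_curve = stats::setNames(wss, 1:k_max), hclust = hc)
}

#' Classify clusters as slow, fast, or neutral by analysis of means
#'
#' Compares each cluster's mean growth to the grand mean with ANOM decision
#' limits: cluster i is `fast` when its mean exceeds
#' ybar + h s sqrt((N - n_i)/(N n_i)), `slow` below the mirror limit, else
#' `neutral`. s is the pooled within-cluster standard deviation and h the
#' Bonferroni-adjusted two-sided t quantile t(1 - alpha/(2g), N - g) for g
#' clusters.
#'
#' @param labels named vector mapping plot id to cluster.
#' @param growth named vector mapping plot id to stand (or mean tree)
#'   growth.
#' @param alpha significance level (default 0.05).
#' @return data.frame with `cluster`, `n`, `mean_growth`, `lower`, `upper`
#'   (decision limits), `class`.
#' @export
anom_classify <- function(labels, growth, alpha = 0.05) {
  plots <- intersect(names(labels), names(growth))
  plots <- plots[is.finite(growth[plots])]
  lab <- labels[plots]
  y <- growth[plots]
  groups <- split(y, lab)
  assert_that(length(groups) >= 2, "need at least 2 clusters")
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop_invalid("singleton cluster(s): ",
                 paste(names(groups)[sizes < 2], collapse = ", "))
  }
  N <- length(y)
  g <- length(groups)
  ybar <- mean(y)
  s2 <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) /
    (N - g)
  s <- sqrt(s2)
  h <- stats::qt(1 - alpha / (2 * g), df = N - g)
  means <- vapply(groups, mean, numeric(1))
  half <- h * s * sqrt((N - sizes) / (N * sizes))
  cls <- ifelse(means > ybar + half, "fast",
                ifelse(means < ybar - half, "slow", "neutral"))
  data.frame(cluster = names(groups), n = as.integer(sizes),
             mean_growth = unname(means),
             lower = unname(ybar - half), upper = unname(ybar + half),
             class = unname(cls), row.names = NULL,
             stringsAsFactors = FALSE)
}

# IndVal association statistic for every OTU against a group factor:
# specificity A_g = (m_g/n_g) / sum_h (m_h/n_h) with m_g the OTU's total
# abundance in group g; fidelity B_g = occurrence fraction in group g;
# stat = max_g sqrt(A_g B_g). Returns per-OTU stat and best group.
indval_stat <- function(table, groups) {
  gf <- factor(groups)
  ng <- as.vector(table(gf))
  msum <- rowsum(table, gf)                    # group totals per OTU
  occ <- rowsum((table > 0) * 1, gf)           # occurrences per group
  meang <- msum / ng
  A <- sweep(meang, 2, colSums(meang), "/")
  A[, colSums(meang) == 0] <- 0
  B <- occ / ng
  iv <- sqrt(A * B)
  best <- apply(iv, 2, which.max)
  list(stat = iv[cbind(best, seq_len(ncol(iv)))],
       group = levels(gf)[best])
}

#' Indicator species analysis with permutation test
#'
#' For each OTU the indicator value is sqrt(A B) for its best-associated
#' group, where A (specificity) is the group-equalized share of the OTU's
#' mean abundance and B (fidelity) its occurrence fraction in the group.
#' Significance comes from permuting group labels across plots: p is the
#' share of (n_perm + 1) statistics (observed included) at least as large
#' as the observed one.
#'
#' @param table plot x OTU abundance matrix.
#' @param groups vector of group labels, one per plot (>= 2 groups with
#'   >= 2 plots each).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return data.frame with `otu`, `group`, `stat`, `p`.
#' @export
indicator_species <- function(table, groups, n_perm = 999, seed = 1) {
  table <- as.matrix(table)
  gf <- factor(groups)
  assert_that(nlevels(gf) >= 2, "need >= 2 groups")
  assert_that(all(table(gf) >= 2), "every group needs >= 2 plots")
  obs <- indval_stat(table, gf)
  count <- rep(1, ncol(table))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- indval_stat(table, gf[sample.int(length(gf))])
      count <- count + (perm$stat >= obs$stat - 1e-12)
    }
  })
  data.frame(otu = colnames(table), group = obs$group, stat = obs$stat,
             p = count / (n_perm + 1), row.names = NULL,
             stringsAsFactors = FALSE)
}
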