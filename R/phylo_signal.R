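# Phylogenetic signal statistics for gene-count traits on the reference
# species tree: Blomberg's K with a tip-permutation test and Pagel's lambda
# by profile likelihood, plus the screening wrapper that gates genus-level
# trait imputation.

# Phylogenetic covariance matrix restricted to the named trait vector, with
# tips in trait order. C[i, j] is the shared root-to-MRCA path length.
phylo_vcv <- function(phylo, trait) {
  assert_that(!is.null(names(trait)), "trait vector must be named by tip")
  tips <- intersect(phylo$tip.label, names(trait))
  assert_that(length(tips) >= 4, "need >= 4 tips with trait values")
  C <- ape::vcv(ape::keep.tip(phylo, tips))
  C[tips, tips, drop = FALSE]
}

# Blomberg variance ratio (MSE0/MSE in the original notation) for each column
# of a tip-values matrix X, given C^-1. Vectorized over columns for the
# permutation test.
blomberg_ratio <- function(X, Cinv) {
  n <- nrow(X)
  w <- Cinv %*% rep(1, n)
  sw <- sum(w)
  A <- Cinv %*% X
  ahat <- colSums(w[, 1] * X) / sw
  num <- colSums(X^2) - 2 * ahat * colSums(X) + n * ahat^2
  den <- colSums(X * A) - 2 * ahat * colSums(A) + ahat^2 * sw
  num / den
}

#' Blomberg's K with permutation test
#'
#' K compares the observed ratio of trait variance to phylogenetically
#' corrected variance against its Brownian-motion expectation on the same
#' tree; K near 1 indicates Brownian-like signal, K near 0 none. With
#' phylogenetic GLS mean a = (1'C^-1 x)/(1'C^-1 1), the observed ratio is
#' (x-a)'(x-a) / (x-a)'C^-1(x-a) and the expectation is
#' (tr C - n/(1'C^-1 1))/(n-1). Significance comes from random tip-label
#' permutations: p is the share of permuted ratios (observed included) at
#' least as large as the real one.
#'
#' @param phylo rooted `phylo` tree with branch lengths.
#' @param trait named numeric vector (names are tip labels, >= 4 tips).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `K`, `p`, `n`.
#' @export
blomberg_k <- function(phylo, trait, n_perm = 1000, seed = 1) {
  C <- phylo_vcv(phylo, trait)
  x <- trait[rownames(C)]
  assert_that(stats::var(x) > 0, "trait is constant across tips")
  n <- length(x)
  Cinv <- solve(C)
  obs <- blomberg_ratio(matrix(x, ncol = 1), Cinv)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  K <- unname(obs / expected)
  p <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(seed, {
      Xp <- vapply(seq_len(n_perm), function(i) x[sample.int(n)],
                   numeric(n))
      blomberg_ratio(Xp, Cinv)
    })
    p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  }
  list(K = K, p = p, n = n)
}

# Profile log-likelihood of a trait under the lambda model: the off-diagonal
# of C is scaled by lambda, the GLS mean and sigma^2 are profiled out
# analytically.
lambda_loglik <- function(lambda, x, C) {
  n <- length(x)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Cinv_x <- backsolve(ch, forwardsolve(t(ch), x))
  Cinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a <- sum(Cinv_x) / sum(Cinv_1)
  r <- x - a
  Cinv_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Cinv_r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda by profile maximum likelihood
#'
#' lambda scales the off-diagonal entries of the phylogenetic covariance:
#' lambda = 1 recovers Brownian motion, lambda = 0 a star phylogeny
#' (phylogenetically independent tips). The GLS mean and rate sigma^2 are
#' profiled analytically at each lambda; lambda is maximized over [0, 1] by
#' bounded one-dimensional search (tolerance 1e-6). The p-value is a
#' likelihood-ratio test against lambda = 0 on a chi-squared(1) reference.
#'
#' @inheritParams blomberg_k
#' @return list with `lambda`, `logL`, `logL0`, `p`, `n`.
#' @export
pagel_lambda <- function(phylo, trait) {
  C <- phylo_vcv(phylo, trait)
  x <- trait[rownames(C)]
  assert_that(stats::var(x) > 0, "trait is constant across tips")
  if (all(abs(C[upper.tri(C)]) < 1e-12)) {
    warning("star tree: lambda is unidentifiable, reporting 0")
    ll0 <- lambda_loglik(0, x, C)
    return(list(lambda = 0, logL = ll0, logL0 = ll0, p = 1,
                n = length(x)))
  }
  opt <- stats::optimize(lambda_loglik, c(0, 1), x = x, C = C,
                         maximum = TRUE, tol = 1e-6)
  # the optimum can sit on a boundary the golden-section search skirts
  cand <- c(0, opt$maximum, 1)
  ll <- vapply(cand, lambda_loglik, numeric(1), x = x, C = C)
  best <- which.max(ll)
  lam <- cand[best]
  logL <- ll[best]
  logL0 <- ll[1]
  lr <- max(0, 2 * (logL - logL0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  list(lambda = lam, logL = logL, logL0 = logL0, p = min(p, 1),
       n = length(x))
}

#' Screen trait categories for phylogenetic signal
#'
#' Runs Blomberg's K (with permutation test) and Pagel's lambda (with a
#' likelihood-ratio test) on the per-species gene numbers of every category
#' in the reference table. A category is flagged as carrying signal when
#' either test is significant at `alpha`; flagged categories qualify for
#' genus-level trait imputation.
#'
#' @param reference reference genome table (see [simulate_reference_traits()]
#'   for the expected columns: `species`, category count columns).
#' @param phylo species tree whose tip labels match `reference$species`.
#' @param categories character vector of category column names.
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations for the K test (default 10000).
#' @param seed integer seed.
#' @return data.frame with one row per category: `K`, `p_K`, `lambda`,
#'   `p_lambda`, `flagged`.
#' @export
screen_signal <- function(reference, phylo, categories, alpha = 0.05,
                          n_perm = 10000, seed = 1) {
  missing_cat <- setdiff(categories, names(reference))
  assert_that(length(missing_cat) == 0,
              "categories not in reference table: ",
              paste(missing_cat, collapse = ", "))
  shared <- intersect(phylo$tip.label, reference$species)
  assert_that(length(shared) >= 4,
              "need >= 4 species shared between reference table and tree")
  out <- lapply(seq_along(categories), function(i) {
    cat_i <- categories[i]
    x <- stats::setNames(reference[[cat_i]], reference$species)[shared]
    k <- blomberg_k(phylo, x, n_perm = n_perm,
                    seed = stage_seed(seed + i, "blomberg_perm"))
    l <- pagel_lambda(phylo, x)
    data.frame(category = cat_i, K = k$K, p_K = k$p, lambda = l$lambda,
               p_lambda = l$p,
               flagged = isTRUE(k$p <= alpha) | isTRUE(l$p <= alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
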