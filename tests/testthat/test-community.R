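# Rarefaction, diversity, ordination, clustering, ANOM, indicator species.

test_that("rarefaction conserves depth, subsampling, and determinism", {
  set.seed(1)
  tab <- matrix(rpois(8 * 30, 10), 8, 30,
                dimnames = list(paste0("p", 1:8), paste0("o", 1:30)))
  r <- rarefy_table(tab, depth = 100, seed = 3)
  expect_true(all(rowSums(r) == 100))
  expect_true(all(r <= tab))
  expect_identical(r, rarefy_table(tab, depth = 100, seed = 3))
  # shallow plots dropped with a warning
  tab[1, ] <- 0; tab[1, 1] <- 5
  expect_warning(r2 <- rarefy_table(tab, depth = 100, seed = 3), "dropped")
  expect_false("p1" %in% rownames(r2))
  expect_error(rarefy_table(tab * 0, depth = 10, seed = 1), "no plot")
})

test_that("alpha diversity matches closed forms and column-order invariance", {
  tab <- rbind(p1 = c(5, 5, 5, 5), p2 = c(9, 0, 0, 0))
  colnames(tab) <- paste0("o", 1:4)
  a <- alpha_diversity(tab)
  expect_equal(a$richness, c(4, 1))
  expect_equal(a$shannon, c(log(4), 0))
  perm <- tab[, c(3, 1, 4, 2)]
  expect_equal(alpha_diversity(perm)[-1], a[-1])
})

test_that("Bray-Curtis matches its formula on hand cases", {
  x <- rbind(a = c(2, 1, 0), b = c(0, 1, 3), c = c(2, 1, 0),
             d = c(0, 0, 7))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 5 / 7, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0) && all(d >= 0 & d <= 1))
})

test_that("PCoA reconstructs Euclidean-embeddable distances", {
  set.seed(2)
  X <- matrix(rnorm(36), 12, 3)
  D <- as.matrix(dist(X))
  ord <- pcoa_ordination(D)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - D)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
  # sign convention: largest |score| on each axis is positive
  for (j in seq_len(ncol(ord$coordinates))) {
    expect_gt(ord$coordinates[which.max(abs(ord$coordinates[, j])), j], 0)
  }
})

test_that("three equidistant points give two equal positive eigenvalues", {
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(letters[1:3], letters[1:3])
  ord <- pcoa_ordination(D)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-10]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
})

test_that("db-RDA satisfies the projection identities", {
  set.seed(3)
  X <- matrix(rnorm(45), 15, 3)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:15), paste0("p", 1:15))
  # intercept-only: nothing constrained
  expect_equal(db_rda(D, data.frame(row.names = 1:15))$constrained_variance,
               0)
  # the PCoA coordinates themselves explain everything
  ord <- pcoa_ordination(D)
  full <- db_rda(D, as.data.frame(ord$coordinates))
  expect_equal(full$proportion_constrained, 1, tolerance = 1e-8)
  # a random predictor explains part of it
  part <- db_rda(D, data.frame(v = rnorm(15)))
  expect_lte(part$constrained_variance, part$total_variance + 1e-12)
  expect_gte(part$constrained_variance, 0)
  # collinear explanatory matrix is rejected
  bad <- data.frame(v1 = X[, 1], v2 = 2 * X[, 1])
  expect_error(db_rda(D, bad), "collinear")
})

test_that("ordination agrees with independent implementations", {
  set.seed(11)
  tab <- matrix(rpois(12 * 25, 6), 12, 25,
                dimnames = list(paste0("p", 1:12), paste0("o", 1:25)))
  D <- bray_curtis(tab)
  ord <- pcoa_ordination(D)
  ref <- ape::pcoa(as.dist(D))
  npos <- ncol(ord$coordinates)
  expect_equal(ord$eigenvalues[seq_len(npos)],
               ref$values$Eigenvalues[seq_len(npos)], tolerance = 1e-8)
  expect_equal(abs(ord$coordinates[, 1]), abs(ref$vectors[, 1]),
               ignore_attr = TRUE, tolerance = 1e-8)
  ex <- data.frame(v1 = rnorm(12), v2 = rnorm(12))
  ours <- db_rda(D, ex)
  theirs <- vegan::dbrda(D ~ v1 + v2, data = ex)
  expect_equal(ours$proportion_constrained,
               unname(theirs$CCA$tot.chi /
                        (theirs$CCA$tot.chi + theirs$CA$tot.chi)),
               tolerance = 0.02)
})

test_that("clustering finds two planted blobs and selects k = 2", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(20, 0, 0.2), 10), matrix(rnorm(20, 5, 0.2), 10))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("p", 1:20), paste0("p", 1:20))
  cl <- hierarchical_cluster(D, k_max = 8)
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$labels[1:10])), 1)
  expect_equal(length(unique(cl$labels[11:20])), 1)
  expect_false(cl$labels[1] == cl$labels[11])
  # wss non-increasing in k
  expect_true(all(diff(cl$wss_curve) <= 1e-9))
  # permutation invariance up to label renaming
  perm <- sample(20)
  cl2 <- hierarchical_cluster(D[perm, perm], k_max = 8)
  expect_equal(unname(cl2$labels[paste0("p", 1:20)] ==
                        cl2$labels[paste0("p", 1)]),
               unname(cl$labels == cl$labels[1]))
  # degenerate input
  D0 <- matrix(0, 5, 5); dimnames(D0) <- list(letters[1:5], letters[1:5])
  expect_warning(cl0 <- hierarchical_cluster(D0, k_max = 4), "identical")
  expect_equal(cl0$k, 2)
})

test_that("analysis of means classifies against explicit decision limits", {
  labels <- setNames(rep(c("1", "2", "3"), each = 6), paste0("p", 1:18))
  set.seed(5)
  base <- rnorm(18, 0, 1)
  # all means equal: everything neutral
  g0 <- setNames(base - ave(base, labels), names(labels))
  expect_true(all(anom_classify(labels, g0)$class == "neutral"))
  # one cluster shifted by +10 pooled sd: fast at the stated h
  g1 <- g0; g1[labels == "2"] <- g1[labels == "2"] + 10 * sd(g0)
  cls <- anom_classify(labels, g1)
  expect_equal(cls$class[cls$cluster == "2"], "fast")
  # location invariance
  expect_equal(anom_classify(labels, g1 + 100)$class, cls$class)
  # hand-check the limit: h = qt(1 - alpha/(2g), N - g)
  N <- 18; g <- 3; n_i <- 6
  s <- sqrt(sum(tapply(g1, labels, function(v) sum((v - mean(v))^2))) /
              (N - g))
  half <- qt(1 - 0.05 / (2 * g), N - g) * s * sqrt((N - n_i) / (N * n_i))
  expect_equal(cls$upper[1] - mean(g1), half, tolerance = 1e-12)
  # singleton cluster refused
  expect_error(anom_classify(labels[c(1, 7, 8, 13, 14)],
                             g1[c(1, 7, 8, 13, 14)]), "singleton")
})

test_that("indicator statistic matches its formula and brute force", {
  groups <- rep(c("A", "B"), each = 10)
  tab <- matrix(0, 20, 3, dimnames = list(paste0("p", 1:20),
                                          c("perfect", "even", "noise")))
  tab[1:10, "perfect"] <- 5                     # only and always in A
  tab[, "even"] <- 2                            # identical everywhere
  set.seed(6); tab[, "noise"] <- rpois(20, 3)
  res <- indicator_species(tab, groups, n_perm = 99, seed = 2)
  expect_equal(res$stat[res$otu == "perfect"], 1)
  expect_equal(res$p[res$otu == "perfect"], 1 / 100)
  expect_equal(res$stat[res$otu == "even"], sqrt(0.5), tolerance = 1e-12)
  # brute force on random tables
  set.seed(7)
  groups2 <- rep(c("A", "B"), each = 4)
  for (rep in 1:20) {
    m <- matrix(rpois(8 * 5, 3), 8, 5,
                dimnames = list(paste0("p", 1:8), paste0("o", 1:5)))
    got <- indicator_species(m, groups2, n_perm = 0, seed = 1)
    for (j in 1:5) {
      best <- -Inf
      for (gr in c("A", "B")) {
        sel <- groups2 == gr
        mg <- mean(m[sel, j]); mo <- mean(m[!sel, j])
        A <- if (mg + mo > 0) mg / (mg + mo) else 0
        B <- mean(m[sel, j] > 0)
        best <- max(best, sqrt(A * B))
      }
      expect_equal(got$stat[j], best, tolerance = 1e-12)
    }
  }
})
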