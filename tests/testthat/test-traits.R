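# Decision-tree trait assignment, organic-N aggregation, CWM, exploration
# types.

make_ref <- function() {
  data.frame(
    species = c("Amanita muscaria", "Amanita rubescens", "Boletus edulis",
                "Boletus badius"),
    genus = c("Amanita", "Amanita", "Boletus", "Boletus"),
    total_gene_models = c(10000, 20000, 10000, 10000),
    exploration_type = c("medium-distance fringe", "medium-distance fringe",
                         "long-distance", "contact"),
    peptidases = c(200, 800, 100, 300),
    proteases = c(100, 200, 50, 50),
    multicopper_oxidases = c(30, 60, 30, 10),
    peroxidases = c(20, 40, 20, 10),
    stringsAsFactors = FALSE
  )
}

make_signals <- function(flag_pept = TRUE) {
  data.frame(
    category = c("peptidases", "proteases", "multicopper_oxidases",
                 "peroxidases"),
    K = 1, p_K = ifelse(c(flag_pept, TRUE, TRUE, FALSE), 0.01, 0.5),
    lambda = 1, p_lambda = ifelse(c(flag_pept, TRUE, TRUE, FALSE), 0.01, 0.5),
    flagged = c(flag_pept, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

cats4 <- c("peptidases", "proteases", "multicopper_oxidases", "peroxidases")

test_that("the decision tree assigns species matches, genus means, unassigned", {
  tax <- data.frame(
    otu_id = c("o1", "o2", "o3", "o4"),
    genus = c("Amanita", "Amanita", "Russula", NA),
    species = c("Amanita muscaria", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  a <- assign_traits(tax, make_ref(), make_signals(), categories = cats4)
  expect_equal(a$level, c("species_match", "genus_mean", "unassigned",
                          "unassigned"))
  # species match: exact genome proportions
  expect_equal(a$peptidases[1], 200 / 10000)
  expect_equal(a$total_gene_models[1], 10000)
  # genus mean: unweighted mean of the two Amanita proportions
  expect_equal(a$peptidases[2], mean(c(200 / 10000, 800 / 20000)))
  expect_equal(a$total_gene_models[2], 15000)
  # unflagged category not imputed at genus level
  expect_true(is.na(a$peroxidases[2]))
  # unassigned rows carry no values
  expect_true(all(is.na(a$peptidases[3:4])))
  # every OTU exactly once, and idempotent under reordering
  expect_equal(a$otu_id, tax$otu_id)
  a2 <- assign_traits(tax[4:1, ], make_ref(), make_signals(),
                      categories = cats4)
  expect_equal(a2$level, rev(a$level))
})

test_that("direct species matches are not gated by the signal screen", {
  tax <- data.frame(otu_id = "o1", genus = "Boletus",
                    species = "Boletus edulis", stringsAsFactors = FALSE)
  a <- assign_traits(tax, make_ref(), make_signals(), categories = cats4)
  expect_equal(a$peroxidases, 20 / 10000)  # peroxidases unflagged
})

test_that("name matching folds case, whitespace and underscores", {
  tax <- data.frame(otu_id = "o1", genus = "amanita",
                    species = "AMANITA_muscaria", stringsAsFactors = FALSE)
  a <- assign_traits(tax, make_ref(), make_signals(), categories = cats4)
  expect_equal(a$level, "species_match")
})

test_that("organic-N aggregation equals the count-level sum", {
  tax <- data.frame(otu_id = c("o1", "o2"), genus = c("Amanita", "Boletus"),
                    species = c("Amanita rubescens", "Boletus badius"),
                    stringsAsFactors = FALSE)
  a <- aggregate_organic_n(
    assign_traits(tax, make_ref(), make_signals(), categories = cats4))
  expect_equal(a$organic_N_cycling[1], (800 + 200 + 60 + 40) / 20000,
               tolerance = 1e-12)
  expect_equal(a$organic_N_cycling[2], (300 + 50 + 10 + 10) / 10000,
               tolerance = 1e-12)
  expect_error(aggregate_organic_n(a[, -4]), "missing constituent")
})

test_that("CWM matches identity, hand arithmetic, and scale invariance", {
  assn <- data.frame(otu_id = c("o1", "o2", "o3"),
                     level = c("species_match", "species_match",
                               "unassigned"),
                     total_gene_models = c(1, 1, NA),
                     trait = c(0.10, 0.20, NA), stringsAsFactors = FALSE)
  # single assigned OTU: identity
  m1 <- matrix(c(0.6, 0, 0.4), 1, dimnames = list("p1", c("o1", "o2", "o3")))
  cw <- community_weighted_mean(m1, assn, traits = "trait")
  expect_equal(cw$trait, 0.10)
  expect_equal(cw$coverage, 0.6)
  # renormalized weights 0.25/0.75 over assigned OTUs
  m2 <- matrix(c(0.2, 0.6, 0.2), 1, dimnames = list("p1", c("o1", "o2", "o3")))
  expect_equal(community_weighted_mean(m2, assn, traits = "trait")$trait,
               0.25 * 0.10 + 0.75 * 0.20)
  # scale invariance: counts x10 give identical relative abundances
  counts <- matrix(c(2, 6, 2), 1, dimnames = list("p1", c("o1", "o2", "o3")))
  r1 <- counts / sum(counts); r2 <- (counts * 10) / sum(counts * 10)
  expect_equal(community_weighted_mean(r1, assn, traits = "trait"),
               community_weighted_mean(r2, assn, traits = "trait"))
  expect_error(community_weighted_mean(m2 * 2, assn, traits = "trait"),
               "sum to 1")
})

test_that("CWM equals the brute-force double loop on random instances", {
  set.seed(42)
  for (rep in 1:100) {
    n_otu <- sample(4:12, 1); n_plot <- sample(2:6, 1)
    counts <- matrix(rpois(n_plot * n_otu, 8) + 1, n_plot, n_otu,
                     dimnames = list(paste0("p", 1:n_plot),
                                     paste0("o", 1:n_otu)))
    rel <- counts / rowSums(counts)
    tr <- runif(n_otu); tr[sample(n_otu, sample(0:(n_otu - 2), 1))] <- NA
    assn <- data.frame(otu_id = colnames(counts),
                       level = ifelse(is.na(tr), "unassigned",
                                      "species_match"),
                       trait = tr, stringsAsFactors = FALSE)
    got <- community_weighted_mean(rel, assn, traits = "trait")
    for (p in 1:n_plot) {
      num <- den <- 0
      for (o in 1:n_otu) {
        if (!is.na(tr[o])) {
          num <- num + rel[p, o] * tr[o]
          den <- den + rel[p, o]
        }
      }
      expect_equal(got$trait[p], num / den, tolerance = 1e-12)
      # bounded by contributing extrema
      expect_gte(got$trait[p], min(tr, na.rm = TRUE) - 1e-12)
      expect_lte(got$trait[p], max(tr, na.rm = TRUE) + 1e-12)
    }
  }
})

test_that("exploration-type abundances renormalize over typed OTUs", {
  tax <- data.frame(otu_id = c("o1", "o2", "o3"),
                    genus = c("Boletus", "Boletus", NA),
                    species = c("Boletus badius", "Boletus edulis", NA),
                    stringsAsFactors = FALSE)
  m <- matrix(c(0.3, 0.3, 0.4), 1, dimnames = list("p1", tax$otu_id))
  et <- exploration_type_abundance(m, tax, make_ref())
  expect_equal(et$contact, 0.5)
  expect_equal(et$`long-distance`, 0.5)
  expect_equal(sum(et[, exploration_types]), 1)
  # removing the untyped OTU leaves the result unchanged
  m2 <- m[, 1:2, drop = FALSE] / sum(m[, 1:2])
  et2 <- exploration_type_abundance(m2, tax[1:2, ], make_ref())
  expect_equal(et2$contact, et$contact)
  # all typed OTUs one type
  m3 <- matrix(1, 1, dimnames = list("p1", "o1"))
  et3 <- exploration_type_abundance(m3, tax[1, ], make_ref())
  expect_equal(et3$contact, 1)
  expect_equal(et3$`long-distance`, 0)
})
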