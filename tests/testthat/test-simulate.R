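# The synthetic study generator: determinism, config contracts, injected
# invalid records, allometric round trip, and distributional structure.

test_that("config validation catches bad proportions and category names", {
  expect_error(sim_config(frac_dead = 1.2), "proportions")
  expect_error(sim_config(n_ref_species = 3), "at least 4")
  expect_error(sim_config(depth_range = c(300, 100)), "increasing")
  expect_error(sim_config(signal_categories = "not_a_category"), "unknown")
  expect_error(sim_config(signal_categories = c("peptidases"),
                          noise_categories = c("peptidases")), "disjoint")
})

test_that("simulated phylogenies are rooted, ultrametric, unit height, reproducible", {
  tr <- simulate_phylogeny(8, seed = 1)
  expect_equal(length(tr$tip.label), 8)
  expect_true(ape::is.rooted(tr))
  depths <- ape::node.depth.edgelength(tr)[1:8]
  expect_equal(depths, rep(1, 8), tolerance = 1e-10)
  expect_true(all(tr$edge.length > 0))
  # a 2-tip tree is a single cherry
  tr2 <- simulate_phylogeny(2, seed = 7)
  expect_equal(ape::Ntip(tr2), 2)
  C <- ape::vcv(tr2)
  expect_equal(C[1, 1], 1, tolerance = 1e-10)
  # byte-identical serialization under the same seed
  expect_identical(ape::write.tree(simulate_phylogeny(50, seed = 3)),
                   ape::write.tree(simulate_phylogeny(50, seed = 3)))
  expect_error(simulate_phylogeny(1), "at least 2")
})

test_that("reference genomes conserve counts and carry genus/type labels", {
  tr <- simulate_phylogeny(30, seed = 2)
  cfg <- sim_config(n_ref_species = 30)
  out <- simulate_reference_traits(tr, cfg, seed = 5)
  ref <- out$reference
  cats <- c(cfg$signal_categories, cfg$noise_categories)
  expect_true(all(rowSums(ref[cats]) <= ref$total_gene_models))
  expect_true(all(ref$total_gene_models > 0))
  expect_true(all(table(ref$genus) >= 2))
  expect_true(all(ref$exploration_type %in% exploration_types))
  expect_equal(out$signal_flags[cfg$signal_categories],
               setNames(rep(TRUE, length(cfg$signal_categories)),
                        cfg$signal_categories))
  expect_identical(simulate_reference_traits(tr, cfg, seed = 5)$reference,
                   ref)
})

test_that("OTU tables respect depth range and deterministic taxonomy fractions", {
  cfg <- sim_config(n_plots = 20, n_otus = 100, n_ref_species = 20)
  tr <- simulate_phylogeny(20, seed = 3)
  ref <- simulate_reference_traits(tr, cfg, seed = 1)$reference
  out <- simulate_otu_table(cfg, ref, seed = 9)
  depths <- rowSums(out$otu_table)
  expect_true(all(depths >= cfg$depth_range[1] &
                    depths <= cfg$depth_range[2]))
  # 41% of 100 OTUs genus-unassigned, half of the 59 assigned are species
  # matches (floor rule)
  expect_equal(sum(is.na(out$taxonomy$genus)), 41)
  expect_equal(sum(!is.na(out$taxonomy$species)), 29)
  expect_equal(mean(out$latent_axis), 0, tolerance = 1e-12)
  expect_identical(simulate_otu_table(cfg, ref, seed = 9)$otu_table,
                   out$otu_table)
})

test_that("plots with no community gradient show no axis-ordination link", {
  cfg <- sim_config(n_plots = 24, n_otus = 60, n_ref_species = 12,
                    gradient_sd = 0)
  tr <- simulate_phylogeny(12, seed = 4)
  ref <- simulate_reference_traits(tr, cfg, seed = 1)$reference
  rs <- vapply(1:20, function(i) {
    out <- simulate_otu_table(cfg, ref, seed = 100 + i)
    rare <- rarefy_table(out$otu_table, depth = 115, seed = i)
    ord <- pcoa_ordination(bray_curtis(rare))
    abs(cor(ord$coordinates[, 1], out$latent_axis[rownames(rare)]))
  }, numeric(1))
  expect_lt(median(rs), 0.3)
})

test_that("environment tables satisfy the independence screen and label rules", {
  cfg <- sim_config(n_plots = 40)
  env <- simulate_plot_environment(cfg, seed = 6)
  num <- c("MAT", "MAP", "N_deposition", "soil_pH", "inorganic_N",
           "stand_age_class", "stem_density")
  r <- cor(env[num])
  expect_lt(max(abs(r[upper.tri(r)])), 0.71)
  expect_true(all(env$dominant_species[env$leaf_type == "broadleaf"] %in%
                    c("european_beech", "mixed_oak")))
  expect_true(all(env$dominant_species[env$leaf_type == "needleleaf"] %in%
                    c("scots_pine", "norway_spruce")))
  expect_identical(simulate_plot_environment(cfg, seed = 6), env)
})

test_that("invalid tree records are injected at the configured deterministic counts", {
  cfg <- small_config(frac_dead = 0.1, frac_shrinking = 0.1,
                      frac_sub5cm = 0.1)
  sim <- simulate_forest(cfg, seed = 8)
  n_total <- cfg$n_plots * cfg$n_trees_per_plot
  expect_equal(sum(sim$census$status == "dead"), floor(0.1 * n_total))
  alive <- sim$census[sim$census$status == "alive", ]
  expect_equal(sum(alive$dbh_final < alive$dbh_initial),
               floor(0.1 * n_total))
  expect_equal(sum(alive$dbh_initial < 5), floor(0.1 * n_total))
  # every plot keeps measured valid trees
  filt <- filter_census(sim$census)
  expect_equal(length(unique(filt$retained$plot_id)), cfg$n_plots)
})

test_that("recomputed growth matches the simulated targets through the allometry", {
  sim <- simulate_forest(small_config(), seed = 10)
  filt <- filter_census(sim$census)
  growth <- tree_growth_rate(filt$retained)
  target <- sim$targets[match(growth$tree_id, sim$census$tree_id)]
  expect_lt(max(abs(growth$growth_rate - target) / target), 1e-6)
})

test_that("the whole simulation is a pure function of its seed", {
  a <- simulate_forest(small_config(), seed = 12)
  b <- simulate_forest(small_config(), seed = 12)
  expect_identical(a$otu_table, b$otu_table)
  expect_identical(a$census, b$census)
  expect_identical(a$env, b$env)
  expect_identical(a$ground_truth$latent_axis, b$ground_truth$latent_axis)
  c_ <- simulate_forest(small_config(), seed = 13)
  expect_false(identical(a$otu_table, c_$otu_table))
})

test_that("ground truth labels follow the latent axis sign", {
  sim <- simulate_forest(small_config(), seed = 14)
  gt <- sim$ground_truth
  expect_equal(unname(gt$slow_fast_truth[gt$latent_axis > 0]),
               rep("fast", sum(gt$latent_axis > 0)))
  expect_equal(gt$true_gamma, log(3) / 2)
})
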