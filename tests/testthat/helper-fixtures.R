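# Shared fixtures, all built in code.

# Balanced 4-tip tree, every branch length 1: two cherries (a,b) and (c,d).
balanced4 <- function() {
  ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
}

# A small census table exercising every filter rule.
tiny_census <- function() {
  data.frame(
    tree_id = paste0("t", 1:5),
    plot_id = "p1",
    species_group = "norway_spruce",
    dbh_initial = c(20, 4, 20, 20, 25),
    dbh_final   = c(25, 6, 19, 25, 30),
    year_initial = 2005, year_final = 2010,
    status = c("dead", "alive", "alive", "alive", "alive"),
    stringsAsFactors = FALSE
  )
}

# Small config for fast end-to-end tests.
small_config <- function(...) {
  sim_config(n_plots = 30, n_otus = 60, n_ref_species = 20,
             n_trees_per_plot = 10, ...)
}
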