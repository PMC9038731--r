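#!/usr/bin/env Rscript
# Stage 3: phylogenetic-signal screening of reference gene categories,
# decision-tree trait assignment to OTUs, community-weighted means, and
# exploration-type abundances.

library(mycogrowth)

seed <- 20260103 %% 2147483647
reference <- read.delim("results/data/reference.tsv",
                        stringsAsFactors = FALSE)
taxonomy <- read.delim("results/data/taxonomy.tsv",
                       stringsAsFactors = FALSE)
otu <- read_otu_table("results/data/otu_table.tsv")
tree <- read_phylogeny("results/data/species_tree.nwk")

cats <- intersect(trait_categories, names(reference))
signals <- screen_signal(reference, tree, cats, alpha = 0.05,
                         n_perm = 10000, seed = seed)
cat("Signal screen:", sum(signals$flagged), "of", nrow(signals),
    "categories flagged (",
    paste(signals$category[signals$flagged], collapse = ", "), ")\n")

assignment <- aggregate_organic_n(
  assign_traits(taxonomy, reference, signals, categories = cats))
cat("Assignment levels:", paste(names(table(assignment$level)),
                                table(assignment$level), collapse = ", "),
    "\n")

rare <- rarefy_table(otu, depth = 115, seed = stage_seed(seed, "rarefy"))
rel <- rare / rowSums(rare)
cwm <- community_weighted_mean(rel, assignment)
cat("CWM coverage: median", round(median(cwm$coverage), 2),
    "of relative abundance carried by assigned OTUs\n")
etype <- exploration_type_abundance(rel, taxonomy, reference)

dir.create("results/traits", recursive = TRUE, showWarnings = FALSE)
write.table(signals, "results/traits/signal_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(assignment, "results/traits/otu_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cwm, "results/traits/cwm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(etype, "results/traits/exploration_types.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
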