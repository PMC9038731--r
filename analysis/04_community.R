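#!/usr/bin/env Rscript
# Stage 4: rarefaction, alpha diversity, Bray-Curtis ordination, db-RDA
# against the environment, hierarchical clustering with elbow selection,
# analysis-of-means slow/fast classification, and indicator species.

library(mycogrowth)

seed <- 20260104 %% 2147483647
otu <- read_otu_table("results/data/otu_table.tsv")
env <- read.delim("results/data/environment.tsv", stringsAsFactors = FALSE)
stand <- read.delim("results/growth/stand_growth.tsv",
                    stringsAsFactors = FALSE)

rare <- rarefy_table(otu, depth = 115, seed = stage_seed(seed, "rarefy"))
alpha <- alpha_diversity(rare)
cat("Alpha diversity: median richness", median(alpha$richness),
    ", median Shannon", round(median(alpha$shannon), 2), "\n")

d <- bray_curtis(rare)
ord <- pcoa_ordination(d)
cat("PCoA axis 1 explains", round(100 * ord$proportion_explained[1], 1),
    "% of positive-eigenvalue inertia\n")

expl <- env[match(rownames(rare), env$plot_id),
            c("MAT", "MAP", "N_deposition", "soil_pH", "inorganic_N",
              "stand_age_class", "stem_density")]
rda <- db_rda(d, expl)
cat("db-RDA: environment explains",
    round(100 * rda$proportion_constrained, 1),
    "% of community variation\n")

clus <- hierarchical_cluster(d, k_max = 10)
cat("Hierarchical clustering: elbow selects k =", clus$k, "\n")

growth_v <- setNames(log(stand$mean_growth), stand$plot_id)
cls <- anom_classify(clus$labels, growth_v, alpha = 0.05)
print(cls)

indic <- indicator_species(rare, clus$labels[rownames(rare)],
                           n_perm = 999, seed = stage_seed(seed, "indval"))
cat("Indicator species:", sum(indic$p <= 0.05), "OTUs significant at 0.05\n")

dir.create("results/community", recursive = TRUE, showWarnings = FALSE)
write_otu_table(rare, "results/community/rarefied.tsv")
write.table(alpha, "results/community/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(plot_id = rownames(d), d, check.names = FALSE),
            "results/community/bray_curtis.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(plot_id = rownames(ord$coordinates),
                       ord$coordinates[, 1:min(5, ncol(ord$coordinates))],
                       check.names = FALSE),
            "results/community/pcoa.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(plot_id = names(clus$labels),
                       cluster = clus$labels),
            "results/community/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cls, "results/community/anom_classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(indic, "results/community/indicator_species.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
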