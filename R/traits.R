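# Decision-tree trait assignment of reference-genome gene proportions to
# OTUs, aggregation of organic-N cycling genes, community-weighted means,
# and exploration-type relative abundances.

#' Default functional gene categories
#'
#' Gene-count categories carried by the reference genome table. The first
#' four constitute the organic-N cycling aggregate.
#' @export
trait_categories <- c(
  "peptidases", "proteases", "multicopper_oxidases", "peroxidases",
  "energy_nutrient_metabolism", "amino_acid_metabolism",
  "carbohydrate_metabolism", "inorganic_N_metabolism", "N_permeases",
  "ammonium_sensing", "chitin_biosynthesis", "glucan_biosynthesis"
)

#' Recognized exploration types
#' @export
exploration_types <- c("contact", "short-distance", "medium-distance fringe",
                       "medium-distance smooth", "long-distance")

# Exact species-name matching after whitespace/underscore normalization and
# case folding.
normalize_name <- function(x) {
  tolower(gsub("[[:space:]_]+", " ", trimws(x)))
}

#' Assign reference-genome gene proportions to OTUs
#'
#' Implements the decision-tree assignment. An OTU whose species taxonomy
#' exactly matches a reference genome receives that genome's proportions
#' (count / total gene models) for every category: direct matches are not
#' gated by phylogenetic signal. An OTU with genus-only taxonomy (or a
#' species absent from the reference but whose genus is present) receives
#' the unweighted mean proportion across the genus's reference species, but
#' only for categories flagged as carrying phylogenetic signal; unflagged
#' categories are left missing at genus level. OTUs with no genus, or a
#' genus absent from the reference, are `unassigned`. Total gene models are
#' imputed analogously (species value or genus mean, which may be
#' fractional).
#'
#' @param taxonomy data.frame with `otu_id`, `genus`, `species` (`NA` where
#'   unassigned).
#' @param reference reference genome table with `species`, `genus`,
#'   `total_gene_models` and one count column per category.
#' @param signals output of [screen_signal()]; its `flagged` column gates
#'   genus-level imputation.
#' @param categories category columns to assign (default
#'   [trait_categories]).
#' @return data.frame with one row per OTU: `otu_id`, `level` (one of
#'   `species_match`, `genus_mean`, `unassigned`), `total_gene_models`, and
#'   one proportion column per category (`NA` where not assigned).
#' @export
assign_traits <- function(taxonomy, reference, signals,
                          categories = trait_categories) {
  assert_that(all(categories %in% names(reference)),
              "reference table lacks category columns")
  flagged <- intersect(signals$category[signals$flagged %in% TRUE],
                       categories)
  ref_species <- normalize_name(reference$species)
  ref_genus <- normalize_name(reference$genus)
  prop <- as.matrix(reference[categories]) / reference$total_gene_models

  # genus-level unweighted means of proportions and genome size
  genus_levels <- unique(ref_genus)
  gmean <- rowsum(prop, ref_genus)[genus_levels, , drop = FALSE] /
    as.vector(table(ref_genus)[genus_levels])
  gtot <- tapply(reference$total_gene_models, ref_genus, mean)[genus_levels]

  n <- nrow(taxonomy)
  out <- matrix(NA_real_, n, length(categories),
                dimnames = list(NULL, categories))
  level <- rep("unassigned", n)
  total <- rep(NA_real_, n)
  tax_sp <- normalize_name(taxonomy$species)
  tax_gen <- normalize_name(taxonomy$genus)
  for (i in seq_len(n)) {
    si <- if (!is.na(tax_sp[i]) && nzchar(tax_sp[i])) {
      match(tax_sp[i], ref_species)
    } else NA_integer_
    if (!is.na(si)) {
      level[i] <- "species_match"
      out[i, ] <- prop[si, ]
      total[i] <- reference$total_gene_models[si]
    } else if (!is.na(tax_gen[i]) && nzchar(tax_gen[i]) &&
               tax_gen[i] %in% genus_levels) {
      level[i] <- "genus_mean"
      out[i, flagged] <- gmean[tax_gen[i], flagged]
      total[i] <- gtot[[tax_gen[i]]]
    }
  }
  cbind(
    data.frame(otu_id = taxonomy$otu_id, level = level,
               total_gene_models = total, stringsAsFactors = FALSE),
    as.data.frame(out)
  )
}

#' Aggregate organic-N cycling genes
#'
#' Adds an `organic_N_cycling` column: the summed proportion of peptidase,
#' protease, multicopper oxidase, and peroxidase genes. Because the four
#' constituents share the genome-size denominator, summing proportions is
#' exactly the count-level sum divided by total gene models.
#'
#' @param assignment output of [assign_traits()].
#' @return the assignment table with an `organic_N_cycling` column appended.
#' @export
aggregate_organic_n <- function(assignment) {
  parts <- c("peptidases", "proteases", "multicopper_oxidases", "peroxidases")
  missing_cat <- setdiff(parts, names(assignment))
  assert_that(length(missing_cat) == 0,
              "missing constituent categories: ",
              paste(missing_cat, collapse = ", "))
  assignment$organic_N_cycling <- rowSums(assignment[parts])
  assignment
}

#' Community-weighted mean traits per plot
#'
#' CWM_t = sum_i w'_i t_i over OTUs carrying a value for trait t, where w'_i
#' are the plot's relative abundances renormalized over those OTUs
#' (`renormalize = TRUE`, the default) or the raw relative abundances
#' (missing-trait abundance then counts as zero weight and the weights are
#' still renormalized over non-missing OTUs only when renormalize is TRUE).
#' A `coverage` column reports the unrenormalized share of abundance carried
#' by assigned OTUs so that low-coverage plots can be filtered downstream.
#'
#' @param rel_abund plot x OTU matrix of relative abundances (rows sum to 1;
#'   tolerance 1e-9).
#' @param assignment output of [assign_traits()] /
#'   [aggregate_organic_n()].
#' @param traits trait columns to average (default: all category columns
#'   present).
#' @param renormalize logical; renormalize weights over OTUs with a value
#'   for each trait (default TRUE). With FALSE, missing-trait abundance
#'   dilutes the CWM toward zero.
#' @return data.frame with `plot_id`, one column per trait (NA where no
#'   abundance is covered), and `coverage`.
#' @export
community_weighted_mean <- function(rel_abund, assignment,
                                    traits = NULL, renormalize = TRUE) {
  rel_abund <- as.matrix(rel_abund)
  assert_that(all(abs(rowSums(rel_abund) - 1) <= 1e-9),
              "relative abundance rows must sum to 1")
  if (is.null(traits)) {
    traits <- intersect(c(trait_categories, "organic_N_cycling",
                          "total_gene_models"),
                        names(assignment))
  }
  idx <- match(colnames(rel_abund), assignment$otu_id)
  assert_that(!anyNA(idx), "assignment table must cover all OTUs")
  assignment <- assignment[idx, , drop = FALSE]
  assigned <- assignment$level != "unassigned"
  coverage <- rowSums(rel_abund[, assigned, drop = FALSE])
  out <- matrix(NA_real_, nrow(rel_abund), length(traits),
                dimnames = list(rownames(rel_abund), traits))
  for (t in traits) {
    v <- assignment[[t]]
    ok <- !is.na(v)
    w <- rel_abund[, ok, drop = FALSE]
    tot <- rowSums(w)
    num <- as.vector(w %*% v[ok])
    out[, t] <- if (renormalize) {
      ifelse(tot > 0, num / tot, NA_real_)
    } else {
      ifelse(tot > 0, num, NA_real_)
    }
  }
  data.frame(plot_id = rownames(rel_abund), out, coverage = coverage,
             row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Exploration-type relative abundances per plot
#'
#' Sums each plot's relative abundance by hyphal exploration type over OTUs
#' with a type assignment (direct species match, else the genus's majority
#' type), renormalized over typed OTUs so rows sum to 1 wherever any OTU is
#' typed.
#'
#' @param rel_abund plot x OTU relative abundance matrix.
#' @param taxonomy data.frame with `otu_id`, `genus`, `species`.
#' @param reference reference table with `species`, `genus`,
#'   `exploration_type`.
#' @return data.frame with `plot_id` and one column per exploration type.
#' @export
exploration_type_abundance <- function(rel_abund, taxonomy, reference) {
  rel_abund <- as.matrix(rel_abund)
  ref_species <- normalize_name(reference$species)
  ref_genus <- normalize_name(reference$genus)
  genus_type <- vapply(split(reference$exploration_type, ref_genus),
                       function(tt) names(sort(table(tt),
                                               decreasing = TRUE))[1],
                       character(1))
  idx <- match(colnames(rel_abund), taxonomy$otu_id)
  assert_that(!anyNA(idx), "taxonomy must cover all OTUs")
  tax <- taxonomy[idx, , drop = FALSE]
  type <- rep(NA_character_, nrow(tax))
  si <- match(normalize_name(tax$species), ref_species)
  type[!is.na(si)] <- reference$exploration_type[si[!is.na(si)]]
  gi <- is.na(type) & normalize_name(tax$genus) %in% names(genus_type)
  type[gi] <- genus_type[normalize_name(tax$genus)[gi]]
  typed <- !is.na(type)
  types <- exploration_types
  out <- matrix(0, nrow(rel_abund), length(types),
                dimnames = list(rownames(rel_abund), types))
  for (ty in types) {
    sel <- typed & type == ty
    if (any(sel)) out[, ty] <- rowSums(rel_abund[, sel, drop = FALSE])
  }
  tot <- rowSums(out)
  out <- out / ifelse(tot > 0, tot, NA_real_)
  data.frame(plot_id = rownames(rel_abund), out, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
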