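# Layer three: classify candidate driver genes by cancer role, expand to
# their closest pathway neighbors, query the drug-gene interaction table
# with role-specific term sets, score each drug by the product of the gene
# driver probability, the target relatedness probability and the drug
# activity probability, and attach regulatory tiers.

#' Interaction terms that positively influence a tumor suppressor
#' @export
SUPPRESSOR_TERMS <- c(
  "activator", "inducer", "positive allosteric modulator", "potentiator",
  "stimulator")

#' Interaction terms that negatively influence an oncogene
#' @export
ONCOGENE_TERMS <- c(
  "agonist", "antisense", "competitive", "immunotherapy",
  "inhibitory allosteric modulator", "inverse agonist", "negative modulator",
  "partial agonist", "partial antagonist", "vaccine", "inhibitor",
  "suppressor", "antibody", "antagonist", "blocker")

#' Classify a gene's cancer role
#'
#' Membership in the tumor-suppressor or oncogene list determines the role;
#' a gene present in both lists is downgraded to `"other"` with a warning
#' (queried broadly, no directional assumption), as is a gene in neither.
#'
#' @param gene gene symbol.
#' @param suppressor_set,oncogene_set character vectors of member symbols.
#' @return one of `"tumor_suppressor"`, `"oncogene"`, `"other"`.
#' @export
classify_gene_role <- function(gene, suppressor_set, oncogene_set) {
  s <- gene %in% suppressor_set
  o <- gene %in% oncogene_set
  if (s && o) {
    warning("gene ", gene,
            " is listed as both suppressor and oncogene; treating as other")
    return("other")
  }
  if (s) "tumor_suppressor" else if (o) "oncogene" else "other"
}

#' The gene itself plus its top pathway neighbors
#'
#' Returns the gene (self-relatedness 1.0) and the `k` neighbors with the
#' highest normalized relatedness probability; ties at rank `k` break
#' lexicographically by symbol.
#'
#' @param gene gene symbol (the final target).
#' @param links `data.table` with `gene`, `neighbor`, `relatedness`.
#' @param k neighbor count (default 4).
#' @return `data.table` with `neighbor` and `relatedness`, self first,
#'   sorted by descending relatedness.
#' @export
top_neighbors <- function(gene, links, k = 4L) {
  stopifnot(k >= 0L)
  idx <- which(links$gene == gene & links$neighbor != gene) # precomputed so
  nb <- links[idx, ]                       # columns cannot shadow the args
  nb <- nb[order(-nb$relatedness, nb$neighbor), ]
  nb <- head(nb[, c("neighbor", "relatedness")], k)
  rbind(data.table(neighbor = gene, relatedness = 1.0), nb)
}

#' Query drug-gene interactions with role-specific term sets
#'
#' Tumor suppressors admit only the five positively-influencing terms,
#' oncogenes only the fifteen negatively-influencing terms, and other genes
#' any interaction. Records sourced from the curated FDA list always pass
#' the term filter.
#'
#' @param gene gene symbol (the direct target being queried).
#' @param role the gene's cancer role (see [classify_gene_role()]).
#' @param interactions `data.table` with `drug`, `gene`, `term`, `source`
#'   (`curated-db` or `fda-list`).
#' @return the matching interaction rows.
#' @export
query_drugs <- function(gene, role, interactions) {
  idx <- which(interactions$gene == gene) # computed before the bracket so
  rec <- interactions[idx, ]              # the column cannot shadow `gene`
  if (!nrow(rec)) return(rec)
  keep <- switch(role,
    tumor_suppressor = tolower(rec$term) %in% SUPPRESSOR_TERMS,
    oncogene = tolower(rec$term) %in% ONCOGENE_TERMS,
    other = rep(TRUE, nrow(rec)),
    stop("unknown gene role: ", role))
  rec[keep | rec$source == "fda-list", ]
}

#' Normalize raw assay scores into per-drug activity probabilities
#'
#' Per drug, assay values beyond 1.5 IQR of that drug's own scores are
#' dropped as outliers and the rest averaged; the per-drug means are then
#' min-max normalized to `[0, 1]` across drugs. A degenerate (constant)
#' range maps every drug to 1.0.
#'
#' @param raw_scores `data.table` with `drug` and `assay_score` (long
#'   format, one row per assay).
#' @return `data.table` with `drug`, `activity`, `n_assays`.
#' @export
normalize_activity <- function(raw_scores) {
  raw_scores <- as.data.table(raw_scores)
  if (!nrow(raw_scores)) stop("no assay scores supplied")
  means <- raw_scores[, {
    x <- assay_score
    if (length(x) >= 4L) {
      qs <- quantile(x, c(0.25, 0.75), type = 7)
      iqr <- qs[2] - qs[1]
      x <- x[x >= qs[1] - 1.5 * iqr & x <= qs[2] + 1.5 * iqr]
    }
    list(mean_score = mean(x), n_assays = length(x))
  }, by = "drug"]
  rng <- range(means$mean_score)
  means$activity <- if (rng[2] > rng[1])
    (means$mean_score - rng[1]) / (rng[2] - rng[1])
  else rep(1.0, nrow(means))
  means[, c("drug", "activity", "n_assays")]
}

#' Joint probability score of a drug candidate
#'
#' The product of the final-target gene driver probability, the
#' direct-target relatedness probability and the drug activity probability.
#'
#' @param gene_score,relatedness,activity probabilities in `[0, 1]`.
#' @return the product, in `[0, 1]`.
#' @export
score_drug <- function(gene_score, relatedness, activity) {
  args <- c(gene_score = gene_score, relatedness = relatedness,
            activity = activity)
  if (any(!is.finite(args)) || any(args < 0 | args > 1))
    stop("all three factors must be probabilities in [0, 1]")
  unname(gene_score * relatedness * activity)
}

#' Regulatory tier of a drug
#'
#' Tier 1 when FDA approved (regardless of trial status), tier 2 when only
#' in active clinical trials, tier 3 otherwise. Tier-1/2 drugs carry brand,
#' approved-subtype and trial metadata when available.
#'
#' @param drug drug name.
#' @param fda_table `data.table` with `drug`, `brand`, `subtypes`.
#' @param trial_table `data.table` with `drug`, `trial_name`, `trial_org`,
#'   `trial_phase`, `trial_url`.
#' @param patient_subtype optional patient subtype; when it differs from
#'   every approved subtype of a tier-1/2 drug, a tumor-type repurposing
#'   flag is set (metadata only, no score change).
#' @return list with `tier` and metadata fields.
#' @export
assign_tier <- function(drug, fda_table, trial_table,
                        patient_subtype = NA_character_) {
  fda_idx <- which(fda_table$drug == drug)
  trial_idx <- which(trial_table$drug == drug)
  fda <- fda_table[fda_idx, ]
  trial <- trial_table[trial_idx, ]
  meta <- list(tier = 3L, brand = NA_character_, subtypes = NA_character_,
               trial_name = NA_character_, trial_org = NA_character_,
               trial_phase = NA_character_, trial_url = NA_character_,
               repurposing = FALSE)
  if (nrow(trial)) {
    meta$tier <- 2L
    meta$trial_name <- trial$trial_name[1]
    meta$trial_org <- trial$trial_org[1]
    meta$trial_phase <- as.character(trial$trial_phase[1])
    meta$trial_url <- trial$trial_url[1]
  }
  if (nrow(fda)) {
    meta$tier <- 1L
    meta$brand <- fda$brand[1]
    meta$subtypes <- fda$subtypes[1]
  }
  if (meta$tier < 3L && !is.na(patient_subtype) && nrow(fda)) {
    approved <- tolower(trimws(strsplit(fda$subtypes[1], ",")[[1]]))
    meta$repurposing <- !(tolower(patient_subtype) %in% approved)
  }
  meta
}

#' Rank drug candidates
#'
#' Orders candidates by descending drug score, breaking ties by lower tier
#' number and then drug name. A drug reachable through several
#' (direct target, final target) paths keeps only its highest-scoring path.
#'
#' @param candidates `data.table` of drug candidates with at least `drug`,
#'   `drug_score`, `tier`.
#' @return the deduplicated, ranked table.
#' @export
rank_drugs <- function(candidates) {
  candidates <- as.data.table(candidates)
  if (!nrow(candidates)) return(candidates)
  candidates <- candidates[order(-candidates$drug_score, candidates$tier,
                                 candidates$drug), ]
  candidates[!duplicated(candidates$drug), ]
}
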