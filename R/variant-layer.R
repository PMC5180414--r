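# Layer one: one driver-potential score per variant. Point coding mutations
# go through the calibrated radial SVM over eleven predictors; point
# non-coding mutations take a precomputed functional score; structural
# variants and indels take the recurrent focal copy-number signal of the
# regions they overlap, conditional on the gene's cancer role.

# predictor database line layout (tab-delimited, no header):
# chrom, pos, ref, alt, <11 predictor columns in PREDICTOR_NAMES order>, mmaf
PREDICTOR_DB_COLS <- c("chrom", "pos", "ref", "alt", PREDICTOR_NAMES, "mmaf")

parse_predictor_row <- function(fields) {
  v <- suppressWarnings(as.numeric(fields[5:15]))
  names(v) <- PREDICTOR_NAMES
  list(ref = fields[3], alt = fields[4], values = v,
       mmaf = suppressWarnings(as.numeric(fields[16])))
}

# min-max scale the predictors that do not arrive on a 0-1 scale, clamping
# at inference so unseen extremes stay inside the training range
normalize_predictors <- function(values, scalers) {
  for (nm in names(scalers)) {
    s <- scalers[[nm]]
    if (is.null(s)) next
    rng <- s$max - s$min
    x <- if (rng > 0) (values[[nm]] - s$min) / rng else 0.5
    values[[nm]] <- pmin(pmax(x, 0), 1)
  }
  values
}

#' Annotate a point mutation with the eleven-predictor feature vector
#'
#' Looks the variant up in the TDS-indexed predictor database by exact
#' (chrom, pos, ref, alt). The six predictors already on a 0-1
#' deleteriousness scale pass through; the remaining five are min-max scaled
#' with the model's training ranges; predictors missing from the database
#' row are imputed with the model's training medians and flagged in
#' `missing_mask`.
#'
#' @param variant one-row variant record table (a point mutation).
#' @param predictor_db a `tds_index` over the predictor database.
#' @param model an `ensemble_svm_model` providing scalers and medians.
#' @return `NULL` when the site (or the exact allele) is absent -- the
#'   caller should re-route the variant to the non-coding scorer --
#'   otherwise a list with `values` (named, normalized, complete) and
#'   `missing_mask`.
#' @export
annotate_coding <- function(variant, predictor_db, model) {
  stopifnot(nrow(variant) == 1L,
            variant$category %in% c("coding_point", "noncoding_point"))
  hits <- tds_query_fields(predictor_db, variant$chrom, variant$pos)
  if (!length(hits)) return(NULL)
  rows <- lapply(hits, parse_predictor_row)
  match_i <- which(vapply(rows, function(r)
    r$ref == variant$ref && r$alt == variant$alt, logical(1)))
  if (!length(match_i)) {
    warning(sprintf("position %s:%d present but allele %s>%s not found",
                    variant$chrom, variant$pos, variant$ref, variant$alt))
    return(NULL)
  }
  values <- rows[[match_i[1]]]$values
  values <- normalize_predictors(values, model$scalers)
  miss <- names(values)[is.na(values)]
  if (length(miss)) values[miss] <- model$training_medians[miss]
  list(values = values[model$feature_order], missing_mask = miss)
}

#' Score a point non-coding mutation by functional-score lookup
#'
#' The database is tab-delimited `chrom, pos, score`; the stored score is
#' clamped to `[0, 1]`. A site absent from the database scores 0.
#'
#' @param variant one-row variant record table (`noncoding_point`).
#' @param funseq2_db a `tds_index` over the non-coding score database.
#' @return a variant score list (`score_category = "funseq2"`).
#' @export
score_noncoding <- function(variant, funseq2_db) {
  stopifnot(nrow(variant) == 1L)
  hits <- tds_query_fields(funseq2_db, variant$chrom, variant$pos)
  val <- 0
  if (length(hits)) {
    v <- suppressWarnings(as.numeric(hits[[1]][3]))
    if (!is.na(v)) val <- min(max(v, 0), 1)
  }
  list(variant = variant, score_category = "funseq2", value = val)
}

#' Score a structural variant from recurrent focal copy-number signal
#'
#' A loss-of-function variant that overlaps (by at least one base) a
#' deletion-signal region whose gene is a tumor suppressor receives that
#' region's normalized signal; a gain-of-function variant over a
#' duplication-signal region on an oncogene likewise. Multiple overlaps take
#' the maximum signal; no qualifying overlap scores 0.
#'
#' @param variant one-row variant record table (structural or indel).
#' @param effect `"loss_of_function"` or `"gain_of_function"`.
#' @param regions `data.table` with `chrom`, `start`, `end`, `signal`,
#'   `kind` (`deletion`/`duplication`), `gene`.
#' @param suppressors,oncogenes character vectors of gene symbols.
#' @return a variant score list (`score_category = "cnv_signal"`).
#' @export
score_structural <- function(variant, effect = c("loss_of_function",
                                                 "gain_of_function"),
                             regions, suppressors, oncogenes) {
  effect <- match.arg(effect)
  stopifnot(nrow(variant) == 1L)
  if (variant$category == "structural") {
    want <- if (variant$sv_kind == "deletion") "loss_of_function"
            else "gain_of_function"
    if (effect != want)
      stop("effect '", effect, "' is inconsistent with sv_kind '",
           variant$sv_kind, "'")
  }
  if (effect == "loss_of_function") {
    cand <- regions[regions$kind == "deletion" &
                      regions$gene %in% suppressors, ]
  } else {
    cand <- regions[regions$kind == "duplication" &
                      regions$gene %in% oncogenes, ]
  }
  val <- 0
  if (nrow(cand)) {
    ov <- cand$chrom == variant$chrom &
      cand$start <= variant$end & cand$end >= variant$pos
    if (any(ov)) val <- max(cand$signal[ov])
  }
  list(variant = variant, score_category = "cnv_signal", value = val)
}

#' Score a small insertion/deletion
#'
#' With the mode of action unknown, the indel is scored under both the
#' loss-of-function and the gain-of-function rule and the more deleterious
#' of the two annotations is kept.
#'
#' @inheritParams score_structural
#' @return a variant score list (`score_category = "cnv_signal"`).
#' @export
score_indel <- function(variant, regions, suppressors, oncogenes) {
  stopifnot(variant$category == "indel")
  lof <- score_structural(variant, "loss_of_function", regions,
                          suppressors, oncogenes)
  gof <- score_structural(variant, "gain_of_function", regions,
                          suppressors, oncogenes)
  list(variant = variant, score_category = "cnv_signal",
       value = max(lof$value, gof$value))
}

#' Filter labeled mutations by maximum population allele frequency
#'
#' True-positive (driver) candidates keep a maximum minor allele frequency
#' (MMAF) of at most 0.01, screening out likely germline polymorphisms;
#' true-negative candidates keep MMAF of at least 0.20 (frequent, hence
#' likely neutral). A mutation present in both candidate sets is removed
#' from the TP set.
#'
#' @param mutations `data.table` with at least `chrom`, `pos`, `ref`, `alt`,
#'   `mmaf`.
#' @param role `"tp"` or `"tn"`.
#' @param other optional candidate set of the opposite role, used to drop
#'   shared mutations from the TP set.
#' @return the filtered `data.table`.
#' @export
mmaf_filter <- function(mutations, role = c("tp", "tn"), other = NULL) {
  role <- match.arg(role)
  mutations <- as.data.table(mutations)
  if (any(is.na(mutations$mmaf)) ||
      any(mutations$mmaf < 0 | mutations$mmaf > 1))
    stop("MMAF values must lie in [0, 1]")
  out <- if (role == "tp") mutations[mutations$mmaf <= 0.01, ]
         else mutations[mutations$mmaf >= 0.20, ]
  if (role == "tp" && !is.null(other) && nrow(other)) {
    key_of <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    out <- out[!key_of(out) %in% key_of(as.data.table(other)), ]
  }
  out[]
}
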