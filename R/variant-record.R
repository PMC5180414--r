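#' Variant record tables and patient profiles
#'
#' A variant record table is a `data.table` with one row per somatic mutation
#' and columns `chrom`, `pos`, `end`, `ref`, `alt`, `category`, `sv_kind`,
#' `gene`. Coordinates are 1-based inclusive (`end == pos` for single
#' nucleotide variants). `category` is one of `"coding_point"`,
#' `"noncoding_point"`, `"indel"`, `"structural"`; point mutations enter as
#' `"coding_point"` and are re-routed to `"noncoding_point"` when no
#' exact-allele row exists in the coding predictor database. `sv_kind` is
#' `"deletion"`, `"duplication"` or `"none"` and is non-`"none"` exactly for
#' structural records.
#'
#' @param chrom character vector of chromosome/contig names.
#' @param pos integer vector of 1-based start coordinates.
#' @param end integer vector of 1-based inclusive end coordinates.
#' @param ref,alt allele strings (`"-"` denotes absence in the 5-column
#'   dialect; symbolic alleles such as `"<DEL>"` are allowed for structural
#'   records).
#' @param category mutation category, recycled if scalar.
#' @param sv_kind structural-variant kind, recycled if scalar.
#' @param gene optional pre-assigned gene symbol.
#' @return a validated `data.table` of variant records.
#' @export
variant_table <- function(chrom, pos, end = pos, ref, alt,
                          category = "coding_point", sv_kind = "none",
                          gene = NA_character_) {
  dt <- data.table(
    chrom = as.character(chrom), pos = as.integer(pos), end = as.integer(end),
    ref = as.character(ref), alt = as.character(alt),
    category = as.character(category), sv_kind = as.character(sv_kind),
    gene = as.character(gene)
  )
  validate_variant_table(dt)
}

validate_variant_table <- function(dt) {
  stopifnot(is.data.frame(dt))
  dt <- as.data.table(dt)
  bad_cat <- setdiff(unique(dt$category),
                     c("coding_point", "noncoding_point", "indel", "structural"))
  if (length(bad_cat))
    stop("unknown mutation category: ", paste(bad_cat, collapse = ", "))
  bad_kind <- setdiff(unique(dt$sv_kind), c("deletion", "duplication", "none"))
  if (length(bad_kind))
    stop("unknown sv_kind: ", paste(bad_kind, collapse = ", "))
  if (any(dt$pos < 1L)) stop("pos must be >= 1")
  if (any(dt$end < dt$pos)) stop("end must be >= pos")
  if (any((dt$category == "structural") != (dt$sv_kind != "none")))
    stop("category 'structural' must coincide with sv_kind != 'none'")
  pt <- dt$category %in% c("coding_point", "noncoding_point")
  if (any(pt & dt$ref == dt$alt))
    stop("point mutations must have ref != alt")
  dt[]
}

#' Construct a patient profile
#'
#' Bundles one patient's somatic variant records with the sample identity,
#' an optional cancer subtype label and the genome build the coordinates
#' refer to.
#'
#' @param sample_id sample name.
#' @param variants a variant record table (see [variant_table()]).
#' @param cancer_subtype optional subtype label used to select a
#'   subtype-specific gene model.
#' @param genome_build one of `"hg18"`, `"hg19"` (default), `"hg38"`.
#' @return an object of class `patient_profile`.
#' @export
patient_profile <- function(sample_id, variants,
                            cancer_subtype = NA_character_,
                            genome_build = "hg19") {
  genome_build <- match.arg(genome_build, c("hg18", "hg19", "hg38"))
  variants <- validate_variant_table(variants)
  structure(
    list(sample_id = as.character(sample_id), variants = variants,
         cancer_subtype = as.character(cancer_subtype),
         genome_build = genome_build),
    class = "patient_profile"
  )
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile> sample:", x$sample_id,
      " build:", x$genome_build,
      " subtype:", ifelse(is.na(x$cancer_subtype), "(none)", x$cancer_subtype),
      "\n  variants:", nrow(x$variants), "(",
      paste(sprintf("%s=%d", names(table(x$variants$category)),
                    as.integer(table(x$variants$category))), collapse = ", "),
      ")\n")
  invisible(x)
}
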