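# Input dialects: 5-column annotation format (1-based inclusive), VCF 4.x,
# and BED (0-based half-open) for structural variants. Internal coordinates
# are always 1-based inclusive.

#' Read a 5-column annotation-format mutation file
#'
#' Each non-empty line carries at least five whitespace-delimited fields:
#' chromosome, start, end, reference allele, alternate allele (1-based
#' inclusive coordinates; `"-"` marks an absent allele). Single-base
#' substitutions enter as point mutations (coding until proven otherwise by
#' the predictor-database router); dash or length-changing alleles become
#' indels.
#'
#' @param path input file path.
#' @param sample_id sample name recorded on the profile (default the file
#'   base name).
#' @param cancer_subtype,genome_build passed to [patient_profile()].
#' @return a [patient_profile()].
#' @export
read_annovar_input <- function(path, sample_id = basename(path),
                               cancer_subtype = NA_character_,
                               genome_build = "hg19") {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input: no mutation lines in ", path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) < 5)
      stop(sprintf("malformed input at line %d: expected >= 5 fields, got %d",
                   i, length(f)))
    pos <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(pos) || is.na(end))
      stop(sprintf("malformed input at line %d: non-integer coordinate", i))
    ref <- f[4]; alt <- f[5]
    is_point <- nchar(ref) == 1L && nchar(alt) == 1L &&
      ref != "-" && alt != "-"
    recs[[i]] <- list(chrom = f[1], pos = pos, end = end, ref = ref,
                      alt = alt,
                      category = if (is_point) "coding_point" else "indel",
                      sv_kind = "none", gene = NA_character_)
  }
  dt <- rbindlist(recs)
  patient_profile(sample_id, validate_variant_table(dt),
                  cancer_subtype = cancer_subtype,
                  genome_build = genome_build)
}

#' Read somatic variants from a VCF file
#'
#' Emits the variants carried by the selected sample (non-reference
#' genotype), splitting multi-allelic sites into one record per alternate
#' allele. Records flagged germline -- a recognized tag in FILTER or a
#' truthy INFO field named after the tag -- are excluded; when no record
#' carries any tag all records are treated as somatic and a message is
#' logged. Symbolic structural alleles `<DEL>`/`<DUP>` become structural
#' records (the INFO `END` field supplies the interval end); other symbolic
#' alleles are skipped with a warning.
#'
#' @param path VCF file path.
#' @param sample sample name; required when the file carries more than one
#'   sample.
#' @param germline_tags character vector of FILTER/INFO tags that mark a
#'   record as germline.
#' @param cancer_subtype,genome_build passed to [patient_profile()].
#' @return a [patient_profile()].
#' @export
read_vcf_somatic <- function(path, sample = NULL,
                             germline_tags = c("GERMLINE"),
                             cancer_subtype = NA_character_,
                             genome_build = "hg19") {
  if (!file.exists(path)) stop("input file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  if (length(samples) > 1L && is.null(sample))
    stop("multi-sample VCF: the sample to analyze must be specified")
  if (!is.null(sample)) {
    if (!sample %in% samples) stop("sample not present in VCF: ", sample)
  } else {
    sample <- if (length(samples)) samples[[1L]] else NA_character_
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (!n) stop("empty input: no variant records in ", path)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_len(n), function(i) as.character(alt_list[[i]]))

  info <- VariantAnnotation::info(vcf)
  filt <- rr$FILTER
  is_germline <- rep(FALSE, n)
  for (tag in germline_tags) {
    if (!is.null(filt))
      is_germline <- is_germline |
        vapply(strsplit(ifelse(is.na(filt), "", filt), ";"),
               function(x) tag %in% x, logical(1))
    if (tag %in% colnames(info)) {
      v <- info[[tag]]
      hit <- if (is.logical(v)) v %in% TRUE else !is.na(v)
      is_germline <- is_germline | hit
    }
  }
  if (!any(is_germline))
    message("no germline tag (", paste(germline_tags, collapse = ","),
            ") found; treating all VCF records as somatic")

  # which ALT alleles does the selected sample carry?
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  carried <- lapply(seq_len(n), function(i) seq_along(alt_chr[[i]]))
  if (!is.null(gt) && !is.na(sample) && sample %in% colnames(gt)) {
    carried <- lapply(seq_len(n), function(i) {
      g <- gt[i, sample]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(integer(0))
      idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      sort(unique(idx[!is.na(idx) & idx > 0L]))
    })
  }

  svend <- if ("END" %in% colnames(info)) info$END else rep(NA_integer_, n)
  recs <- list(); skipped <- 0L
  for (i in seq_len(n)) {
    if (is_germline[i]) next
    for (ai in carried[[i]]) {
      a <- alt_chr[[i]][ai]
      if (!nzchar(a) || is.na(a)) next
      if (grepl("^<", a)) {
        kind <- switch(a, "<DEL>" = "deletion", "<DUP>" = "duplication", NA)
        if (is.na(kind)) { skipped <- skipped + 1L; next }
        e <- if (!is.na(svend[i])) as.integer(svend[i]) else pos[i]
        recs[[length(recs) + 1L]] <- list(
          chrom = chrom[i], pos = pos[i], end = e, ref = ref[i], alt = a,
          category = "structural", sv_kind = kind, gene = NA_character_)
      } else {
        is_point <- nchar(ref[i]) == 1L && nchar(a) == 1L
        recs[[length(recs) + 1L]] <- list(
          chrom = chrom[i], pos = pos[i],
          end = pos[i] + nchar(ref[i]) - 1L, ref = ref[i], alt = a,
          category = if (is_point) "coding_point" else "indel",
          sv_kind = "none", gene = NA_character_)
      }
    }
  }
  if (skipped > 0L)
    warning(skipped, " record(s) with unsupported symbolic alleles skipped")
  if (!length(recs)) stop("no somatic variants for sample ", sample)
  patient_profile(sample, validate_variant_table(rbindlist(recs)),
                  cancer_subtype = cancer_subtype,
                  genome_build = genome_build)
}

#' Read structural variants from a BED file
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' structural variant records; a label column carries the kind
#' (`deletion`/`duplication`).
#'
#' @param path BED file path.
#' @param kind_field 1-based index of the column carrying the kind label.
#' @return a variant record table with `category == "structural"`.
#' @export
read_bed_structural <- function(path, kind_field = 4L) {
  if (!file.exists(path)) stop("input file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (!nrow(dt)) stop("empty input: no BED intervals in ", path)
  if (ncol(dt) < kind_field)
    stop("BED file lacks the kind label column (", kind_field, ")")
  start0 <- as.integer(dt[[2]]); end0 <- as.integer(dt[[3]])
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("invalid interval at BED line %d: start >= end", bad[1]))
  kind <- tolower(as.character(dt[[kind_field]]))
  unknown <- which(!kind %in% c("deletion", "duplication"))
  if (length(unknown))
    stop(sprintf("unknown structural kind '%s' at BED line %d",
                 kind[unknown[1]], unknown[1]))
  variant_table(chrom = dt[[1]], pos = start0 + 1L, end = end0,
                ref = "N", alt = ifelse(kind == "deletion", "<DEL>", "<DUP>"),
                category = "structural", sv_kind = kind)
}

# column headers of the three output tables (fixed contract)
MUTATION_CSV_COLS <- c(
  "Gene name", "Chromosome number", "Coordinate", "Reference allele",
  "Alternative allele", "Mutation category", "Mutation context",
  "Protein context", "Score category", "Driver mutation score")
GENE_CSV_COLS <- c(
  "Gene name", "Gene category", "Maximum radial SVM score",
  "Maximum FunSeq2 score", "Maximum normalized CNV signal score",
  "Phenolyzer score", "Driver gene score")
DRUG_CSV_COLS <- c(
  "Drug name", "Final target gene", "Direct target gene",
  "Driver gene score", "BioSystems normalized relatedness probability",
  "PubChem normalized drug active probability", "Driver drug score", "Tier",
  "Brand name", "FDA approved subtype", "Clinical trial name",
  "Clinical trial organization", "Clinical trial phase", "Clinical trial URL")

fmt_score <- function(x) ifelse(is.na(x), ".", sprintf("%.3f", x))
fmt_chr <- function(x) {
  x <- as.character(x)
  ifelse(is.na(x) | !nzchar(x), ".", x)
}

category_label <- function(category) {
  c(coding_point = "Point coding mutation",
    noncoding_point = "Point non-coding mutation",
    indel = "Structural variation",
    structural = "Structural variation")[category]
}

score_category_label <- function(score_category) {
  c(radial_svm = "Radial SVM", funseq2 = "FunSeq2",
    cnv_signal = "Normalized CNV signal")[score_category]
}

#' Write the three result tables and their JSON mirror
#'
#' Serializes the mutation, gene and drug prioritization tables to
#' `<out_prefix>.mutations.csv`, `<out_prefix>.genes.csv`,
#' `<out_prefix>.drugs.csv` plus `<out_prefix>.json`, which carries the same
#' information as the three CSV files. Scores are printed with three
#' decimals; missing values print as `"."`.
#'
#' @param mutation_table,gene_table,drug_table internal result tables as
#'   produced by [run_patient()] (a header-only file is written for an empty
#'   table).
#' @param out_prefix path prefix for the four output files.
#' @return invisibly, the three serialized (display-formatted) tables.
#' @export
write_outputs <- function(mutation_table, gene_table, drug_table, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  mut <- data.table(
    fmt_chr(mutation_table$gene), fmt_chr(mutation_table$chrom),
    fmt_chr(mutation_table$pos), fmt_chr(mutation_table$ref),
    fmt_chr(mutation_table$alt),
    fmt_chr(category_label(mutation_table$category)),
    fmt_chr(mutation_table$context), fmt_chr(mutation_table$protein_context),
    fmt_chr(score_category_label(mutation_table$score_category)),
    fmt_score(mutation_table$score))
  setnames(mut, MUTATION_CSV_COLS)

  gen <- data.table(
    fmt_chr(gene_table$gene), fmt_chr(gene_category_label(gene_table$gene_category)),
    fmt_score(gene_table$max_radial_svm), fmt_score(gene_table$max_funseq2),
    fmt_score(gene_table$max_cnv_signal), fmt_score(gene_table$phenolyzer),
    fmt_score(gene_table$gene_score))
  setnames(gen, GENE_CSV_COLS)

  if (nrow(drug_table)) {
    drg <- data.table(
      fmt_chr(drug_table$drug), fmt_chr(drug_table$final_target),
      fmt_chr(drug_table$direct_target), fmt_score(drug_table$gene_score),
      fmt_score(drug_table$relatedness), fmt_score(drug_table$activity),
      fmt_score(drug_table$drug_score), fmt_chr(drug_table$tier),
      fmt_chr(drug_table$brand), fmt_chr(drug_table$subtypes),
      fmt_chr(drug_table$trial_name), fmt_chr(drug_table$trial_org),
      fmt_chr(drug_table$trial_phase), fmt_chr(drug_table$trial_url))
    setnames(drg, DRUG_CSV_COLS)
  } else {
    drg <- setNames(
      as.data.table(lapply(DRUG_CSV_COLS, function(x) character(0))),
      DRUG_CSV_COLS)
  }

  paths <- paste0(out_prefix, c(".mutations.csv", ".genes.csv", ".drugs.csv"))
  fwrite(mut, paths[1]); fwrite(gen, paths[2]); fwrite(drg, paths[3])
  jsonlite::write_json(
    list(mutations = mut, genes = gen, drugs = drg),
    paste0(out_prefix, ".json"), dataframe = "rows", na = "string")
  invisible(list(mutations = mut, genes = gen, drugs = drg))
}

gene_category_label <- function(x) {
  c(cancer_gene_census = "Cancer Gene Census",
    kegg_cancer_pathway = "KEGG cancer pathway",
    other = "Other")[x]
}
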