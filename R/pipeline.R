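# Single-patient orchestration of the three layers.

#' Assemble a run configuration
#'
#' Collects everything [run_patient()] needs. Inputs can be given as a
#' ready-made [patient_profile()] (`profile`) or as a file (`input` +
#' `format`). Models may be passed as fitted objects or as archive paths
#' (see [save_ensemble_model()] / [save_logistic_model()]).
#'
#' @param profile a [patient_profile()], or `NULL` to read from `input`.
#' @param input input file path (used when `profile` is `NULL`).
#' @param format `"vcf"` or `"annovar"`.
#' @param sample sample to analyze in a multi-sample VCF.
#' @param bed_sv optional BED file of structural variants to append.
#' @param subtype optional cancer subtype label (overrides the profile's).
#' @param build genome build label (`"hg19"` default); non-default builds
#'   require databases in matching coordinates.
#' @param resources the resource list (gene models, class sets, priors, CNV
#'   regions, drug tables, TDS-indexed databases), e.g. from
#'   [make_patient()].
#' @param variant_model an `ensemble_svm_model` or archive path.
#' @param gene_model a `logistic_driver_model`, an archive path, or a named
#'   list of per-subtype models (with a `default` entry).
#' @param cutoff driver-call threshold (default 0.11).
#' @param out_prefix optional output path prefix for [write_outputs()].
#' @return list of class `run_config`.
#' @export
run_config <- function(profile = NULL, input = NULL,
                       format = c("vcf", "annovar"), sample = NULL,
                       bed_sv = NULL, subtype = NULL, build = "hg19",
                       resources, variant_model, gene_model,
                       cutoff = 0.11, out_prefix = NULL) {
  format <- match.arg(format)
  if (is.null(profile) && is.null(input))
    stop("configuration error: either profile or input must be given")
  for (p in c(input, bed_sv))
    if (!is.null(p) && !file.exists(p))
      stop("configuration error: missing input file ", p)
  if (is.character(variant_model))
    variant_model <- load_ensemble_model(variant_model)
  if (is.character(gene_model)) gene_model <- load_logistic_model(gene_model)
  needed <- c("predictor_db", "funseq_db", "gene_models", "census_set",
              "kegg_set", "suppressor_set", "oncogene_set", "cnv_regions",
              "prior_scores", "links", "interactions", "activity",
              "fda_table", "trial_table")
  missing <- setdiff(needed, names(resources))
  if (length(missing))
    stop("configuration error: resources lack ",
         paste(missing, collapse = ", "))
  structure(list(profile = profile, input = input, format = format,
                 sample = sample, bed_sv = bed_sv, subtype = subtype,
                 build = build, resources = resources,
                 variant_model = variant_model, gene_model = gene_model,
                 cutoff = cutoff, out_prefix = out_prefix),
            class = "run_config")
}

lookup_prior <- function(gene, prior_scores, subtype) {
  v <- prior_scores$prior[prior_scores$gene == gene &
                            prior_scores$subtype == subtype]
  if (length(v)) v[1] else 0
}

#' Run the full three-layer analysis for one patient
#'
#' Layer one scores every variant (coding points through the calibrated
#' radial SVM, non-coding points through the functional score database,
#' indels and structural variants through the CNV signal rules); layer two
#' assigns each variant to its closest gene, aggregates per-category score
#' maxima, attaches the phenotype prior and ranks genes by the logistic
#' driver probability; layer three expands driver-called genes to their top
#' pathway neighbors, queries role-filtered drug interactions and ranks
#' candidate drugs by the multiplicative joint score with regulatory tiers.
#'
#' @param config a [run_config()].
#' @return list with `mutations`, `genes`, `drugs` tables and the analyzed
#'   `profile`; tables are also written via [write_outputs()] when
#'   `out_prefix` is configured.
#' @export
run_patient <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- config$resources
  profile <- config$profile
  if (is.null(profile)) {
    profile <- if (config$format == "vcf")
      read_vcf_somatic(config$input, sample = config$sample,
                       genome_build = config$build)
    else read_annovar_input(config$input, genome_build = config$build)
  }
  if (!is.null(config$bed_sv)) {
    sv <- read_bed_structural(config$bed_sv)
    profile$variants <- rbind(profile$variants, sv)
  }
  subtype <- config$subtype
  if (is.null(subtype) || is.na(subtype)) subtype <- profile$cancer_subtype
  known <- unique(res$prior_scores$subtype)
  if (is.na(subtype) || !subtype %in% known) {
    fallback <- if (!is.null(res$default_subtype)) res$default_subtype
                else known[1]
    if (!is.na(subtype))
      warning("unknown subtype '", subtype, "'; falling back to '",
              fallback, "'")
    subtype <- fallback
  }
  gene_model <- config$gene_model
  if (is.list(gene_model) && !inherits(gene_model, "logistic_driver_model")) {
    gene_model <- if (subtype %in% names(gene_model)) gene_model[[subtype]]
                  else gene_model[["default"]]
  }

  # ---- layer 1: one score per variant -----------------------------------
  variants <- profile$variants
  scores <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$category %in% c("coding_point", "noncoding_point")) {
      fv <- annotate_coding(v, res$predictor_db, config$variant_model)
      if (is.null(fv)) {
        variants$category[i] <- "noncoding_point"
        scores[[i]] <- score_noncoding(variants[i, ], res$funseq_db)
      } else {
        variants$category[i] <- "coding_point"
        scores[[i]] <- list(
          variant = v, score_category = "radial_svm",
          value = score_coding(fv$values, config$variant_model))
      }
    } else if (v$category == "indel") {
      scores[[i]] <- score_indel(v, res$cnv_regions, res$suppressor_set,
                                 res$oncogene_set)
    } else {
      effect <- if (v$sv_kind == "deletion") "loss_of_function"
                else "gain_of_function"
      scores[[i]] <- score_structural(v, effect, res$cnv_regions,
                                      res$suppressor_set, res$oncogene_set)
    }
  }

  # ---- layer 2: gene assignment, aggregation, logistic ranking ----------
  assigned <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    hit <- assign_closest_gene(variants[i, ], res$gene_models)
    if (!is.null(hit)) assigned[i] <- hit$gene
  }
  variants$gene <- assigned

  mutations <- data.table(
    gene = assigned, chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt, category = variants$category,
    context = NA_character_, protein_context = NA_character_,
    score_category = vapply(scores, `[[`, character(1), "score_category"),
    score = vapply(scores, `[[`, numeric(1), "value"))

  keep <- !is.na(assigned)
  ev <- rbindlist(lapply(unique(assigned[keep]), function(g) {
    aggregate_gene(scores[which(assigned == g)], g,
                   phenolyzer = lookup_prior(g, res$prior_scores, subtype))
  }))
  genes <- rank_genes(ev, gene_model, cutoff = config$cutoff)
  genes$gene_category <- categorize_gene(genes$gene, res$census_set,
                                         res$kegg_set)

  # ---- layer 3: drug search over driver-called genes --------------------
  activity <- normalize_activity(res$activity)
  act_of <- setNames(activity$activity, activity$drug)
  cand_genes <- genes[genes$driver == TRUE, ]
  if (!nrow(cand_genes)) cand_genes <- genes[1, ]
  cands <- list()
  for (gi in seq_len(nrow(cand_genes))) {
    final <- cand_genes$gene[gi]
    gscore <- cand_genes$gene_score[gi]
    nbs <- top_neighbors(final, res$links, k = 4L)
    for (ni in seq_len(nrow(nbs))) {
      direct <- nbs$neighbor[ni]
      role <- classify_gene_role(direct, res$suppressor_set,
                                 res$oncogene_set)
      recs <- query_drugs(direct, role, res$interactions)
      if (!nrow(recs)) next
      cands[[length(cands) + 1L]] <- data.table(
        drug = unique(recs$drug), final_target = final,
        direct_target = direct, gene_score = gscore,
        relatedness = nbs$relatedness[ni])
    }
  }
  drugs <- if (length(cands)) {
    cand <- rbindlist(cands)
    cand$activity <- unname(act_of[cand$drug])
    cand$no_activity_data <- is.na(cand$activity)
    cand$activity[cand$no_activity_data] <- 0.5
    cand$drug_score <- cand$gene_score * cand$relatedness * cand$activity
    tiers <- rbindlist(lapply(unique(cand$drug), function(d)
      c(list(drug = d), assign_tier(d, res$fda_table, res$trial_table,
                                    patient_subtype = subtype))))
    cand <- merge(cand, tiers, by = "drug", sort = FALSE)
    rank_drugs(cand)
  }
           else data.table(drug = character(0), final_target = character(0),
                           direct_target = character(0),
                           gene_score = numeric(0), relatedness = numeric(0),
                           activity = numeric(0), drug_score = numeric(0),
                           tier = integer(0), brand = character(0),
                           subtypes = character(0),
                           trial_name = character(0),
                           trial_org = character(0),
                           trial_phase = character(0),
                           trial_url = character(0))

  if (!is.null(config$out_prefix))
    write_outputs(mutations, genes, drugs, config$out_prefix)
  list(mutations = mutations, genes = genes, drugs = drugs,
       profile = profile, subtype = subtype)
}
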