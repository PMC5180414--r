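# Synthetic resource generators. Everything the pipeline consumes --
# predictor databases, non-coding score tables, gene resources, drug tables,
# labeled training sets and toy patients -- can be generated at miniature
# scale from a seeded specification, so the package builds and tests
# end-to-end with no downloads. All outputs are deterministic functions of
# the spec seed.

#' Fixture generation specification
#'
#' @param seed RNG seed; a fixed seed yields byte-identical fixtures.
#' @param n_genes number of gene models (default 200).
#' @param n_variants_per_patient somatic mutation count per toy patient
#'   (default 129, one mutated gene each).
#' @param n_training_tp,n_training_tn labeled training mutation counts
#'   (default 1000 each).
#' @param class_separation shift (in latent standard deviations) between the
#'   driver-like and neutral-like predictor score distributions (default 2).
#' @param planted_lr_weights,planted_lr_bias the generating logistic model
#'   for gene-label simulation (defaults `c(2, 1, 1, 3)` and `-2`).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 200L,
                         n_variants_per_patient = 129L,
                         n_training_tp = 1000L, n_training_tn = 1000L,
                         class_separation = 2,
                         planted_lr_weights = c(2, 1, 1, 3),
                         planted_lr_bias = -2) {
  stopifnot(n_genes >= 1L, n_variants_per_patient >= 1L,
            n_training_tp >= 1L, n_training_tn >= 1L,
            length(planted_lr_weights) == 4L)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_variants_per_patient = as.integer(n_variants_per_patient),
                 n_training_tp = as.integer(n_training_tp),
                 n_training_tn = as.integer(n_training_tn),
                 class_separation = class_separation,
                 planted_lr_weights = planted_lr_weights,
                 planted_lr_bias = planted_lr_bias),
            class = "fixture_spec")
}

FIXTURE_CHROMS <- paste0("chr", 1:4)
BASES <- c("A", "C", "G", "T")

# map a shared latent deleteriousness value to each predictor's native scale
latent_to_predictors <- function(latent, loadings, noise) {
  n <- length(latent)
  raw <- sapply(seq_along(PREDICTOR_NAMES), function(j)
    loadings[j] * latent + noise[, j])
  colnames(raw) <- PREDICTOR_NAMES
  out <- data.table(
    sift = pnorm(raw[, "sift"]),
    polyphen2_humdiv = pnorm(raw[, "polyphen2_humdiv"]),
    lrt = pnorm(raw[, "lrt"]),
    mutation_taster = pnorm(raw[, "mutation_taster"]),
    mutation_assessor = pnorm(raw[, "mutation_assessor"]),
    fathmm = pnorm(raw[, "fathmm"]),
    gerp_pp = pmin(pmax(2.0 * raw[, "gerp_pp"], -12), 6),
    phylop = pmin(pmax(1.5 * raw[, "phylop"], -14), 10),
    cadd = pmin(pmax(15 + 8 * raw[, "cadd"], 0), 40),
    vest = pnorm(raw[, "vest"]),
    siphy = pmin(pmax(12 + 6 * raw[, "siphy"], 0), 37))
  out
}

#' Generate a sorted 11-predictor site database with labels and MMAF
#'
#' Driver-like (TP) sites draw their shared latent deleteriousness high,
#' neutral-like (TN) sites low; all eleven predictors load positively on the
#' latent factor plus independent noise, reproducing the mutually positively
#' correlated predictor structure of real pathogenicity scores. TP sites
#' carry a maximum population allele frequency of at most 0.01, TN sites of
#' at least 0.20.
#'
#' @param spec a [fixture_spec()].
#' @param path optional file to write the sorted, tab-delimited,
#'   headerless database to (columns: chrom, pos, ref, alt, the eleven
#'   predictors, mmaf).
#' @return list with `db` (the sorted `data.table`, including a `label`
#'   column that is not written to disk), and `path` if written.
#' @export
make_predictor_db <- function(spec, path = NULL) {
  set.seed(spec$seed)
  n_tp <- spec$n_training_tp; n_tn <- spec$n_training_tn
  n <- n_tp + n_tn
  label <- c(rep(1L, n_tp), rep(0L, n_tn))
  latent <- rnorm(n, mean = ifelse(label == 1L, spec$class_separation / 2,
                                   -spec$class_separation / 2), sd = 1)
  loadings <- runif(length(PREDICTOR_NAMES), 0.6, 1.0)
  noise <- matrix(rnorm(n * length(PREDICTOR_NAMES), sd = 0.8), nrow = n)
  preds <- latent_to_predictors(latent, loadings, noise)

  chrom <- sample(FIXTURE_CHROMS, n, replace = TRUE)
  pos <- integer(n)
  for (cc in FIXTURE_CHROMS) {
    idx <- which(chrom == cc)
    pos[idx] <- sample(1e4:2e6, length(idx), replace = FALSE)
  }
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  mmaf <- ifelse(label == 1L, runif(n, 0, 0.01), runif(n, 0.20, 0.50))

  db <- data.table(chrom = chrom, pos = pos, ref = ref, alt = alt)
  db <- cbind(db, preds)
  db$mmaf <- round(mmaf, 6)
  db$label <- label
  db <- db[order(match(db$chrom, FIXTURE_CHROMS), db$pos), ]
  for (nm in PREDICTOR_NAMES) db[[nm]] <- round(db[[nm]], 6)
  if (!is.null(path)) write_predictor_db(db, path)
  list(db = db[], path = path)
}

#' Write a predictor database table to its on-disk form
#'
#' Tab-delimited, headerless, sorted; the `label` column (if present) is
#' dropped. The result is directly indexable with [tds_build()].
#'
#' @param db the predictor `data.table`.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_predictor_db <- function(db, path) {
  out <- db[, intersect(PREDICTOR_DB_COLS, colnames(db)), with = FALSE]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Generate a sorted non-coding functional score database
#'
#' @param spec a [fixture_spec()].
#' @param n_sites number of scored sites (default 500).
#' @param max_score upper bound of the generated scores (default 0.5, so
#'   planted coding evidence dominates in scenario patients).
#' @param path optional file to write (`chrom`, `pos`, `score`, tab
#'   delimited, headerless, sorted).
#' @return list with `db` and `path`.
#' @export
make_funseq_db <- function(spec, n_sites = 500L, max_score = 0.5,
                           path = NULL) {
  set.seed(spec$seed + 101L)
  chrom <- sample(FIXTURE_CHROMS, n_sites, replace = TRUE)
  pos <- integer(n_sites)
  for (cc in FIXTURE_CHROMS) {
    idx <- which(chrom == cc)
    pos[idx] <- sample(1e4:2e6, length(idx))
  }
  db <- data.table(chrom = chrom, pos = pos,
                   score = round(runif(n_sites, 0, max_score), 6))
  db <- db[order(match(db$chrom, FIXTURE_CHROMS), db$pos), ]
  if (!is.null(path)) fwrite(db, path, sep = "\t", col.names = FALSE)
  list(db = db[], path = path)
}

#' Generate gene spans, gene-class sets, priors and CNV signal regions
#'
#' Gene spans are non-overlapping within each chromosome. Disjoint subsets
#' become tumor suppressors and oncogenes; deletion-signal regions are
#' placed inside suppressor spans and duplication-signal regions inside
#' oncogene spans, each with a normalized recurrence signal in `[0, 1]`.
#' Census and KEGG category sets and a per-subtype phenotype prior table
#' round out the resources.
#'
#' @param spec a [fixture_spec()].
#' @param subtypes subtype labels for the prior table
#'   (default `c("breast", "lung")`; the first is the fallback default).
#' @return list with `gene_models`, `suppressor_set`, `oncogene_set`,
#'   `census_set`, `kegg_set`, `prior_scores`, `cnv_regions`,
#'   `default_subtype`.
#' @export
make_gene_resources <- function(spec, subtypes = c("breast", "lung")) {
  set.seed(spec$seed + 202L)
  n <- spec$n_genes
  gene <- sprintf("GEN%04d", seq_len(n))
  chrom <- rep(FIXTURE_CHROMS, length.out = n)
  gm <- list()
  for (cc in FIXTURE_CHROMS) {
    idx <- which(chrom == cc)
    len <- sample(5e3:3e4, length(idx), replace = TRUE)
    gap <- sample(5e3:2e4, length(idx), replace = TRUE)
    start <- cumsum(gap) + c(0, cumsum(head(len, -1)))
    gm[[cc]] <- data.table(gene = gene[idx], chrom = cc,
                           start = as.integer(start),
                           end = as.integer(start + len - 1L))
  }
  gene_models <- rbindlist(gm)

  n_role <- max(1L, round(0.15 * n))
  roles <- sample(gene, min(2L * n_role, n))
  suppressor_set <- roles[seq_len(n_role)]
  oncogene_set <- setdiff(roles, suppressor_set)
  census_set <- sample(gene, max(1L, round(0.10 * n)))
  kegg_set <- sample(gene, max(1L, round(0.20 * n)))

  prior_scores <- rbindlist(lapply(subtypes, function(s)
    data.table(gene = gene, subtype = s,
               prior = round(stats::rbeta(n, 1, 6), 6))))

  region_of <- function(genes, kind) {
    gsel <- gene_models[gene_models$gene %in% genes, ]
    keep <- runif(nrow(gsel)) < 0.7
    gsel <- gsel[keep, ]
    if (!nrow(gsel)) return(data.table())
    w <- pmax(1L, as.integer((gsel$end - gsel$start) * runif(nrow(gsel),
                                                             0.3, 0.9)))
    st <- gsel$start + as.integer((gsel$end - gsel$start - w) *
                                    runif(nrow(gsel)))
    data.table(chrom = gsel$chrom, start = st, end = st + w,
               signal = round(runif(nrow(gsel)), 6), kind = kind,
               gene = gsel$gene)
  }
  cnv_regions <- rbindlist(list(region_of(suppressor_set, "deletion"),
                                region_of(oncogene_set, "duplication")))

  list(gene_models = gene_models, suppressor_set = suppressor_set,
       oncogene_set = oncogene_set, census_set = census_set,
       kegg_set = kegg_set, prior_scores = prior_scores,
       cnv_regions = cnv_regions, default_subtype = subtypes[1])
}

#' Generate drug-layer resources
#'
#' Pathway-neighbor links with normalized relatedness, a drug-gene
#' interaction table with role-plausible vocabulary terms, per-drug assay
#' activity scores, and FDA/clinical-trial membership lists.
#'
#' @param spec a [fixture_spec()].
#' @param gene_resources output of [make_gene_resources()].
#' @param n_drugs number of synthetic drugs (default 40).
#' @return list with `links`, `interactions`, `activity`, `fda_table`,
#'   `trial_table`.
#' @export
make_drug_resources <- function(spec, gene_resources, n_drugs = 40L) {
  set.seed(spec$seed + 303L)
  genes <- gene_resources$gene_models$gene
  drugs <- sprintf("DRUG%03d", seq_len(n_drugs))

  links <- rbindlist(lapply(genes, function(g) {
    nb <- sample(setdiff(genes, g), min(6L, length(genes) - 1L))
    data.table(gene = g, neighbor = nb,
               relatedness = round(runif(length(nb)), 6))
  }))

  all_terms <- unique(c(SUPPRESSOR_TERMS, ONCOGENE_TERMS,
                        "binder", "modulator", "cofactor"))
  interactions <- data.table(
    drug = sample(drugs, 3L * n_drugs, replace = TRUE),
    gene = sample(genes, 3L * n_drugs, replace = TRUE),
    term = sample(all_terms, 3L * n_drugs, replace = TRUE),
    source = "curated-db")
  interactions <- unique(interactions, by = c("drug", "gene"))

  activity <- rbindlist(lapply(drugs, function(d) {
    k <- sample(3:8, 1)
    data.table(drug = d, assay_score = round(runif(k, 0, 100), 3))
  }))

  fda_idx <- sample(n_drugs, max(1L, round(0.25 * n_drugs)))
  fda_table <- data.table(
    drug = drugs[fda_idx],
    brand = paste0("BRAND", sprintf("%03d", fda_idx)),
    subtypes = sample(c("breast", "lung", "renal cancer"),
                      length(fda_idx), replace = TRUE))
  trial_idx <- sample(setdiff(seq_len(n_drugs), fda_idx),
                      max(1L, round(0.25 * n_drugs)))
  trial_table <- data.table(
    drug = drugs[trial_idx],
    trial_name = paste0("Phase II study of ", drugs[trial_idx]),
    trial_org = "SYNTHETIC TRIALS GROUP",
    trial_phase = sample(1:3, length(trial_idx), replace = TRUE),
    trial_url = paste0("http://trials.example.org/", drugs[trial_idx]))

  list(links = links, interactions = interactions, activity = activity,
       fda_table = fda_table, trial_table = trial_table)
}

#' Simulate a labeled gene set from the planted logistic model
#'
#' Features are uniform on `[0, 1]^4`; labels are Bernoulli draws from the
#' sigmoid of the planted linear predictor, enabling parameter-recovery
#' checks of [train_logistic()].
#'
#' @param spec a [fixture_spec()].
#' @param n number of genes to simulate (default 5000).
#' @return list with `features` (a 4-column `data.table`), `labels`, and
#'   the planted `w`/`b`.
#' @export
make_labeled_gene_set <- function(spec, n = 5000L) {
  set.seed(spec$seed + 404L)
  X <- matrix(runif(n * 4L), n, 4L,
              dimnames = list(NULL, c("max_radial_svm", "max_funseq2",
                                      "max_cnv_signal", "phenolyzer")))
  eta <- drop(X %*% spec$planted_lr_weights) + spec$planted_lr_bias
  p <- 1 / (1 + exp(-eta))
  labels <- rbinom(n, 1L, p)
  list(features = as.data.table(X), labels = labels,
       w = spec$planted_lr_weights, b = spec$planted_lr_bias)
}

#' Generate a toy patient with matched annotation resources
#'
#' The `araf_like` scenario plants, among `n_variants_per_patient` mutated
#' genes, one gene carrying a maximally deleterious coding mutation and a
#' high phenotype prior, plus one FDA-approved, maximum-activity drug
#' directly targeting it -- so the planted gene should emerge at rank 1 of
#' the gene table and the planted drug at rank 1 of the drug table. The
#' `generic` scenario draws all variants uniformly.
#'
#' All databases are written (and TDS-indexed) under `dir`, and every file
#' parses through the production readers.
#'
#' @param spec a [fixture_spec()].
#' @param scenario `"araf_like"` or `"generic"`.
#' @param dir directory for the generated database files (default a fresh
#'   temporary directory).
#' @return list with `profile` (a [patient_profile()]), `resources` (the
#'   list consumed by [run_patient()]), `planted` (`gene`, `drug`; `NULL`
#'   for the generic scenario) and `training` (the predictor table with
#'   labels, for model fitting).
#' @export
make_patient <- function(spec, scenario = c("araf_like", "generic"),
                         dir = tempfile("fixtures")) {
  scenario <- match.arg(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  gene_res <- make_gene_resources(spec)
  drug_res <- make_drug_resources(spec, gene_res)
  pdb <- make_predictor_db(spec)
  fdb <- make_funseq_db(spec)
  db <- pdb$db

  set.seed(spec$seed + 505L)
  nvar <- spec$n_variants_per_patient
  genes <- gene_res$gene_models
  if (nvar > nrow(genes))
    stop("n_variants_per_patient exceeds the number of gene models")
  mut_genes <- sort(sample(genes$gene, nvar))
  planted <- NULL

  site_in_gene <- function(g) {
    row <- genes[genes$gene == g, ]
    list(chrom = row$chrom,
         pos = as.integer(row$start +
                            floor((row$end - row$start) * runif(1))))
  }

  extra_rows <- list(); variants <- list()
  if (scenario == "araf_like") {
    planted_gene <- mut_genes[1]
    site <- site_in_gene(planted_gene)
    ref <- "C"; alt <- "G"
    # a fresh maximally deleterious database row at the planted site
    top <- db[db$label == 1L, ][which.max(db[db$label == 1L, ]$sift), ]
    prow <- copy(top)
    prow$chrom <- site$chrom; prow$pos <- site$pos
    prow$ref <- ref; prow$alt <- alt
    for (nm in TRANSFORMED_PREDICTORS) prow[[nm]] <- 0.999
    prow$gerp_pp <- 6; prow$phylop <- 10; prow$cadd <- 40
    prow$vest <- 0.999; prow$siphy <- 37; prow$mmaf <- 0
    extra_rows[[length(extra_rows) + 1L]] <- prow
    variants[[length(variants) + 1L]] <- data.table(
      chrom = site$chrom, pos = site$pos, end = site$pos, ref = ref,
      alt = alt, category = "coding_point", sv_kind = "none",
      gene = NA_character_)

    # planted prior and a planted on-target tier-1 drug
    gene_res$prior_scores[gene_res$prior_scores$gene == planted_gene,
                          "prior"] <- 0.9
    gene_res$prior_scores[gene_res$prior_scores$gene != planted_gene &
                            gene_res$prior_scores$prior > 0.3,
                          "prior"] <- 0.3
    gene_res$oncogene_set <- union(
      setdiff(gene_res$oncogene_set, character(0)), planted_gene)
    gene_res$suppressor_set <- setdiff(gene_res$suppressor_set, planted_gene)
    planted_drug <- "TARGETINIB"
    drug_res$interactions <- rbind(
      drug_res$interactions[drug_res$interactions$gene != planted_gene, ],
      data.table(drug = planted_drug, gene = planted_gene,
                 term = "inhibitor", source = "curated-db"))
    amax <- max(drug_res$activity$assay_score) + 10
    drug_res$activity <- rbind(
      drug_res$activity,
      data.table(drug = planted_drug, assay_score = rep(amax, 3)))
    drug_res$fda_table <- rbind(
      drug_res$fda_table,
      data.table(drug = planted_drug, brand = "TARGETRA",
                 subtypes = "breast"))
    # keep competing CNV evidence below the planted gene's feature level
    if (nrow(gene_res$cnv_regions))
      gene_res$cnv_regions$signal <- pmin(gene_res$cnv_regions$signal, 0.6)
    planted <- list(gene = planted_gene, drug = planted_drug)
    rest <- mut_genes[-1]
  } else {
    rest <- mut_genes
  }

  # remaining mutated genes: mostly neutral-like coding points, some
  # non-coding points and a few structural variants / indels
  n_rest <- length(rest)
  n_nc <- round(0.15 * n_rest); n_sv <- round(0.08 * n_rest)
  kinds <- sample(c(rep("coding", n_rest - n_nc - n_sv),
                    rep("noncoding", n_nc), rep("sv", n_sv)))
  tn_pool <- which(db$label == 0L)
  fdb_tab <- fdb$db
  for (i in seq_len(n_rest)) {
    g <- rest[i]
    site <- site_in_gene(g)
    if (kinds[i] == "coding") {
      src <- db[sample(tn_pool, 1), ]
      row <- copy(src)
      row$chrom <- site$chrom; row$pos <- site$pos
      extra_rows[[length(extra_rows) + 1L]] <- row
      variants[[length(variants) + 1L]] <- data.table(
        chrom = site$chrom, pos = site$pos, end = site$pos, ref = row$ref,
        alt = row$alt, category = "coding_point", sv_kind = "none",
        gene = NA_character_)
    } else if (kinds[i] == "noncoding") {
      # a site absent from the predictor db: routed to the non-coding scorer
      fdb_tab <- rbind(fdb_tab, data.table(
        chrom = site$chrom, pos = site$pos,
        score = round(runif(1, 0, 0.5), 6)))
      ref <- sample(BASES, 1)
      variants[[length(variants) + 1L]] <- data.table(
        chrom = site$chrom, pos = site$pos, end = site$pos, ref = ref,
        alt = sample(setdiff(BASES, ref), 1), category = "coding_point",
        sv_kind = "none", gene = NA_character_)
    } else {
      kind <- sample(c("deletion", "duplication"), 1)
      w <- sample(1000:20000, 1)
      variants[[length(variants) + 1L]] <- data.table(
        chrom = site$chrom, pos = site$pos,
        end = site$pos + w, ref = "N",
        alt = if (kind == "deletion") "<DEL>" else "<DUP>",
        category = "structural", sv_kind = kind, gene = NA_character_)
    }
  }

  # assemble and write the databases (dropping duplicate sites)
  db_full <- rbind(db, rbindlist(extra_rows))
  db_full <- db_full[!duplicated(db_full[, c("chrom", "pos")],
                                 fromLast = TRUE), ]
  db_full <- db_full[order(match(db_full$chrom, FIXTURE_CHROMS),
                           db_full$pos), ]
  fdb_tab <- fdb_tab[!duplicated(fdb_tab[, c("chrom", "pos")],
                                 fromLast = TRUE), ]
  fdb_tab <- fdb_tab[order(match(fdb_tab$chrom, FIXTURE_CHROMS),
                           fdb_tab$pos), ]

  pdb_path <- file.path(dir, "predictors.tsv")
  write_predictor_db(db_full, pdb_path)
  fdb_path <- file.path(dir, "noncoding_scores.tsv")
  fwrite(fdb_tab, fdb_path, sep = "\t", col.names = FALSE)

  resources <- c(gene_res, drug_res)
  resources$predictor_db <- tds_build(pdb_path)
  resources$funseq_db <- tds_build(fdb_path)

  vt <- validate_variant_table(rbindlist(variants))
  profile <- patient_profile("TOY001", vt, cancer_subtype = "breast")
  training <- db[, c(PREDICTOR_NAMES, "label"), with = FALSE]

  list(profile = profile, resources = resources, planted = planted,
       training = training, dir = dir)
}
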