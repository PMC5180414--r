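# Layer two: map variant scores to genes, take per-category maxima, attach
# the phenotype prior, and convert the four features into a driver
# probability with the logistic model.

#' Assign a variant to its closest gene
#'
#' Distance is 0 when the position lies within a gene span, otherwise the
#' smallest gap to a span boundary; ties break lexicographically by symbol.
#'
#' @param variant one-row variant record table.
#' @param gene_models `data.table` with `gene`, `chrom`, `start`, `end`.
#' @return list with `gene` and `distance`, or `NULL` (with a warning) when
#'   the chromosome carries no genes.
#' @export
assign_closest_gene <- function(variant, gene_models) {
  g <- gene_models[gene_models$chrom == variant$chrom, ]
  if (!nrow(g)) {
    warning("no gene models on chromosome ", variant$chrom,
            "; variant left unassigned")
    return(NULL)
  }
  # gap between [pos, end] and each span; 0 when overlapping
  d <- pmax(g$start - variant$end, variant$pos - g$end, 0L)
  best <- min(d)
  cand <- sort(g$gene[d == best])
  list(gene = cand[1], distance = as.integer(best))
}

#' Aggregate variant scores into per-gene evidence
#'
#' For one gene, takes the maximum score within each score category; a
#' category with no variant contributes 0.
#'
#' @param scores list of variant score lists (as returned by the layer-one
#'   scorers), all belonging to the same gene.
#' @param gene the gene symbol.
#' @param phenolyzer phenotype-prior score in `[0, 1]` (default 0).
#' @return a one-row `data.table` of gene evidence.
#' @export
aggregate_gene <- function(scores, gene, phenolyzer = 0) {
  if (!length(scores)) stop("cannot aggregate a gene with no variant scores")
  cat_of <- vapply(scores, `[[`, character(1), "score_category")
  val_of <- vapply(scores, `[[`, numeric(1), "value")
  mx <- function(cat) {
    v <- val_of[cat_of == cat]
    if (length(v)) max(v) else 0
  }
  data.table(gene = gene,
             max_radial_svm = mx("radial_svm"),
             max_funseq2 = mx("funseq2"),
             max_cnv_signal = mx("cnv_signal"),
             phenolyzer = phenolyzer)
}

#' Driver probability of a gene under the logistic model
#'
#' Evaluates `h(x) = 1 / (1 + exp(-(w'x + b)))` on the feature vector
#' `x = (max radial SVM, max FunSeq2, max CNV signal, phenotype prior)`.
#'
#' @param evidence one-row gene evidence table (from [aggregate_gene()]) or
#'   a numeric 4-vector in that order.
#' @param model a `logistic_driver_model`.
#' @return driver probability in `(0, 1)`.
#' @export
gene_driver_score <- function(evidence, model) {
  if (!inherits(model, "logistic_driver_model"))
    stop("model is not a fitted logistic_driver_model")
  x <- if (is.numeric(evidence)) evidence
       else unlist(evidence[, c("max_radial_svm", "max_funseq2",
                                "max_cnv_signal", "phenolyzer")])
  if (length(x) != length(model$w))
    stop("evidence has ", length(x), " features; model expects ",
         length(model$w))
  1 / (1 + exp(-(sum(model$w * x) + model$b)))
}

#' Binary driver call at the recommended cutoff
#'
#' @param score driver probability in `[0, 1]`.
#' @param cutoff decision threshold (default 0.11); the boundary is
#'   inclusive, so `score == cutoff` calls a driver.
#' @return logical driver call.
#' @export
call_driver <- function(score, cutoff = 0.11) {
  stopifnot(all(score >= 0 & score <= 1))
  score >= cutoff
}

#' Categorize a gene by curated cancer-gene resources
#'
#' Cancer Gene Census membership takes precedence over the KEGG cancer
#' pathway; genes in neither are `"other"`.
#'
#' @param gene gene symbol.
#' @param census_set,kegg_set character vectors of member symbols.
#' @return one of `"cancer_gene_census"`, `"kegg_cancer_pathway"`,
#'   `"other"`.
#' @export
categorize_gene <- function(gene, census_set, kegg_set) {
  ifelse(gene %in% census_set, "cancer_gene_census",
         ifelse(gene %in% kegg_set, "kegg_cancer_pathway", "other"))
}

#' Score and rank per-gene evidence
#'
#' Attaches the driver probability and call to each evidence row and orders
#' genes by descending score, breaking ties by descending maximum radial SVM
#' score and then by symbol.
#'
#' @param evidence gene evidence table (rows as from [aggregate_gene()]).
#' @param model a `logistic_driver_model`.
#' @param cutoff driver-call threshold (default the model's).
#' @return the evidence table with `gene_score` and `driver` columns, ranked.
#' @export
rank_genes <- function(evidence, model, cutoff = model$cutoff) {
  evidence <- as.data.table(evidence)
  if (!nrow(evidence)) stop("no genes to rank")
  evidence$gene_score <- vapply(seq_len(nrow(evidence)), function(i)
    gene_driver_score(evidence[i, ], model), numeric(1))
  evidence$driver <- call_driver(evidence$gene_score, cutoff)
  evidence[order(-evidence$gene_score, -evidence$max_radial_svm,
                 evidence$gene), ]
}
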