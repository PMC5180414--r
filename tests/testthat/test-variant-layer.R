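# a miniature predictor database written through the production writer
local_predictor_db <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  db <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(1234560L, 1234560L, 777L),
    ref = c("C", "C", "A"), alt = c("G", "T", "T"))
  for (nm in PREDICTOR_NAMES) db[[nm]] <- c(0.9, 0.5, 0.2)
  db$gerp_pp <- c(5, 0, -3); db$phylop <- c(8, 1, -2)
  db$cadd <- c(35, 20, 5); db$siphy <- c(30, 15, 4)
  db$fathmm[3] <- NA # missing predictor -> imputed
  db$mmaf <- c(0.001, 0.001, 0.3)
  path <- file.path(dir, "pred.tsv")
  write_predictor_db(db, path)
  tds_build(path)
}

test_that("coding annotation: exact-allele hit, miss, and imputation", {
  idx <- local_predictor_db()
  vm <- shared_variant_model()

  hit <- variant_table("chr1", 1234560L, ref = "C", alt = "G")
  fv <- annotate_coding(hit, idx, vm)
  expect_length(fv$values, 11L)
  expect_equal(fv$missing_mask, character(0))
  expect_true(all(fv$values >= 0 & fv$values <= 1))
  expect_named(fv$values, vm$feature_order)

  # site absent entirely -> NULL (router sends it to the non-coding scorer)
  absent <- variant_table("chr9", 42L, ref = "A", alt = "C")
  expect_null(annotate_coding(absent, idx, vm))

  # position hit but allele miss -> warning + NULL
  miss <- variant_table("chr1", 1234560L, ref = "C", alt = "A")
  expect_warning(res <- annotate_coding(miss, idx, vm), "allele")
  expect_null(res)

  # missing FATHMM is imputed with the training median and flagged
  imput <- variant_table("chr2", 777L, ref = "A", alt = "T")
  fv2 <- annotate_coding(imput, idx, vm)
  expect_equal(fv2$missing_mask, "fathmm")
  expect_equal(unname(fv2$values["fathmm"]),
               unname(vm$training_medians["fathmm"]))
})

test_that("non-coding lookup returns the stored score, 0 when absent", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "nc.tsv")
  writeLines(c("chr1\t500\t0.8", "chr1\t900\t1.7"), path)
  idx <- tds_build(path)
  v <- variant_table("chr1", 500L, ref = "A", alt = "G",
                     category = "noncoding_point")
  expect_equal(score_noncoding(v, idx)$value, 0.8)
  expect_equal(score_noncoding(v, idx)$score_category, "funseq2")
  # out-of-range stored value is clamped into [0, 1]
  v2 <- variant_table("chr1", 900L, ref = "A", alt = "G",
                      category = "noncoding_point")
  expect_equal(score_noncoding(v2, idx)$value, 1)
  v3 <- variant_table("chr1", 123L, ref = "A", alt = "G",
                      category = "noncoding_point")
  expect_equal(score_noncoding(v3, idx)$value, 0)
})

cnv_fixture <- function() {
  list(
    regions = data.table::data.table(
      chrom = c("chr1", "chr1", "chr1", "chr2"),
      start = c(100L, 150L, 400L, 100L),
      end = c(300L, 350L, 600L, 200L),
      signal = c(0.4, 0.9, 0.7, 0.8),
      kind = c("deletion", "deletion", "deletion", "duplication"),
      gene = c("TSG1", "TSG2", "TSG3", "ONC1")),
    suppressors = c("TSG1", "TSG2", "TSG3"),
    oncogenes = "ONC1")
}

test_that("structural scoring follows the role-matched region rules", {
  fx <- cnv_fixture()
  del <- variant_table("chr1", 420L, end = 500L, ref = "N", alt = "<DEL>",
                       category = "structural", sv_kind = "deletion")
  s <- score_structural(del, "loss_of_function", fx$regions,
                        fx$suppressors, fx$oncogenes)
  expect_equal(s$value, 0.7)
  expect_equal(s$score_category, "cnv_signal")

  # no qualifying overlap scores 0, not an error
  del2 <- variant_table("chr1", 5000L, end = 5100L, ref = "N",
                        alt = "<DEL>", category = "structural",
                        sv_kind = "deletion")
  expect_equal(score_structural(del2, "loss_of_function", fx$regions,
                                fx$suppressors, fx$oncogenes)$value, 0)

  # two overlapping suppressor regions -> the maximum; order-independent
  del3 <- variant_table("chr1", 140L, end = 360L, ref = "N", alt = "<DEL>",
                        category = "structural", sv_kind = "deletion")
  s3 <- score_structural(del3, "loss_of_function", fx$regions,
                         fx$suppressors, fx$oncogenes)
  expect_equal(s3$value, 0.9)
  shuf <- fx$regions[c(4, 2, 3, 1), ]
  expect_equal(score_structural(del3, "loss_of_function", shuf,
                                fx$suppressors, fx$oncogenes)$value, 0.9)

  # effect direction inconsistent with sv_kind is an error
  expect_error(score_structural(del, "gain_of_function", fx$regions,
                                fx$suppressors, fx$oncogenes),
               "inconsistent")
})

test_that("indels take the more deleterious of the two effect branches", {
  fx <- cnv_fixture()
  # overlaps the suppressor deletion region (0.4) on chr1
  ind <- variant_table("chr1", 120L, end = 130L, ref = "AAG", alt = "A",
                       category = "indel")
  s <- score_indel(ind, fx$regions, fx$suppressors, fx$oncogenes)
  expect_equal(s$value, 0.4)
  lof <- score_structural(ind, "loss_of_function", fx$regions,
                          fx$suppressors, fx$oncogenes)$value
  gof <- score_structural(ind, "gain_of_function", fx$regions,
                          fx$suppressors, fx$oncogenes)$value
  expect_gte(s$value, lof); expect_gte(s$value, gof)
  expect_true(s$value %in% c(lof, gof))

  # overlapping suppressor(0.4) and oncogene(0.8) territory picks 0.8
  both <- cnv_fixture()
  both$regions$chrom <- "chr1"
  both$regions$start <- c(100L, 900L, 900L, 110L)
  both$regions$end <- c(300L, 950L, 950L, 290L)
  s2 <- score_indel(ind, both$regions, both$suppressors, both$oncogenes)
  expect_equal(s2$value, 0.8)

  none <- variant_table("chr3", 10L, end = 12L, ref = "A", alt = "-",
                        category = "indel")
  expect_equal(score_indel(none, fx$regions, fx$suppressors,
                           fx$oncogenes)$value, 0)
})

test_that("MMAF filtering applies the role thresholds and TP/TN exclusion", {
  tp <- data.table::data.table(
    chrom = "chr1", pos = 1:3, ref = "A", alt = "G",
    mmaf = c(0.005, 0.01, 0.011))
  expect_equal(mmaf_filter(tp, "tp")$mmaf, c(0.005, 0.01))
  tn <- data.table::data.table(
    chrom = "chr1", pos = 4:5, ref = "A", alt = "G", mmaf = c(0.19, 0.20))
  expect_equal(mmaf_filter(tn, "tn")$mmaf, 0.20)

  # a mutation in both candidate sets stays TN and leaves TP
  shared <- data.table::data.table(chrom = "chr1", pos = 1L, ref = "A",
                                   alt = "G", mmaf = 0.005)
  kept_tp <- mmaf_filter(tp, "tp", other = shared)
  expect_false(1L %in% kept_tp$pos)

  bad <- data.table::data.table(chrom = "chr1", pos = 1L, ref = "A",
                                alt = "G", mmaf = 1.2)
  expect_error(mmaf_filter(bad, "tp"), "\\[0, 1\\]")
})
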