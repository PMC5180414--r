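test_that("5-column input parses, infers categories, and rejects bad lines", {
  f <- withr::local_tempfile()
  writeLines(c("1 1234560 1234560 C G",
               "1 100 100 A -",
               "chr2\t500\t502\tATG\tA"), f)
  prof <- read_annovar_input(f)
  v <- prof$variants
  expect_equal(nrow(v), 3L)
  expect_equal(v$chrom[1], "1")
  expect_equal(v$pos[1], 1234560L)
  expect_equal(v$ref[1], "C")
  expect_equal(v$alt[1], "G")
  expect_equal(v$category, c("coding_point", "indel", "indel"))

  bad <- withr::local_tempfile()
  writeLines(c("1 10 10 A G", "1 20 20"), bad)
  expect_error(read_annovar_input(bad), "line 2")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(read_annovar_input(empty), "empty input")
})

write_test_vcf <- function(path, samples = "S1", rows) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##INFO=<ID=GERMLINE,Number=0,Type=Flag,Description=\"G\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
}

test_that("VCF reading selects samples, splits alleles, drops germline", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, samples = c("S1", "S2", "S3"), rows = c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/1",
    "1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t1/2\t0/0",
    "1\t300\t.\tG\tA\t.\tGERMLINE\t.\tGT\t0/1\t0/1\t0/1",
    "1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0"))
  expect_error(read_vcf_somatic(f), "sample")
  expect_error(read_vcf_somatic(f, sample = "NOPE"), "not present")

  p2 <- read_vcf_somatic(f, sample = "S2")
  # S2 carries both ALT alleles at pos 200 and the (germline) 300 and 400
  expect_equal(p2$variants$pos, c(200L, 200L, 400L))
  expect_equal(p2$variants$alt, c("T", "G", "C"))

  p1 <- read_vcf_somatic(f, sample = "S1")
  expect_equal(p1$variants$pos, 100L)
})

test_that("VCF symbolic SV alleles map to structural records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, rows = c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "2\t500\t.\tN\t<DEL>\t.\tPASS\tEND=1500\tGT\t0/1",
    "2\t2000\t.\tN\t<DUP>\t.\tPASS\tEND=2600\tGT\t0/1"))
  prof <- suppressMessages(read_vcf_somatic(f))
  v <- prof$variants
  expect_equal(v$category, c("coding_point", "structural", "structural"))
  expect_equal(v$sv_kind, c("none", "deletion", "duplication"))
  expect_equal(v$end[2], 1500L)
})

test_that("BED structural input converts coordinates and validates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tdeletion",
               "chr1\t0\t10\tduplication"), f)
  v <- read_bed_structural(f)
  expect_equal(v$pos, c(100L, 1L))
  expect_equal(v$end, c(200L, 10L))
  expect_equal(v$sv_kind, c("deletion", "duplication"))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t200\t100\tdeletion", bad)
  expect_error(read_bed_structural(bad), "invalid interval")
  bad2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tinversion", bad2)
  expect_error(read_bed_structural(bad2), "unknown structural kind")
})

test_that("outputs serialize with the fixed headers and round-trip", {
  mut <- data.table::data.table(
    gene = "ARAF", chrom = "1", pos = 1234560L, ref = "C", alt = "G",
    category = "coding_point", context = "c.641C > G",
    protein_context = "p.S214C", score_category = "radial_svm",
    score = 0.932)
  gen <- data.table::data.table(
    gene = "ARAF", gene_category = "kegg_cancer_pathway",
    max_radial_svm = 0.932, max_funseq2 = 0, max_cnv_signal = 0,
    phenolyzer = 0.306, gene_score = 0.484)
  drg <- data.table::data.table(
    drug = "SORAFENIB", final_target = "ARAF", direct_target = "ARAF",
    gene_score = 0.484, relatedness = 1, activity = 1, drug_score = 0.484,
    tier = 1L, brand = "NEXAVAR", subtypes = "renal cancer",
    trial_name = NA_character_, trial_org = NA_character_,
    trial_phase = NA_character_, trial_url = NA_character_)
  prefix <- file.path(withr::local_tempdir(), "out")
  tabs <- write_outputs(mut, gen, drg, prefix)

  m <- data.table::fread(paste0(prefix, ".mutations.csv"),
                         colClasses = "character")
  expect_equal(names(m), oncotriad:::MUTATION_CSV_COLS)
  expect_equal(m[["Driver mutation score"]], "0.932")
  expect_equal(m[["Score category"]], "Radial SVM")
  g <- data.table::fread(paste0(prefix, ".genes.csv"),
                         colClasses = "character")
  expect_equal(g[["Driver gene score"]], "0.484")
  d <- data.table::fread(paste0(prefix, ".drugs.csv"),
                         colClasses = "character")
  expect_equal(d[["Tier"]], "1")
  expect_equal(d[["Clinical trial name"]], ".")

  # JSON mirror carries the same information as the three CSV tables
  j <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(as.data.frame(j$mutations), as.data.frame(tabs$mutations))
  expect_equal(as.data.frame(j$genes), as.data.frame(tabs$genes))
  expect_equal(as.data.frame(j$drugs), as.data.frame(tabs$drugs))

  # byte-for-byte stability of a rewrite (golden determinism)
  prefix2 <- file.path(withr::local_tempdir(), "out")
  write_outputs(mut, gen, drg, prefix2)
  for (suf in c(".mutations.csv", ".genes.csv", ".drugs.csv", ".json"))
    expect_identical(readLines(paste0(prefix, suf)),
                     readLines(paste0(prefix2, suf)))

  # empty drug table -> header-only CSV
  prefix3 <- file.path(withr::local_tempdir(), "out")
  write_outputs(mut, gen, drg[0L, ], prefix3)
  expect_equal(readLines(paste0(prefix3, ".drugs.csv")),
               paste(oncotriad:::DRUG_CSV_COLS, collapse = ","))
})
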