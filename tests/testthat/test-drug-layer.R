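test_that("gene role classification with conflict downgrade", {
  expect_equal(classify_gene_role("PTEN", "PTEN", "MTOR"),
               "tumor_suppressor")
  expect_equal(classify_gene_role("MTOR", "PTEN", "MTOR"), "oncogene")
  expect_equal(classify_gene_role("XYZ", "PTEN", "MTOR"), "other")
  expect_warning(r <- classify_gene_role("DUAL", c("DUAL"), c("DUAL")),
                 "both")
  expect_equal(r, "other")
})

test_that("top neighbors: self first at 1.0, then k best, ties by name", {
  links <- data.table::data.table(
    gene = "ARAF",
    neighbor = c("N1", "N2", "N3", "N4", "N5", "N6"),
    relatedness = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  nb <- top_neighbors("ARAF", links, k = 4)
  expect_equal(nb$neighbor, c("ARAF", "N1", "N2", "N3", "N4"))
  expect_equal(nb$relatedness[1], 1.0)
  expect_true(all(diff(nb$relatedness) <= 0))

  # ties at rank k break lexicographically
  links2 <- data.table::data.table(
    gene = "G", neighbor = c("BB", "AA", "CC"),
    relatedness = c(0.5, 0.5, 0.9))
  nb2 <- top_neighbors("G", links2, k = 2)
  expect_equal(nb2$neighbor, c("G", "CC", "AA"))

  # fewer than k neighbors returns all of them
  expect_equal(nrow(top_neighbors("G", links2[1:2, ], k = 4)), 3L)
  expect_equal(nrow(top_neighbors("LONER", links2, k = 4)), 1L)
})

interaction_fixture <- function() {
  data.table::data.table(
    drug = paste0("D", 1:6),
    gene = "G1",
    term = c("inhibitor", "activator", "stimulator", "vaccine",
             "binder", "inhibitor"),
    source = c(rep("curated-db", 5), "fda-list"))
}

test_that("role-specific term filtering is exhaustive and exclusive", {
  rec <- interaction_fixture()
  sup <- query_drugs("G1", "tumor_suppressor", rec)
  expect_setequal(sup$drug, c("D2", "D3", "D6")) # activating + fda-list
  onc <- query_drugs("G1", "oncogene", rec)
  expect_setequal(onc$drug, c("D1", "D4", "D6")) # inhibiting + fda-list
  oth <- query_drugs("G1", "other", rec)
  expect_equal(nrow(oth), nrow(rec))

  # inclusion depends only on (role, term, source): the curated-db split is
  # a partition for each directional role
  curated <- rec[rec$source == "curated-db", ]
  for (role in c("tumor_suppressor", "oncogene")) {
    inc <- query_drugs("G1", role, curated)$term
    exc <- setdiff(curated$term, inc)
    expect_setequal(c(inc, exc), curated$term)
  }
  expect_equal(nrow(query_drugs("NOPE", "other", rec)), 0L)
})

test_that("activity normalization: outlier trim, min-max, degenerate range", {
  raw <- data.table::data.table(
    drug = rep(c("A", "B", "C"), each = 2),
    assay_score = c(10, 10, 20, 20, 30, 30))
  act <- normalize_activity(raw)
  expect_equal(act$activity[match(c("A", "B", "C"), act$drug)],
               c(0, 0.5, 1))

  expect_equal(normalize_activity(
    data.table::data.table(drug = "X", assay_score = 7))$activity, 1)

  # an extreme assay outlier is trimmed before averaging
  out <- data.table::data.table(
    drug = c(rep("A", 5), "B"),
    assay_score = c(10, 11, 9, 10, 1000, 20))
  act2 <- normalize_activity(out)
  a_mean <- mean(c(10, 11, 9, 10))
  expect_equal(act2$activity[act2$drug == "A"], 0)
  expect_equal(act2$n_assays[act2$drug == "A"], 4L)
  expect_lt(a_mean, 20)
  expect_error(normalize_activity(out[0, ]), "no assay")
})

test_that("drug score is the product of the three probabilities", {
  expect_equal(score_drug(0.484, 1.000, 1.000), 0.484)
  expect_equal(score_drug(0.7, 0, 0.9), 0)
  expect_equal(score_drug(0.5, 0.5, 0.5), 0.125)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(3)
    s <- score_drug(p[1], p[2], p[3])
    expect_lte(s, min(p))
  }
  expect_error(score_drug(1.5, 1, 1), "\\[0, 1\\]")
  expect_error(score_drug(0.5, -0.1, 1), "\\[0, 1\\]")
})

tier_fixture <- function() {
  list(
    fda = data.table::data.table(
      drug = "SORAFENIB", brand = "NEXAVAR",
      subtypes = "hepatocellular carcinoma, renal cancer, thyroid cancer"),
    trials = data.table::data.table(
      drug = c("SORAFENIB", "NEWDRUG"),
      trial_name = c("phase II thyroid study", "first-in-human"),
      trial_org = c("ORG1", "ORG2"), trial_phase = c("2", "1"),
      trial_url = c("http://t/1", "http://t/2")))
}

test_that("tier assignment: FDA beats trials, trials beat neither", {
  fx <- tier_fixture()
  t1 <- assign_tier("SORAFENIB", fx$fda, fx$trials)
  expect_equal(t1$tier, 1L)
  expect_equal(t1$brand, "NEXAVAR")
  t2 <- assign_tier("NEWDRUG", fx$fda, fx$trials)
  expect_equal(t2$tier, 2L)
  expect_equal(t2$trial_org, "ORG2")
  expect_equal(assign_tier("MYSTERY", fx$fda, fx$trials)$tier, 3L)

  # tumor-type repurposing flag: approved subtypes do not cover the patient
  rep1 <- assign_tier("SORAFENIB", fx$fda, fx$trials,
                      patient_subtype = "breast")
  expect_true(rep1$repurposing)
  rep2 <- assign_tier("SORAFENIB", fx$fda, fx$trials,
                      patient_subtype = "renal cancer")
  expect_false(rep2$repurposing)
})

test_that("drug ranking deduplicates paths and breaks ties by tier, name", {
  cand <- data.table::data.table(
    drug = c("X", "Y", "X", "Z", "W"),
    drug_score = c(0.2, 0.1, 0.4, 0.4, 0.4),
    tier = c(1L, 2L, 2L, 1L, 2L))
  ranked <- rank_drugs(cand)
  expect_equal(nrow(ranked), 4L)                 # X deduplicated
  expect_equal(ranked$drug_score[ranked$drug == "X"], 0.4)
  expect_equal(ranked$drug, c("Z", "W", "X", "Y"))
  expect_setequal(ranked$drug, unique(cand$drug))
})
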