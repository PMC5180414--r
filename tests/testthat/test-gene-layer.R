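test_that("closest-gene assignment: containment, distance, ties", {
  gm <- toy_gene_models()
  inside <- variant_table("chr1", 1500L, ref = "A", alt = "G")
  hit <- assign_closest_gene(inside, gm)
  expect_equal(hit$gene, "ABCA1")
  expect_equal(hit$distance, 0L)

  # 100 bp right of ABCA1 (end 1999), 901 bp left of BRCA1 (start 3000)
  near <- variant_table("chr1", 2099L, ref = "A", alt = "G")
  expect_equal(assign_closest_gene(near, gm)$gene, "ABCA1")

  # exact midpoint between ABCA1 and BRCA1 -> lexicographic tie-break
  mid <- variant_table("chr1", 2500L, ref = "A", alt = "G")
  h <- assign_closest_gene(mid, gm)
  expect_equal(h$gene, "ABCA1")
  expect_equal(h$distance, 500L)

  lost <- variant_table("chr9", 1L, ref = "A", alt = "G")
  expect_warning(expect_null(assign_closest_gene(lost, gm)), "no gene")
})

vscore <- function(cat, val)
  list(variant = NULL, score_category = cat, value = val)

test_that("per-gene aggregation takes category maxima, 0 when absent", {
  ev <- aggregate_gene(list(vscore("radial_svm", 0.932)), "ARAF",
                       phenolyzer = 0.306)
  expect_equal(ev$max_radial_svm, 0.932)
  expect_equal(ev$max_funseq2, 0)
  expect_equal(ev$max_cnv_signal, 0)
  expect_equal(ev$phenolyzer, 0.306)

  ev2 <- aggregate_gene(list(vscore("radial_svm", 0.2),
                             vscore("radial_svm", 0.9),
                             vscore("radial_svm", 0.5),
                             vscore("funseq2", 0.3),
                             vscore("cnv_signal", 0.1)), "G1")
  expect_equal(ev2$max_radial_svm, 0.9)
  expect_equal(ev2$max_funseq2, 0.3)
  expect_equal(ev2$max_cnv_signal, 0.1)

  # aggregating an already-aggregated singleton is the identity
  again <- aggregate_gene(list(vscore("radial_svm", ev2$max_radial_svm),
                               vscore("funseq2", ev2$max_funseq2),
                               vscore("cnv_signal", ev2$max_cnv_signal)),
                          "G1", phenolyzer = ev2$phenolyzer)
  expect_equal(again, ev2)
  expect_error(aggregate_gene(list(), "G1"), "no variant")
})

planted_model <- function(w = c(2, 1, 1, 3), b = -2) {
  structure(list(w = setNames(w, c("max_radial_svm", "max_funseq2",
                                   "max_cnv_signal", "phenolyzer")),
                 b = b, cutoff = 0.11, converged = TRUE),
            class = "logistic_driver_model")
}

test_that("gene score is the sigmoid of the linear predictor", {
  m <- planted_model()
  # hand-evaluated oracle: eta = 2*0.932 + 3*0.306 - 2 = 0.782
  x <- c(0.932, 0, 0, 0.306)
  expect_equal(gene_driver_score(x, m), 1 / (1 + exp(-0.782)),
               tolerance = 1e-12)
  expect_equal(gene_driver_score(x, m), 0.6861110, tolerance = 1e-6)

  z <- planted_model(w = c(0, 0, 0, 0), b = 0)
  expect_equal(gene_driver_score(runif(4), z), 0.5)
  sat <- planted_model(w = c(0, 0, 0, 0), b = 50)
  expect_equal(gene_driver_score(runif(4), sat), 1, tolerance = 1e-12)

  # formula oracle on random inputs
  set.seed(17)
  for (i in 1:50) {
    w <- rnorm(4); b <- rnorm(1); x <- runif(4)
    expect_equal(gene_driver_score(x, planted_model(w, b)),
                 1 / (1 + exp(-(sum(w * x) + b))), tolerance = 1e-12)
  }
  # monotone in each feature under strictly positive weights
  m2 <- planted_model()
  x0 <- c(0.3, 0.2, 0.1, 0.4)
  for (j in 1:4) {
    x1 <- x0; x1[j] <- x1[j] + 0.2
    expect_gt(gene_driver_score(x1, m2), gene_driver_score(x0, m2))
  }
})

test_that("driver calls use an inclusive 0.11 cutoff", {
  expect_true(call_driver(0.484))
  expect_false(call_driver(0.10))
  expect_true(call_driver(0.11))
  expect_error(call_driver(1.2), ">= 0")
})

test_that("gene categories: census precedence, KEGG, other", {
  census <- c("TP53", "BOTH")
  kegg <- c("ARAF", "BOTH")
  expect_equal(categorize_gene("BOTH", census, kegg), "cancer_gene_census")
  expect_equal(categorize_gene("ARAF", census, kegg), "kegg_cancer_pathway")
  expect_equal(categorize_gene("XYZ", census, kegg), "other")
})

test_that("gene ranking orders by score with deterministic tie-breaks", {
  m <- planted_model()
  ev <- data.table::rbindlist(list(
    aggregate_gene(list(vscore("radial_svm", 0.1)), "BBB", 0.9),
    aggregate_gene(list(vscore("radial_svm", 0.1)), "AAA", 0.2),
    aggregate_gene(list(vscore("radial_svm", 0.9)), "CCC", 0.9)))
  ranked <- rank_genes(ev, m)
  expect_equal(ranked$gene, c("CCC", "BBB", "AAA"))
  expect_setequal(ranked$gene, ev$gene)
  # exact ties on every feature fall back to alphabetical order
  ev2 <- data.table::rbindlist(list(
    aggregate_gene(list(vscore("radial_svm", 0.5)), "ZZ", 0.5),
    aggregate_gene(list(vscore("radial_svm", 0.5)), "AA", 0.5)))
  expect_equal(rank_genes(ev2, m)$gene, c("AA", "ZZ"))
})
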