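# Shared fixture builders and independent oracles. Expensive shared objects
# (the trained toy models and patient bundle) are built lazily once per test
# run and memoized in this environment.

.shared <- new.env(parent = emptyenv())

# small training world used across tests: quick to fit, clearly separable
small_spec <- function(seed = 1L)
  fixture_spec(seed = seed, n_training_tp = 300L, n_training_tn = 300L)

shared_patient <- function() {
  if (is.null(.shared$fx))
    .shared$fx <- make_patient(small_spec(), "araf_like",
                               dir = file.path(tempdir(), "shared-fx"))
  .shared$fx
}

shared_variant_model <- function() {
  if (is.null(.shared$vm)) {
    fx <- shared_patient()
    .shared$vm <- train_ensemble(
      fx$training[, PREDICTOR_NAMES, with = FALSE], fx$training$label,
      grid = list(svm_hyperparams(10, 0.001)), folds = 5L, seed = 1L,
      replicates = 0L)
  }
  .shared$vm
}

shared_gene_model <- function() {
  if (is.null(.shared$gm)) {
    gs <- make_labeled_gene_set(small_spec(), n = 2000L)
    .shared$gm <- train_logistic(gs$features, gs$labels)
  }
  .shared$gm
}

shared_run <- function() {
  if (is.null(.shared$run)) {
    fx <- shared_patient()
    cfg <- run_config(profile = fx$profile, resources = fx$resources,
                      variant_model = shared_variant_model(),
                      gene_model = shared_gene_model())
    .shared$run <- suppressWarnings(suppressMessages(run_patient(cfg)))
  }
  .shared$run
}

# brute-force pairwise-concordance AUC (ties credit 0.5); the independent
# oracle for roc_auc
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# a sorted key-coordinate database with duplicate coordinates allowed
random_sorted_db <- function(path, n_keys = 3L, n_lines = 60L,
                             coord_max = 300L) {
  keys <- paste0("k", seq_len(n_keys))
  kk <- sort(sample(seq_len(n_keys), n_lines, replace = TRUE))
  coord <- unlist(lapply(split(seq_along(kk), kk), function(idx)
    sort(sample(seq_len(coord_max), length(idx), replace = TRUE))),
    use.names = FALSE)
  lines <- paste(keys[kk], coord, paste0("payload", seq_len(n_lines)),
                 sep = "\t")
  writeLines(lines, path)
  list(path = path, keys = keys[kk], coord = coord, lines = lines)
}

# concentric rings: radially separable, linearly inseparable
make_rings <- function(n_per_class = 150L, seed = 7L) {
  set.seed(seed)
  r1 <- sqrt(runif(n_per_class)); a1 <- runif(n_per_class, 0, 2 * pi)
  r2 <- sqrt(runif(n_per_class, 4, 6)); a2 <- runif(n_per_class, 0, 2 * pi)
  X <- rbind(cbind(r1 * cos(a1), r1 * sin(a1)),
             cbind(r2 * cos(a2), r2 * sin(a2)))
  colnames(X) <- c("f1", "f2")
  list(x = X, y = c(rep(1L, n_per_class), rep(0L, n_per_class)))
}

# a tiny deterministic gene-resource world for unit tests
toy_gene_models <- function() {
  data.table::data.table(
    gene = c("ABCA1", "BRCA1", "GENX"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 3000L, 500L),
    end = c(2000L, 3999L, 900L))
}
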