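# Radial-kernel support vector classification with probability calibration.
# The dual problem is solved by the SMO routine in src/smo.cpp; decision
# values are mapped to probabilities with a Platt sigmoid fitted on
# cross-validated decision values.

#' The eleven coding pathogenicity predictors, in model order
#' @export
PREDICTOR_NAMES <- c(
  "sift", "polyphen2_humdiv", "lrt", "mutation_taster", "mutation_assessor",
  "fathmm", "gerp_pp", "phylop", "cadd", "vest", "siphy")

# the first six arrive already on a 0-1 deleteriousness scale; the rest are
# min-max scaled with ranges learned from the training table
TRANSFORMED_PREDICTORS <- PREDICTOR_NAMES[1:6]
SCALED_PREDICTORS <- PREDICTOR_NAMES[7:11]

#' Gaussian radial basis kernel
#'
#' `k(u, v) = exp(-gamma * ||u - v||^2)`; equals 1 iff `u == v` and decreases
#' strictly in the squared distance.
#'
#' @param u,v numeric vectors of equal length with no missing values.
#' @param gamma positive kernel width parameter.
#' @return kernel value in `(0, 1]`.
#' @export
radial_kernel <- function(u, v, gamma) {
  if (length(u) != length(v)) stop("u and v must have the same dimension")
  if (anyNA(u) || anyNA(v)) stop("kernel arguments must not contain NA")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((u - v)^2))
}

#' Radial SVM hyperparameters
#'
#' @param cost constraint-violation cost `c` (default 10).
#' @param gamma radial kernel width (default 0.001); larger values shrink
#'   the kernel.
#' @return list of class `svm_hyperparams`.
#' @export
svm_hyperparams <- function(cost = 10, gamma = 0.001) {
  if (cost <= 0) stop("cost must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(cost = cost, gamma = gamma), class = "svm_hyperparams")
}

# Platt's sigmoid fit (Lin, Lin & Weng 2007): find (A, B) minimizing the
# regularized log-loss of p = 1 / (1 + exp(A*f + B)) on decision values f.
fit_platt <- function(decision, labels) {
  n <- length(decision)
  prior1 <- sum(labels == 1); prior0 <- n - prior1
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(labels == 1, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    fApB <- decision * A + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(A, B)
  for (it in 1:100) {
    fApB <- decision * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(decision * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(decision^2 * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(decision * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      nA <- A + step * dA; nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) { A <- nA; B <- nB; fv <- nf; break }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

platt_prob <- function(decision, calibration) {
  1 / (1 + exp(calibration$A * decision + calibration$B))
}

# fit one SVM on a feature matrix with 0/1 labels
svm_fit <- function(x, y, hyper, kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  yy <- ifelse(y == 1, 1, -1)
  fit <- smo_train(x, yy, cost = hyper$cost, gamma = hyper$gamma,
                   kernel_type = if (kernel == "radial") 0L else 1L)
  fit$kernel <- kernel
  fit$hyperparams <- hyper
  fit
}

svm_decision_values <- function(fit, xnew) {
  smo_decision(fit$sv, fit$coef, fit$b, as.matrix(xnew),
               gamma = fit$hyperparams$gamma,
               kernel_type = if (fit$kernel == "radial") 0L else 1L)
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, folds, seed) {
  if (folds > min(table(labels)))
    stop("fold count exceeds the size of the smaller class")
  assign <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- sample(idx)
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Score coding feature vectors with a fitted ensemble model
#'
#' Applies the radial SVM decision function and the model's Platt
#' calibration, returning the probability that each mutation is a cancer
#' driver.
#'
#' @param x a normalized 11-predictor vector (or a matrix with one row per
#'   mutation, columns in the model's feature order).
#' @param model an `ensemble_svm_model` from [train_ensemble()].
#' @return calibrated probabilities in `[0, 1]`.
#' @export
score_coding <- function(x, model) {
  if (!inherits(model, "ensemble_svm_model") || is.null(model$fit))
    stop("model is not a fitted ensemble_svm_model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$feature_order))
    stop("expected ", length(model$feature_order), " predictor columns")
  dec <- svm_decision_values(model$fit, x)
  p <- platt_prob(dec, model$calibration)
  pmin(pmax(p, 0), 1)
}

#' @export
print.ensemble_svm_model <- function(x, ...) {
  cat("<ensemble_svm_model> kernel:", x$fit$kernel,
      " cost:", x$hyperparams$cost, " gamma:", x$hyperparams$gamma,
      "\n  support vectors:", nrow(x$fit$sv),
      " cv auc:", round(x$roc$auc, 4), "\n")
  invisible(x)
}

#' Persist / restore an ensemble model as a versioned JSON archive
#'
#' Stores support vectors, dual coefficients, intercept, hyperparameters,
#' Platt calibration, feature order, per-predictor scalers and imputation
#' medians; everything needed to score deterministically later.
#'
#' @param model an `ensemble_svm_model`.
#' @param path file to write / read.
#' @return `save_ensemble_model` the path, invisibly; `load_ensemble_model`
#'   the restored model.
#' @export
save_ensemble_model <- function(model, path) {
  payload <- list(
    format = "oncotriad-ensemble-model", version = 1L,
    kernel = model$fit$kernel,
    hyperparams = model$hyperparams[c("cost", "gamma")],
    sv = model$fit$sv, coef = model$fit$coef, b = model$fit$b,
    calibration = model$calibration,
    feature_order = model$feature_order,
    training_medians = as.list(model$training_medians),
    scalers = model$scalers)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_ensemble_model
#' @export
load_ensemble_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "oncotriad-ensemble-model"))
    stop("not an ensemble model archive: ", path)
  hyper <- svm_hyperparams(p$hyperparams$cost, p$hyperparams$gamma)
  fit <- list(sv = as.matrix(p$sv), coef = as.numeric(p$coef),
              b = as.numeric(p$b), kernel = p$kernel, hyperparams = hyper)
  structure(
    list(fit = fit, hyperparams = hyper,
         calibration = list(A = p$calibration$A, B = p$calibration$B),
         feature_order = p$feature_order,
         training_medians = unlist(p$training_medians),
         scalers = p$scalers, roc = NULL),
    class = "ensemble_svm_model")
}
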