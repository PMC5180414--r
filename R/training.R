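# Training and evaluation harness: hyperparameter tuning with stratified
# cross-validation, greedy backward feature elimination, the non-regularized
# logistic gene model, and tie-aware ROC AUC with stratified bootstrap
# confidence intervals.

#' Tie-aware ROC AUC with a stratified bootstrap confidence interval
#'
#' The AUC is the pairwise concordance probability: over all
#' positive-negative pairs, the fraction where the positive scores higher,
#' with ties crediting 0.5 (equivalently the Mann-Whitney statistic computed
#' from mid-ranks). The confidence interval is percentile-based over
#' stratified bootstrap resamples (positives and negatives resampled
#' separately).
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels binary labels (0/1) of the same length.
#' @param replicates bootstrap replicate count (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return an object of class `roc_result` with `auc`, `ci_low`, `ci_high`,
#'   `replicates`.
#' @export
roc_auc <- function(scores, labels, replicates = 2000L, seed = 1L,
                    conf = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: both classes must be present")
  auc <- auc_rank(scores, labels)
  ci <- c(NA_real_, NA_real_)
  if (replicates > 0L) {
    pos <- which(labels == 1L); neg <- which(labels == 0L)
    set.seed(seed)
    boot <- vapply(seq_len(replicates), function(i) {
      bp <- sample(pos, length(pos), replace = TRUE)
      bn <- sample(neg, length(neg), replace = TRUE)
      auc_rank(c(scores[bp], scores[bn]),
               c(rep(1L, length(bp)), rep(0L, length(bn))))
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  }
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 replicates = as.integer(replicates)),
            class = "roc_result")
}

# mid-rank Mann-Whitney AUC; ties credit 0.5 automatically
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (95%% CI %.4f-%.4f, %d bootstrap)\n",
              x$auc, x$ci_low, x$ci_high, x$replicates))
  invisible(x)
}

# cross-validated decision values for one hyperparameter point; returns the
# out-of-fold decision vector (aligned to rows of x) and the per-fold AUCs
cv_decisions <- function(x, y, hyper, kernel, folds, fold_id) {
  dec <- numeric(nrow(x))
  fold_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    fit <- svm_fit(x[tr, , drop = FALSE], y[tr], hyper, kernel)
    dec[te] <- svm_decision_values(fit, x[te, , drop = FALSE])
    fold_auc[f] <- auc_rank(dec[te], y[te])
  }
  list(decision = dec, fold_auc = fold_auc)
}

#' Default hyperparameter tuning grid
#'
#' Cost in `{0.1, 1, 10, 100}` crossed with gamma in
#' `{1e-4, 1e-3, 1e-2, 1e-1}`.
#' @return list of `svm_hyperparams`.
#' @export
default_svm_grid <- function() {
  g <- expand.grid(cost = c(0.1, 1, 10, 100),
                   gamma = c(1e-4, 1e-3, 1e-2, 1e-1))
  lapply(seq_len(nrow(g)), function(i) svm_hyperparams(g$cost[i], g$gamma[i]))
}

#' Train the calibrated ensemble variant classifier
#'
#' For every grid point the mean stratified cross-validation AUC of the SVM
#' decision values is computed; the winning point (ties within 0.001 broken
#' toward smaller cost, then smaller gamma -- the least overfitting-prone
#' corner) is refit on all data. The Platt probability calibration is fitted
#' on the pooled out-of-fold decision values of the winning point, so
#' calibration never sees its own training predictions.
#'
#' @param features data.frame/matrix of predictor columns on their raw
#'   scales (the five conservation/aggregate predictors are min-max scaled
#'   internally; scalers are stored with the model).
#' @param labels binary labels (1 = driver, 0 = neutral).
#' @param grid list of [svm_hyperparams()] to search (default
#'   [default_svm_grid()]).
#' @param folds cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param kernel `"radial"` (default) or `"linear"` (for comparison runs).
#' @param replicates bootstrap replicates for the reported CV ROC.
#' @return an `ensemble_svm_model` with a `roc` element (`roc_result` of the
#'   pooled out-of-fold decisions) and a `tuning` table.
#' @export
train_ensemble <- function(features, labels, grid = default_svm_grid(),
                           folds = 5L, seed = 1L, kernel = "radial",
                           replicates = 200L) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training requires both classes")
  if (!length(grid)) stop("empty hyperparameter grid")

  # learn scalers on the training table, then normalize
  scalers <- setNames(vector("list", ncol(features)), colnames(features))
  for (nm in intersect(colnames(features), SCALED_PREDICTORS)) {
    scalers[[nm]] <- list(min = min(features[[nm]], na.rm = TRUE),
                          max = max(features[[nm]], na.rm = TRUE))
  }
  x <- as.matrix(as.data.frame(
    normalize_predictors(as.list(features), scalers)))
  if (anyNA(x)) stop("training features must be complete")
  medians <- apply(x, 2, median)

  fold_id <- stratified_folds(labels, folds, seed)
  tuning <- data.table(
    cost = vapply(grid, `[[`, numeric(1), "cost"),
    gamma = vapply(grid, `[[`, numeric(1), "gamma"),
    cv_auc = NA_real_)
  cv_cache <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cv_cache[[i]] <- cv_decisions(x, labels, grid[[i]], kernel, folds, fold_id)
    tuning$cv_auc[i] <- mean(cv_cache[[i]]$fold_auc)
  }
  best_auc <- max(tuning$cv_auc)
  tied <- which(tuning$cv_auc >= best_auc - 0.001)
  tied <- tied[order(tuning$cost[tied], tuning$gamma[tied])]
  best <- tied[1]

  hyper <- grid[[best]]
  fit <- svm_fit(x, labels, hyper, kernel)
  calibration <- fit_platt(cv_cache[[best]]$decision, labels)
  roc <- roc_auc(cv_cache[[best]]$decision, labels,
                 replicates = replicates, seed = seed)

  structure(
    list(fit = fit, hyperparams = hyper, calibration = calibration,
         feature_order = colnames(x), training_medians = medians,
         scalers = scalers, roc = roc, tuning = tuning[],
         folds = as.integer(folds), seed = as.integer(seed)),
    class = "ensemble_svm_model")
}

#' Greedy backward feature elimination by cross-validated AUC
#'
#' Starting from the full predictor set, each step removes the feature whose
#' removal most improves the mean CV AUC; elimination stops when no removal
#' improves on the current set.
#'
#' @inheritParams train_ensemble
#' @param hyper hyperparameters used for every candidate fit.
#' @return list with `retained` (feature names) and `trace` (a `data.table`
#'   of step, dropped feature and AUC).
#' @export
backward_select <- function(features, labels,
                            hyper = svm_hyperparams(10, 0.001),
                            folds = 5L, seed = 1L, kernel = "radial") {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  if (ncol(features) < 2L) stop("need at least two features")
  scalers <- setNames(vector("list", ncol(features)), colnames(features))
  for (nm in intersect(colnames(features), SCALED_PREDICTORS))
    scalers[[nm]] <- list(min = min(features[[nm]]), max = max(features[[nm]]))
  x <- as.matrix(as.data.frame(
    normalize_predictors(as.list(features), scalers)))
  fold_id <- stratified_folds(labels, folds, seed)
  cv_auc_of <- function(cols)
    mean(cv_decisions(x[, cols, drop = FALSE], labels, hyper, kernel,
                      folds, fold_id)$fold_auc)

  current <- colnames(x)
  trace <- list(list(step = 0L, dropped = NA_character_,
                     cv_auc = cv_auc_of(current)))
  step <- 0L
  while (length(current) > 1L) {
    base_auc <- trace[[length(trace)]]$cv_auc
    cand <- vapply(current, function(f)
      cv_auc_of(setdiff(current, f)), numeric(1))
    if (max(cand) <= base_auc) break
    drop <- names(cand)[order(-cand, names(cand))][1]
    step <- step + 1L
    current <- setdiff(current, drop)
    trace[[length(trace) + 1L]] <-
      list(step = step, dropped = drop, cv_auc = max(cand))
  }
  list(retained = current, trace = rbindlist(trace))
}

#' Fit the non-regularized logistic driver-gene model
#'
#' Minimizes the mean binary cross-entropy
#' `(1/m) * sum(-y*log(h) - (1-y)*log(1-h))` with
#' `h(x) = 1 / (1 + exp(-(w'x + b)))` by Newton-Raphson with step halving,
#' declaring convergence when the gradient norm drops below `tol`. Feature
#' pairs with squared Pearson correlation of 0.90 or more abort the fit
#' (collinearity), and data that are perfectly separated raise an error
#' reporting the direction along which the weights diverge.
#'
#' @param features matrix/data.frame of gene-level features (one column per
#'   predictor, values in `[0, 1]`).
#' @param labels binary driver status (0/1).
#' @param cutoff binary decision threshold stored on the model
#'   (default 0.11).
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return an object of class `logistic_driver_model` with `w`, `b`,
#'   `cutoff`, `loss`, `grad_norm`, `converged`.
#' @export
train_logistic <- function(features, labels, cutoff = 0.11, tol = 1e-8,
                           max_iter = 100L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  m <- nrow(X)
  if (length(unique(y)) < 2L) stop("training requires both classes")
  if (ncol(X) >= 2L) {
    cm <- suppressWarnings(cor(X))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (any(cm^2 >= 0.90)) {
      bad <- which(cm^2 >= 0.90, arr.ind = TRUE)[1, ]
      stop(sprintf("collinear features (R^2 >= 0.90): %s ~ %s",
                   colnames(X)[bad[1]], colnames(X)[bad[2]]))
    }
  }

  Xb <- cbind(X, `(bias)` = 1)
  theta <- numeric(ncol(Xb))
  loss_of <- function(eta) {
    # numerically stable mean cross-entropy
    mean(ifelse(eta >= 0, log1p(exp(-eta)) + (1 - y) * eta,
                log1p(exp(eta)) - y * eta))
  }
  eta <- drop(Xb %*% theta)
  loss <- loss_of(eta)
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(Xb, p - y)) / m
    grad_norm <- sqrt(sum(g^2))
    if (grad_norm <= tol) break
    w2 <- p * (1 - p)
    H <- crossprod(Xb * w2, Xb) / m
    step <- tryCatch(solve(H + diag(1e-12, ncol(Xb)), g),
                     error = function(e) g)
    # full Newton step unless it increases the loss; then backtrack
    s <- 1
    repeat {
      cand <- theta - s * step
      cl <- loss_of(drop(Xb %*% cand))
      if (cl <= loss + 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    theta <- theta - s * step
    eta <- drop(Xb %*% theta)
    loss <- loss_of(eta)
    if (max(abs(theta)) > 1e4) {
      dir <- theta / sqrt(sum(theta^2))
      stop("perfect separation: weights diverge along direction (",
           paste(sprintf("%.3f", dir), collapse = ", "),
           "); the non-regularized fit does not converge")
    }
  }
  converged <- grad_norm <= tol
  # every case fitted to its own class at vanishing loss: the data are
  # separated, the MLE does not exist, and the weights diverge along the
  # fitted direction (the gradient only vanishes in the limit)
  p <- 1 / (1 + exp(-eta))
  if (loss < 1e-5 && all(p[y == 1] > 0.999) && all(p[y == 0] < 0.001)) {
    dir <- theta / sqrt(sum(theta^2))
    stop("perfect separation: weights diverge along direction (",
         paste(sprintf("%.3f", dir), collapse = ", "),
         "); the non-regularized fit does not converge")
  }
  w <- theta[-length(theta)]
  names(w) <- colnames(X)
  structure(list(w = w, b = unname(theta[length(theta)]), cutoff = cutoff,
                 loss = loss, grad_norm = grad_norm, converged = converged,
                 iterations = it),
            class = "logistic_driver_model")
}

#' @export
print.logistic_driver_model <- function(x, ...) {
  cat("<logistic_driver_model> b =", signif(x$b, 5), " cutoff =", x$cutoff,
      "\n  w:", paste(sprintf("%s=%.4g", names(x$w), x$w), collapse = ", "),
      "\n  converged:", x$converged,
      sprintf("(grad norm %.2e, loss %.5f)", x$grad_norm, x$loss), "\n")
  invisible(x)
}

#' Persist / restore the logistic gene model as JSON
#' @param model a `logistic_driver_model`.
#' @param path file to write / read.
#' @return the path (save) or the restored model (load).
#' @export
save_logistic_model <- function(model, path) {
  jsonlite::write_json(
    list(format = "oncotriad-gene-model", version = 1L,
         w = as.list(model$w), b = model$b, cutoff = model$cutoff),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_logistic_model
#' @export
load_logistic_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "oncotriad-gene-model"))
    stop("not a gene model archive: ", path)
  structure(list(w = unlist(p$w), b = p$b, cutoff = p$cutoff,
                 converged = TRUE),
            class = "logistic_driver_model")
}
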