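## Model validation machinery: venetian-blind cross-validation, external
## validation through stored preprocessing state, R2 / RMSE / NRMSE
## metrics, and y-permutation testing with a Wilcoxon signed-rank check.

#' Venetian-blind fold assignment
#'
#' Sample i (input order) goes to fold `(i - 1) mod n_splits`: cyclic
#' assignment with blind width 1. Fold sizes differ by at most 1.
#'
#' @param n number of samples (>= `n_splits`).
#' @param n_splits number of folds (study default 10).
#' @return integer vector of fold indices in `0:(n_splits - 1)`.
#' @export
venetian_blinds <- function(n, n_splits = 10) {
  if (n < n_splits) stop("n must be >= n_splits")
  (seq_len(n) - 1L) %% as.integer(n_splits)
}

.metrics <- function(y, pred, y_center = mean(y)) {
  sse <- sum((y - pred)^2)
  sst <- sum((y - y_center)^2)
  list(r2 = 1 - sse / sst, rmse = sqrt(mean((y - pred)^2)))
}

#' Root mean square error normalized by the interquartile interval
#'
#' @param rmse root mean square error (response units).
#' @param y_observed observed responses; quartiles by linear interpolation.
#' @return dimensionless NRMSE.
#' @export
nrmse <- function(rmse, y_observed) {
  q <- stats::quantile(y_observed, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (iqr <= 0) stop("interquartile interval of y_observed must be > 0")
  rmse / iqr
}

#' Cross-validate a model on a centered spectral matrix
#'
#' For each fold the training-set column means and the model fit are
#' recomputed on training samples only (no leakage); predictions are
#' assembled over held-out samples. R2 uses the full-sample mean of `y`.
#'
#' @param X uncentered (or centered; centering is redone per fold) matrix
#'   or `spectra_set`.
#' @param y response vector.
#' @param n_orth orthogonal component count for the default OPLS fit.
#' @param folds fold assignment from [venetian_blinds()].
#' @param fit optional override: `function(X_train_centered, y_train)`
#'   returning either an object with a `predict(object, X_centered)`
#'   method or a plain prediction `function(X_centered)`.
#' @return list with `report` (a `validation_report`: r2, rmse, nrmse,
#'   context `"cv"`, n) and `predictions` (per-sample CV predictions in
#'   input order).
#' @export
cross_validate <- function(X, y, n_orth = 0,
                           folds = venetian_blinds(length(y)),
                           fit = NULL) {
  if (inherits(X, "spectra_set")) X <- X$intensities
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(folds) == nrow(X))
  if (is.null(fit)) fit <- function(Xtr, ytr) .opls_fit(Xtr, ytr, n_orth)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (sum(tr) < 1) stop("fold ", f, " leaves no training samples")
    mu <- colMeans(X[tr, , drop = FALSE])
    m <- fit(sweep(X[tr, , drop = FALSE], 2, mu), y[tr])
    Xte <- sweep(X[!tr, , drop = FALSE], 2, mu)
    pred[!tr] <- if (is.function(m)) m(Xte) else predict(m, Xte)
  }
  mt <- .metrics(y, pred)
  rep <- structure(list(r2 = mt$r2, rmse = mt$rmse,
                        nrmse = nrmse(mt$rmse, y), context = "cv",
                        n = length(y)),
                   class = "validation_report")
  list(report = rep, predictions = pred)
}

#' Strict cross-validation with full per-fold preprocessing
#'
#' Re-runs the entire preprocessing chain (including the warping reference)
#' on each training fold and replays the fold's stored state on its
#' held-out samples before predicting. The default [cross_validate()]
#' recomputes only the centering means per fold, since the warping
#' reference leaks negligibly; this variant removes even that shortcut at
#' substantial cost.
#'
#' @param raw raw (unpreprocessed) `spectra_set`.
#' @param y response vector.
#' @param config a [preprocess_config()].
#' @param n_orth orthogonal component count for the OPLS fit.
#' @param folds fold assignment from [venetian_blinds()].
#' @return list with `report` and `predictions` as in [cross_validate()].
#' @export
cross_validate_strict <- function(raw, y, config = preprocess_config(),
                                  n_orth = 0,
                                  folds = venetian_blinds(length(y))) {
  stopifnot(inherits(raw, "spectra_set"),
            length(y) == nrow(raw$intensities), length(folds) == length(y))
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (sum(tr) < 1) stop("fold ", f, " leaves no training samples")
    pp <- run_preprocess(raw[which(tr), ], config)
    m <- opls(pp$spectra, y[tr], n_orth = n_orth)
    pred[!tr] <- predict(m, replay_preprocess(raw[which(!tr), ], pp$state))
  }
  mt <- .metrics(y, pred)
  rep <- structure(list(r2 = mt$r2, rmse = mt$rmse,
                        nrmse = nrmse(mt$rmse, y), context = "cv",
                        n = length(y)),
                   class = "validation_report")
  list(report = rep, predictions = pred)
}

#' Externally validate a fitted OPLS model
#'
#' Validation spectra are pushed through the stored preprocessing state
#' (calibration COW reference, calibration column means) and predicted
#' with the stored model. R2 is `1 - SSE/SST` with SST about the
#' validation-set mean.
#'
#' @param model a fitted `opls` model.
#' @param state a `preprocess_state` from the calibration run.
#' @param raw_val raw validation `spectra_set` on the calibration raw axis.
#' @param y_val observed validation responses.
#' @return a `validation_report` (context `"external"`) plus `predictions`.
#' @export
external_validate <- function(model, state, raw_val, y_val) {
  proc <- replay_preprocess(raw_val, state)
  pred <- predict(model, proc)
  mt <- .metrics(y_val, pred)
  structure(list(r2 = mt$r2, rmse = mt$rmse, nrmse = nrmse(mt$rmse, y_val),
                 context = "external", n = length(y_val),
                 predictions = pred),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s validation (n = %d): R2 = %.4f, RMSE = %.4g, NRMSE = %.3f\n",
              x$context, x$n, x$r2, x$rmse, x$nrmse))
  invisible(x)
}

#' y-permutation test of model overfitting
#'
#' The response is randomly permuted `n_iter` times; the full
#' cross-validation is re-run on each permuted response and the CV R2
#' recorded. Reports both a one-sided Wilcoxon signed-rank p (observed
#' minus permuted R2 > 0) and the assumption-free empirical
#' `p = (1 + #{permuted >= observed}) / (n_iter + 1)`.
#'
#' @param X matrix or `spectra_set`.
#' @param y response vector.
#' @param n_orth orthogonal components for the OPLS fit.
#' @param folds fold assignment.
#' @param n_iter number of permutations (study default 50).
#' @param seed RNG seed.
#' @param fit optional model override as in [cross_validate()].
#' @return a `permutation_report`: `observed_r2`, `permuted_r2`
#'   (length `n_iter`), `wilcoxon_p`, `empirical_p`.
#' @export
permutation_test <- function(X, y, n_orth = 0,
                             folds = venetian_blinds(length(y)),
                             n_iter = 50, seed = 1L, fit = NULL) {
  stopifnot(n_iter >= 1)
  if (inherits(X, "spectra_set")) X <- X$intensities
  observed <- cross_validate(X, y, n_orth, folds, fit)$report$r2
  permuted <- numeric(n_iter)
  with_seed(seed, {
    for (b in seq_len(n_iter)) {
      yp <- sample(y)
      permuted[b] <- cross_validate(X, yp, n_orth, folds, fit)$report$r2
    }
  })
  wp <- stats::wilcox.test(observed - permuted, alternative = "greater",
                           exact = FALSE)$p.value
  structure(list(observed_r2 = observed, permuted_r2 = permuted,
                 wilcoxon_p = wp,
                 empirical_p = (1 + sum(permuted >= observed)) / (n_iter + 1)),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation test: observed CV R2 = %.4f over %d permutations\n",
              x$observed_r2, length(x$permuted_r2)))
  cat(sprintf("  empirical p = %.4g, Wilcoxon signed-rank p = %.4g\n",
              x$empirical_p, x$wilcoxon_p))
  invisible(x)
}
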