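## Single-response orthogonal projections to latent structures (OPLS)
## regression, plus a NIPALS PLS1 used as an algorithmic building block
## and cross-check. X is expected column-centered (done by the
## preprocessing chain) and y is centered internally.

#' NIPALS PLS1 regression
#'
#' Standard single-response NIPALS with X- and y-deflation; deterministic
#' (no random initialization).
#'
#' @param X centered predictor matrix (n x K).
#' @param y response vector, length n (centered internally).
#' @param ncomp number of latent components, at most `rank(X)`.
#' @return an object of class `pls1` with per-component weights `W`
#'   (unit-norm columns), scores `T`, X-loadings `P`, y-loadings `q`,
#'   regression vector `b`, and the training y mean.
#' @export
pls1 <- function(X, y, ncomp = 1) {
  X <- as.matrix(X)
  y_mean <- mean(y)
  yc <- y - y_mean
  n <- nrow(X); K <- ncol(X)
  W <- P <- matrix(0, K, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- X; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("X'y vanished at component ", a,
                         "; reduce ncomp (max feasible: ", a - 1L, ")")
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - t * qa
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- qa
  }
  b <- W %*% solve(crossprod(P, W), q)
  structure(list(W = W, P = P, T = Tm, q = q, b = drop(b), ncomp = ncomp,
                 y_mean = y_mean),
            class = "pls1")
}

#' @export
predict.pls1 <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$b) + object$y_mean
}

#' Fit an OPLS regression model
#'
#' Single-y orthogonal projections to latent structures: the predictive
#' weight is `w = X'y / (y'y)` normalized; orthogonal components are
#' extracted iteratively (`w_o` proportional to `p - (w'p) w`, X deflated
#' by `t_o p_o'`), then one predictive component is computed from the
#' filtered matrix. The predictive component is the model's first latent
#' variable; its sign is fixed so that `cor(t_p, y) >= 0`, i.e. larger
#' scores correspond to higher response concentrations. Each orthogonal
#' weight is sign-fixed so its largest-magnitude loading is positive.
#'
#' @param x centered predictor matrix (n x K) or a centered `spectra_set`.
#' @param y response vector (e.g. biomarker concentration, mmol/L).
#' @param n_orth number of orthogonal components (>= 0), or `"auto"` to
#'   choose by [select_n_orth()].
#' @param max_orth upper bound scanned when `n_orth = "auto"`.
#' @param folds fold count for the auto rule.
#' @param ... unused.
#' @return an object of class `opls`: predictive weight `w_p` (unit norm),
#'   score `t_p`, loading `p_p`, y-loading `q`; orthogonal weights `W_o`,
#'   scores `T_o`, loadings `P_o`; regression vector `b` such that
#'   `yhat = X_new b + y_mean`; `vip` scores; `ppm` axis when available.
#' @export
opls <- function(x, y, n_orth = 0, max_orth = 5, folds = 10, ...) {
  ppm <- NULL
  if (inherits(x, "spectra_set")) { ppm <- x$ppm; x <- x$intensities }
  X <- as.matrix(x)
  if (identical(n_orth, "auto")) {
    sel <- select_n_orth(X, y, n_splits = folds, max_orth = max_orth)
    n_orth <- sel$n_orth
  }
  m <- .opls_fit(X, y, n_orth)
  m$ppm <- ppm
  m$call <- match.call()
  m
}

.opls_fit <- function(X, y, n_orth) {
  stopifnot(n_orth >= 0)
  n <- nrow(X); K <- ncol(X)
  y_mean <- mean(y)
  yc <- y - y_mean
  w <- drop(crossprod(X, yc)) / sum(yc^2)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("X'y is numerically zero; no predictive direction")
  w <- w / nw
  W_o <- P_o <- matrix(0, K, n_orth)
  T_o <- matrix(0, n, n_orth)
  Xd <- X
  for (a in seq_len(n_orth)) {
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-12)
      stop("degenerate deflation at orthogonal component ", a,
           "; max feasible n_orth: ", a - 1L)
    w_o <- w_o / nwo
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    ## sign convention: largest-|loading| element positive
    sgn <- sign(p_o[which.max(abs(p_o))])
    if (sgn < 0) { w_o <- -w_o; t_o <- -t_o; p_o <- -p_o }
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o[, a] <- w_o; T_o[, a] <- t_o; P_o[, a] <- p_o
  }
  t_p <- drop(Xd %*% w)
  p_p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)
  ## sign convention: cor(t_p, y) >= 0
  if (q < 0) { w <- -w; t_p <- -t_p; p_p <- -p_p; q <- -q }
  ## linear filter F = prod (I - w_o p_o') applied right-to-left on rows;
  ## regression vector b = F w q computed without forming F.
  v <- w * q
  if (n_orth > 0) {
    for (a in n_orth:1)
      v <- v - W_o[, a] * drop(crossprod(P_o[, a], v))
  }
  fitted <- drop(X %*% v) + y_mean
  vip <- sqrt(K) * abs(w)
  structure(list(w_p = w, t_p = t_p, p_p = p_p, q = q,
                 W_o = W_o, T_o = T_o, P_o = P_o, n_orth = n_orth,
                 b = v, y_mean = y_mean, fitted = fitted, y = y,
                 vip = vip, K = K, n = n),
            class = "opls")
}

#' Predict from an OPLS model
#'
#' New rows must be centered with the calibration column means and live on
#' the model's retained axis. Orthogonal variation is removed with the
#' stored `W_o`, `P_o` before scoring, which is equivalent to applying the
#' stored regression vector.
#'
#' @param object an `opls` model.
#' @param newdata centered matrix or `spectra_set`.
#' @param ... unused.
#' @return predicted response vector.
#' @export
predict.opls <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$intensities
  drop(as.matrix(newdata) %*% object$b) + object$y_mean
}

#' Orthogonal-filtered scores for new data
#'
#' @param object an `opls` model.
#' @param newdata centered matrix or `spectra_set`.
#' @return list with predictive scores `t_p` and orthogonal scores `T_o`.
#' @export
opls_scores <- function(object, newdata) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$intensities
  X <- as.matrix(newdata)
  T_o <- matrix(0, nrow(X), object$n_orth)
  for (a in seq_len(object$n_orth)) {
    t_o <- drop(X %*% object$W_o[, a])
    X <- X - tcrossprod(t_o, object$P_o[, a])
    T_o[, a] <- t_o
  }
  list(t_p = drop(X %*% object$w_p), T_o = T_o)
}

#' @export
fitted.opls <- function(object, ...) object$fitted

#' @export
residuals.opls <- function(object, ...) object$y - object$fitted

#' @export
coef.opls <- function(object, ...) object$b

#' @export
print.opls <- function(x, ...) {
  r2 <- 1 - sum((x$y - x$fitted)^2) / sum((x$y - mean(x$y))^2)
  cat(sprintf("OPLS model: %d samples, %d variables, 1 predictive + %d orthogonal component(s)\n",
              x$n, x$K, x$n_orth))
  cat(sprintf("  training R2 = %.4f; %d variables with VIP > 1\n",
              r2, sum(x$vip > 1)))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  r2 <- 1 - sum((object$y - object$fitted)^2) /
    sum((object$y - mean(object$y))^2)
  ans <- list(n = object$n, K = object$K, n_orth = object$n_orth,
              r2 = r2, rmse = sqrt(mean((object$y - object$fitted)^2)),
              n_vip_gt1 = sum(object$vip > 1))
  class(ans) <- "summary.opls"
  ans
}

#' @export
print.summary.opls <- function(x, ...) {
  cat(sprintf("OPLS: n = %d, K = %d, orthogonal components = %d\n",
              x$n, x$K, x$n_orth))
  cat(sprintf("training R2 = %.4f, RMSE = %.4g, VIP > 1 variables = %d\n",
              x$r2, x$rmse, x$n_vip_gt1))
  invisible(x)
}

#' @export
plot.opls <- function(x, type = c("scores", "loadings", "vip"), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    t2 <- if (x$n_orth > 0) x$T_o[, 1] else rep(0, x$n)
    graphics::plot(x$t_p, t2, xlab = "LV1 (predictive) score",
                   ylab = if (x$n_orth > 0) "LV2 (orthogonal 1) score" else "",
                   main = "OPLS scores", ...)
  } else if (type == "loadings") {
    xx <- if (!is.null(x$ppm)) x$ppm else seq_len(x$K)
    graphics::plot(xx, x$p_p, type = "l", xlim = rev(range(xx)),
                   xlab = "ppm", ylab = "LV1 loading", main = "OPLS loadings", ...)
  } else {
    xx <- if (!is.null(x$ppm)) x$ppm else seq_len(x$K)
    graphics::plot(xx, x$vip, type = "h", xlim = rev(range(xx)),
                   xlab = "ppm", ylab = "VIP", main = "VIP (LV1)", ...)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}

#' @importFrom stats simulate
#' @export
simulate.opls <- function(object, nsim = 1, seed = NULL, ...) {
  rs <- sqrt(mean((object$y - object$fitted)^2))
  gen <- function() object$fitted + stats::rnorm(object$n, 0, rs)
  sims <- if (is.null(seed)) replicate(nsim, gen())
  else with_seed(seed, replicate(nsim, gen()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Variable importance in projection
#'
#' VIP on the single predictive latent variable: with a unit-norm
#' predictive weight the component sum-of-squares weighting cancels and
#' `VIP_j = sqrt(K) |w_pj|`, so `mean(VIP^2) = 1` and VIP > 1 is the
#' conventional significance cutoff.
#'
#' @param m a fitted `opls` model.
#' @return numeric vector of VIP scores aligned to the retained axis.
#' @export
vip <- function(m) {
  stopifnot(inherits(m, "opls"))
  m$vip
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Fits OPLS with 0..`max_orth` orthogonal components on venetian-blind
#' folds and returns the smallest count whose RMSECV is within
#' `within` (default 2%) of the curve minimum.
#'
#' @param X centered matrix.
#' @param y response.
#' @param n_splits venetian-blind fold count.
#' @param max_orth largest count scanned.
#' @param within parsimony band relative to the minimum RMSECV.
#' @return list with `n_orth`, `rmsecv` (length `max_orth + 1`).
#' @export
select_n_orth <- function(X, y, n_splits = 10, max_orth = 5, within = 0.02) {
  if (inherits(X, "spectra_set")) X <- X$intensities
  X <- as.matrix(X)
  folds <- venetian_blinds(nrow(X), n_splits)
  rmsecv <- numeric(max_orth + 1)
  for (k in 0:max_orth) {
    pred <- rep(NA_real_, nrow(X))
    ok <- TRUE
    for (f in sort(unique(folds))) {
      tr <- folds != f
      mu <- colMeans(X[tr, , drop = FALSE])
      m <- tryCatch(.opls_fit(sweep(X[tr, , drop = FALSE], 2, mu), y[tr], k),
                    error = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      pred[!tr] <- predict(m, sweep(X[!tr, , drop = FALSE], 2, mu))
    }
    rmsecv[k + 1] <- if (ok) sqrt(mean((y - pred)^2)) else Inf
  }
  best <- min(rmsecv)
  n_orth <- which(rmsecv <= best * (1 + within))[1] - 1L
  list(n_orth = n_orth, rmsecv = rmsecv)
}

#' Serialize an OPLS model to JSON
#' @param m an `opls` model.
#' @param path file path.
#' @return `path` (write) or an `opls` model (read).
#' @export
write_opls_json <- function(m, path) {
  out <- list(w_p = m$w_p, p_p = m$p_p, q = m$q,
              W_o = as.matrix(m$W_o), P_o = as.matrix(m$P_o),
              n_orth = m$n_orth, b = m$b, y_mean = m$y_mean,
              vip = m$vip, K = m$K, n = m$n, ppm = m$ppm)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_opls_json
#' @export
read_opls_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (m$n_orth == 0) {
    m$W_o <- matrix(0, m$K, 0); m$P_o <- matrix(0, m$K, 0)
  } else {
    m$W_o <- matrix(unlist(m$W_o), nrow = m$K)
    m$P_o <- matrix(unlist(m$P_o), nrow = m$K)
  }
  class(m) <- "opls"
  m
}
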