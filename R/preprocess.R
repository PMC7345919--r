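## Spectral pre-processing chain: region deletion, correlation optimized
## warping (COW), total-area normalization, asymmetric least squares
## baseline correction, mean centering. Each step is a pure transform on a
## spectra_set; run_preprocess() applies them in the study's order and
## records a replayable state.

.PPM_TOL <- 1e-9

#' Default deletion regions
#'
#' Residual water 4.68-5.00 ppm, methanol 3.32-3.36 ppm, and the internal
#' standard (DSS-d6) region 0.40-0.60 ppm; the non-informative region
#' beyond 9.00 ppm is handled by `max_ppm` in [run_preprocess()].
#' @name regions
NULL

#' @rdname regions
#' @export
water_region <- function() list(c(4.68, 5.00))

#' @rdname regions
#' @export
solvent_regions <- function() list(c(3.32, 3.36), c(0.40, 0.60))

#' Delete chemical-shift regions
#'
#' Columns whose ppm lies inside any closed interval (comparison tolerance
#' 1e-9) are removed, not zeroed; the axis and matrix stay aligned.
#'
#' @param s a `spectra_set`.
#' @param regions list of `c(low, high)` closed ppm intervals.
#' @return a `spectra_set` on the retained bins.
#' @export
delete_regions <- function(s, regions) {
  if (length(regions) == 0) return(s)
  drop <- rep(FALSE, length(s$ppm))
  for (r in regions) {
    if (r[1] >= r[2]) stop("region low must be < high")
    drop <- drop | (s$ppm >= r[1] - .PPM_TOL & s$ppm <= r[2] + .PPM_TOL)
  }
  if (all(drop)) stop("region deletion would remove every bin")
  s[, !drop]
}

#' Correlation optimized warping configuration
#'
#' @param segment_length segment length in bins (>= 2*slack + 3).
#' @param slack maximum boundary displacement in bins (>= 0).
#' @param reference `"mean"` (mean spectrum), a sample id, or a numeric
#'   vector of reference intensities.
#' @return a `cow_config` list.
#' @export
cow_config <- function(segment_length = 80, slack = 5, reference = "mean") {
  stopifnot(slack >= 0, segment_length >= 2 * slack + 3)
  structure(list(segment_length = as.integer(segment_length),
                 slack = as.integer(slack), reference = reference),
            class = "cow_config")
}

## Reference segment boundaries: 1 = b0 < b1 < ... < bK = L, near-equal
## lengths close to cfg$segment_length.
.cow_boundaries <- function(L, seglen) {
  K <- max(1L, as.integer(round((L - 1) / seglen)))
  unique(1L + as.integer(round((0:K) * (L - 1) / K)))
}

## Correlation of each row of V with vector r; all-constant rows or an
## all-constant reference contribute 0.
.rowcor0 <- function(V, r) {
  rc <- r - mean(r)
  rn <- sqrt(sum(rc^2))
  if (rn < 1e-300) return(rep(0, nrow(V)))
  Vc <- V - rowMeans(V)
  vn <- sqrt(rowSums(Vc^2))
  out <- as.vector(Vc %*% rc) / (vn * rn)
  out[!is.finite(out)] <- 0
  out
}

## Linear interpolation of y at (possibly fractional) positions, matrix in,
## matrix out. Positions assumed within [1, length(y)].
.interp_mat <- function(y, P) {
  L <- length(y)
  lo <- pmin(pmax(floor(P), 1L), L - 1L)
  fr <- P - lo
  V <- y[lo] * (1 - fr) + y[lo + 1L] * fr
  dim(V) <- dim(P)
  V
}

## COW of one sample y onto reference ref. Dynamic programme over integer
## boundary displacements u in [-slack, slack]; score = sum of per-segment
## Pearson correlations between the linearly rescaled sample segment and
## the reference segment; endpoints fixed; ties broken toward zero shift.
.cow_one <- function(y, ref, b, slack) {
  K <- length(b) - 1L
  us <- (-slack):slack
  nu <- length(us)
  pref_rank <- integer(nu)                 # small |u| preferred on ties
  pref_rank[order(abs(us), us)] <- seq_len(nu)
  zero <- which(us == 0L)
  NEG <- -1e18
  f <- rep(NEG, nu)
  f[zero] <- 0
  back <- matrix(NA_integer_, K, nu)
  for (k in seq_len(K)) {
    m <- b[k + 1L] - b[k]
    rseg <- ref[b[k]:b[k + 1L]]
    ip_set <- if (k == 1L) zero else seq_len(nu)
    ic_set <- if (k == K) zero else seq_len(nu)
    grid <- expand.grid(ip = ip_set, ic = ic_set)
    x0 <- b[k] + us[grid$ip]
    x1 <- b[k + 1L] + us[grid$ic]
    P <- outer((x1 - x0) / m, 0:m) + x0
    V <- .interp_mat(y, P)
    sc <- .rowcor0(V, rseg)
    fnew <- rep(NEG, nu)
    bnew <- rep(NA_integer_, nu)
    for (ic in ic_set) {
      rows <- which(grid$ic == ic)
      cand <- f[grid$ip[rows]] + sc[rows]
      ord <- order(pref_rank[grid$ip[rows]])
      best <- ord[which.max(cand[ord])]
      fnew[ic] <- cand[best]
      bnew[ic] <- grid$ip[rows][best]
    }
    f <- fnew
    back[k, ] <- bnew
  }
  ## trace back boundary displacements
  u_idx <- integer(K + 1L)
  u_idx[K + 1L] <- zero
  for (k in K:1L) u_idx[k] <- back[k, u_idx[k + 1L]]
  u <- us[u_idx]
  x <- b + u
  ## warp sample onto the reference grid
  warped <- numeric(length(y))
  for (k in seq_len(K)) {
    tt <- b[k]:b[k + 1L]
    pos <- x[k] + (tt - b[k]) * (x[k + 1L] - x[k]) / (b[k + 1L] - b[k])
    warped[tt] <- .interp_mat(y, matrix(pos, 1))[1, ]
  }
  list(warped = warped, boundaries = x, score = f[which(us == 0L)])
}

#' Align spectra by correlation optimized warping
#'
#' Each sample is piecewise-linearly warped onto the reference: segment
#' boundaries move within `slack` bins, chosen by dynamic programming
#' maximizing the sum of per-segment Pearson correlations with the
#' reference; endpoints are fixed and warped intensities are obtained by
#' linear interpolation.
#'
#' @param s a `spectra_set`.
#' @param cfg a [cow_config()].
#' @param reference optional explicit reference vector overriding
#'   `cfg$reference` (used when replaying stored preprocessing state).
#' @return list with `spectra` (aligned `spectra_set`), `paths` (matrix of
#'   per-sample warped boundary positions), `boundaries` (reference
#'   boundary positions) and `reference` (the reference vector used).
#' @export
cow_align <- function(s, cfg = cow_config(), reference = NULL) {
  X <- s$intensities
  L <- ncol(X)
  b <- .cow_boundaries(L, cfg$segment_length)
  if (length(b) < 2L) stop("spectrum too short for the segment length")
  if (is.null(reference)) {
    reference <- if (is.numeric(cfg$reference)) {
      cfg$reference
    } else if (identical(cfg$reference, "mean")) {
      colMeans(X)
    } else {
      X[match(cfg$reference, s$sample_ids), ]
    }
  }
  if (length(reference) != L) stop("reference length does not match axis")
  W <- matrix(0, nrow(X), L)
  paths <- matrix(0L, nrow(X), length(b))
  for (i in seq_len(nrow(X))) {
    r <- .cow_one(X[i, ], reference, b, cfg$slack)
    W[i, ] <- r$warped
    paths[i, ] <- r$boundaries
  }
  list(spectra = spectra_set(W, s$ppm, s$sample_ids), paths = paths,
       boundaries = b, reference = as.numeric(reference))
}

#' Normalize each spectrum to unit total signal area
#'
#' @param s a `spectra_set`.
#' @return a `spectra_set` whose rows each sum to 1.
#' @export
normalize_total_area <- function(s) {
  tot <- rowSums(s$intensities)
  if (any(tot == 0)) stop("sample with zero total signal cannot be normalized")
  spectra_set(s$intensities / tot, s$ppm, s$sample_ids)
}

#' Asymmetric least squares baseline configuration
#'
#' A smooth baseline z minimizes sum_i w_i (y_i - z_i)^2 +
#' lambda ||D2 z||^2 with asymmetric weights w_i = p where y_i > z_i and
#' 1 - p otherwise, iterated to weight convergence. Defaults suit rows
#' normalized to unit total area.
#'
#' @param lambda second-difference smoothness penalty (> 0).
#' @param p asymmetry in (0, 0.5); small p lets peaks sit above the
#'   baseline.
#' @param max_iterations,tolerance iteration cap and (unused numeric)
#'   tolerance kept for completeness; convergence is exact weight
#'   stability.
#' @return a `baseline_config` list.
#' @export
baseline_config <- function(lambda = 1e5, p = 0.001, max_iterations = 10,
                            tolerance = 0) {
  stopifnot(lambda > 0, p > 0, p < 0.5, max_iterations >= 1)
  structure(list(method = "asymmetric-weighted-least-squares",
                 lambda = as.numeric(lambda), p = as.numeric(p),
                 max_iterations = as.integer(max_iterations),
                 tolerance = as.numeric(tolerance)),
            class = "baseline_config")
}

.als_one <- function(y, lambda, p, max_iter) {
  m <- length(y)
  D <- Matrix::diff(Matrix::Diagonal(m), differences = 2)
  DD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(x = w) + DD, w * y))
    wn <- ifelse(y > z, p, 1 - p)
    if (identical(wn, w) && it > 1) { converged <- TRUE; break }
    if (all(wn == w) && it > 1) { converged <- TRUE; break }
    w <- wn
  }
  list(baseline = z, converged = converged)
}

#' Subtract an asymmetric least squares baseline from each spectrum
#'
#' @param s a `spectra_set` with rows of length >= 10.
#' @param cfg a [baseline_config()].
#' @return list with `spectra` (baseline-subtracted) and `converged`
#'   (per-sample logical). Non-convergence raises a warning and keeps the
#'   last iterate.
#' @export
baseline_correct <- function(s, cfg = baseline_config()) {
  if (ncol(s$intensities) < 10) stop("rows must have length >= 10")
  X <- s$intensities
  conv <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    r <- .als_one(X[i, ], cfg$lambda, cfg$p, cfg$max_iterations)
    X[i, ] <- X[i, ] - r$baseline
    conv[i] <- r$converged
  }
  if (!all(conv))
    warning(sum(!conv), " spectra did not reach weight convergence in ",
            cfg$max_iterations, " iterations; last iterate used")
  list(spectra = spectra_set(X, s$ppm, s$sample_ids), converged = conv)
}

#' Mean-center spectra columnwise
#'
#' When `means` is omitted the column means are computed from `s` and
#' returned (calibration use); validation data must be centered with the
#' stored calibration means.
#'
#' @param s a `spectra_set`.
#' @param means optional numeric vector of column means.
#' @return list with `spectra` (centered) and `means`.
#' @export
mean_center <- function(s, means = NULL) {
  if (is.null(means)) means <- colMeans(s$intensities)
  if (length(means) != ncol(s$intensities))
    stop("means length does not match number of bins")
  list(spectra = spectra_set(sweep(s$intensities, 2, means), s$ppm,
                             s$sample_ids),
       means = as.numeric(means))
}

#' Preprocessing configuration
#'
#' @param water water deletion region(s).
#' @param cow a [cow_config()] or `NULL` to skip alignment.
#' @param normalize normalize rows to unit total area.
#' @param solvent solvent/internal-standard deletion regions.
#' @param max_ppm retain only bins at or below this shift (ppm);
#'   `Inf` disables the cut.
#' @param baseline a [baseline_config()] or `NULL` to skip.
#' @param center mean-center columns.
#' @param renormalize_after_deletion renormalize rows after the second
#'   deletion step (off by default: the study order is followed literally,
#'   so post-deletion rows no longer sum to 1).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(water = water_region(), cow = cow_config(),
                              normalize = TRUE, solvent = solvent_regions(),
                              max_ppm = 9.00, baseline = baseline_config(),
                              center = TRUE,
                              renormalize_after_deletion = FALSE) {
  structure(list(water = water, cow = cow, normalize = normalize,
                 solvent = solvent, max_ppm = max_ppm, baseline = baseline,
                 center = center,
                 renormalize_after_deletion = renormalize_after_deletion),
            class = "preprocess_config")
}

#' Run the full preprocessing chain
#'
#' Applies, in order: (1) water region deletion, (2) COW alignment,
#' (3) total-area normalization, (4) solvent/internal-standard region
#' deletion plus the downfield cut, (5) asymmetric least squares baseline
#' correction, (6) mean centering. Every step is logged; the returned
#' state (COW reference, retained regions, calibration means) replays
#' bit-identically via [replay_preprocess()].
#'
#' @param raw a raw `spectra_set` (calibration data).
#' @param config a [preprocess_config()].
#' @return list with `spectra` (processed) and `state`
#'   (a `preprocess_state`).
#' @export
run_preprocess <- function(raw, config = preprocess_config()) {
  s <- raw
  log <- list()
  state <- list(config = config)
  if (length(config$water)) {
    s <- delete_regions(s, config$water)
    log <- c(log, list(list(step = "delete_water", regions = config$water)))
  }
  if (!is.null(config$cow)) {
    al <- cow_align(s, config$cow)
    s <- al$spectra
    state$cow_reference <- al$reference
    state$cow_boundaries <- al$boundaries
    state$warp_paths <- al$paths
    log <- c(log, list(list(step = "cow_align",
                            segment_length = config$cow$segment_length,
                            slack = config$cow$slack)))
  }
  if (isTRUE(config$normalize)) {
    s <- normalize_total_area(s)
    log <- c(log, list(list(step = "normalize_total_area")))
  }
  s2 <- s
  if (length(config$solvent)) s2 <- delete_regions(s2, config$solvent)
  if (is.finite(config$max_ppm))
    s2 <- s2[, s2$ppm <= config$max_ppm + .PPM_TOL]
  if (!identical(dim(s2), dim(s)) || length(config$solvent) ||
      is.finite(config$max_ppm)) {
    log <- c(log, list(list(step = "delete_solvent_downfield",
                            regions = config$solvent,
                            max_ppm = config$max_ppm)))
  }
  s <- s2
  if (isTRUE(config$renormalize_after_deletion)) {
    s <- normalize_total_area(s)
    log <- c(log, list(list(step = "renormalize")))
  }
  if (!is.null(config$baseline)) {
    bc <- baseline_correct(s, config$baseline)
    s <- bc$spectra
    log <- c(log, list(list(step = "baseline_correct",
                            lambda = config$baseline$lambda,
                            p = config$baseline$p,
                            converged = all(bc$converged))))
  }
  if (isTRUE(config$center)) {
    mc <- mean_center(s)
    s <- mc$spectra
    state$means <- mc$means
    log <- c(log, list(list(step = "mean_center")))
  }
  state$log <- log
  state$retained_ppm <- s$ppm
  class(state) <- "preprocess_state"
  list(spectra = s, state = state)
}

#' Replay stored preprocessing on new raw spectra
#'
#' Validation spectra are pushed through the stored state: same deletion
#' regions, warping onto the stored calibration COW reference, the same
#' baseline settings, and centering with the stored calibration means.
#' Replaying the state on the raw calibration matrix reproduces the
#' processed calibration matrix bit-for-bit.
#'
#' @param raw a raw `spectra_set` sharing the calibration raw axis.
#' @param state a `preprocess_state` from [run_preprocess()].
#' @return the processed `spectra_set`.
#' @export
replay_preprocess <- function(raw, state) {
  config <- state$config
  s <- raw
  if (length(config$water)) s <- delete_regions(s, config$water)
  if (!is.null(config$cow))
    s <- cow_align(s, config$cow, reference = state$cow_reference)$spectra
  if (isTRUE(config$normalize)) s <- normalize_total_area(s)
  if (length(config$solvent)) s <- delete_regions(s, config$solvent)
  if (is.finite(config$max_ppm)) s <- s[, s$ppm <= config$max_ppm + .PPM_TOL]
  if (isTRUE(config$renormalize_after_deletion)) s <- normalize_total_area(s)
  if (!is.null(config$baseline))
    s <- suppressWarnings(baseline_correct(s, config$baseline)$spectra)
  if (isTRUE(config$center)) s <- mean_center(s, state$means)$spectra
  s
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat("preprocess_state:", length(x$log), "steps:\n")
  for (st in x$log) cat("  -", st$step, "\n")
  invisible(x)
}

#' Serialize / restore preprocessing state as JSON
#' @param state a `preprocess_state`.
#' @param path file path.
#' @return `path` (write) or a `preprocess_state` (read).
#' @export
write_preprocess_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

## Rebuild a preprocess_config (with classed cow/baseline sub-configs)
## from its JSON-deserialized plain-list form.
.rebuild_preprocess_config <- function(cfg) {
  as_regions <- function(r) {
    if (!length(r)) return(list())
    m <- as.matrix(r)
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  }
  preprocess_config(
    water = as_regions(cfg$water),
    cow = if (!is.null(cfg$cow)) cow_config(cfg$cow$segment_length,
      cfg$cow$slack, cfg$cow$reference) else NULL,
    normalize = isTRUE(cfg$normalize),
    solvent = as_regions(cfg$solvent),
    max_ppm = if (is.null(cfg$max_ppm)) Inf else as.numeric(cfg$max_ppm),
    baseline = if (!is.null(cfg$baseline)) baseline_config(cfg$baseline$lambda,
      cfg$baseline$p, cfg$baseline$max_iterations) else NULL,
    center = isTRUE(cfg$center),
    renormalize_after_deletion = isTRUE(cfg$renormalize_after_deletion))
}

#' @rdname write_preprocess_state
#' @export
read_preprocess_state <- function(path) {
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  st$config <- .rebuild_preprocess_config(st$config)
  class(st) <- "preprocess_state"
  st
}
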