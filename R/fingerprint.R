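## Metabolomic fingerprint extraction: STOCSY traces, VIP-significant
## spectral regions with correlation direction, and the four-way
## classification of metabolites against the two biomarker models.

#' Statistical total correlation spectroscopy
#'
#' Correlates the intensity at a driver chemical shift against every
#' retained bin across samples, grouping resonances of the same molecule.
#'
#' @param X preprocessed `spectra_set` or matrix with a `ppm` attribute.
#' @param driver_ppm driver position (snapped to the nearest bin).
#' @param ppm axis when `X` is a bare matrix.
#' @return a `stocsy_trace`: `ppm`, `r` (Pearson correlation per bin),
#'   `cov` (covariance per bin), `driver_ppm` (snapped).
#' @export
stocsy <- function(X, driver_ppm, ppm = NULL) {
  if (inherits(X, "spectra_set")) { ppm <- X$ppm; X <- X$intensities }
  if (is.null(ppm)) stop("ppm axis required")
  j <- which.min(abs(ppm - driver_ppm))
  halfbin <- if (length(ppm) > 1) max(abs(diff(ppm))) / 2 else Inf
  if (abs(ppm[j] - driver_ppm) > halfbin + 1e-12)
    stop("driver_ppm is not on the retained axis")
  d <- X[, j]
  Xc <- sweep(X, 2, colMeans(X))
  dc <- d - mean(d)
  cv <- drop(crossprod(Xc, dc)) / (nrow(X) - 1)
  sds <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  r <- cv / (sds * sds[j])
  r[!is.finite(r)] <- 0
  structure(list(ppm = ppm, r = r, cov = cv, driver_ppm = ppm[j]),
            class = "stocsy_trace")
}

#' @export
print.stocsy_trace <- function(x, ...) {
  cat(sprintf("STOCSY trace, driver %.4f ppm; %d bins with |r| > 0.8\n",
              x$driver_ppm, sum(abs(x$r) > 0.8)))
  invisible(x)
}

#' @export
plot.stocsy_trace <- function(x, ...) {
  graphics::plot(x$ppm, x$cov, type = "l", xlim = rev(range(x$ppm)),
                 xlab = "ppm", ylab = "covariance with driver",
                 main = sprintf("STOCSY, driver %.3f ppm", x$driver_ppm), ...)
  invisible(x)
}

#' VIP-significant spectral regions
#'
#' Maximal runs of contiguous bins with VIP above the threshold, each
#' tagged with the sign of the predictive loading at its max-VIP bin
#' (positive loadings mean positive correlation with the biomarker).
#'
#' @param vip VIP vector aligned to `ppm`.
#' @param loadings predictive loadings aligned to `ppm`.
#' @param ppm retained axis.
#' @param threshold significance cutoff (conventionally 1).
#' @return data frame with `low_ppm`, `high_ppm`, `max_vip`, `sign`
#'   (+1/-1/0), one row per region; zero rows when nothing exceeds the
#'   threshold.
#' @export
significant_regions <- function(vip, loadings, ppm, threshold = 1) {
  stopifnot(length(vip) == length(ppm), length(loadings) == length(ppm))
  sig <- vip > threshold
  if (!any(sig)) {
    return(data.frame(low_ppm = numeric(0), high_ppm = numeric(0),
                      max_vip = numeric(0), sign = numeric(0)))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    jmax <- idx[which.max(vip[idx])]
    data.frame(low_ppm = min(ppm[idx]), high_ppm = max(ppm[idx]),
               max_vip = vip[jmax], sign = sign(loadings[jmax]))
  })
  do.call(rbind, out)
}

#' Default metabolite annotation windows
#'
#' Windows of +/- `pad` ppm around every multiplet line of each library
#' metabolite, restricted to fingerprint metabolites: the two glucose
#' anomers are merged into one `glucose` entry, and the response analyte
#' itself (BHBA) and the planted-null formate are excluded from
#' classification. Overlapping windows are reported as-is.
#'
#' @param lib a signature library.
#' @param pad half-width of each window (ppm).
#' @param exclude metabolites left out of the fingerprint.
#' @return data frame `metabolite`, `low_ppm`, `high_ppm`, `source`.
#' @export
default_annotations <- function(lib = default_library(), pad = 0.01,
                                exclude = c("bhba", "formate")) {
  lines <- .library_lines(lib)
  src <- vapply(lib, function(g) attr(g, "source"), character(1))
  lines$metabolite[lines$metabolite %in% c("glucose_alpha", "glucose_beta")] <-
    "glucose"
  lines <- lines[!lines$metabolite %in% exclude, , drop = FALSE]
  ## one window per multiplet group: merge lines closer than 2*pad
  out <- lapply(split(lines, lines$metabolite), function(d) {
    d <- d[order(d$pos), ]
    grp <- cumsum(c(1, diff(d$pos) > 2 * pad))
    wins <- lapply(split(d, grp), function(w)
      data.frame(metabolite = w$metabolite[1], low_ppm = min(w$pos) - pad,
                 high_ppm = max(w$pos) + pad, stringsAsFactors = FALSE))
    do.call(rbind, wins)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$source <- ifelse(out$metabolite == "glucose", "library-default",
                       unname(src[out$metabolite]))
  out
}

.max_vip_in_windows <- function(model, windows) {
  ppm <- model$ppm
  idx <- rep(FALSE, length(ppm))
  for (i in seq_len(nrow(windows)))
    idx <- idx | (ppm >= windows$low_ppm[i] - 1e-9 &
                    ppm <= windows$high_ppm[i] + 1e-9)
  if (!any(idx)) return(list(vip = NA_real_, sign = 0))
  j <- which(idx)[which.max(model$vip[idx])]
  list(vip = model$vip[j], sign = sign(model$p_p[j]))
}

#' Classify metabolites against the BHBA and NEFA models
#'
#' A metabolite is significant in a model when its maximum VIP within any
#' of its annotation windows exceeds the threshold; its direction is the
#' sign of the predictive loading at that bin. Classification: significant
#' in both with equal sign gives `shared-positive`/`shared-negative`,
#' with opposite signs `opposite`; significant in one only gives
#' `bhba-only`/`nefa-only`; otherwise `neither`. A zero loading at the
#' max-VIP bin counts as not significant.
#'
#' @param bhba_model,nefa_model fitted `opls` models sharing the retained
#'   axis (`ppm` stored in the model).
#' @param annotations annotation window table from [default_annotations()].
#' @param threshold VIP cutoff (default 1).
#' @return a `fingerprint` data frame: one row per metabolite with
#'   `vip_bhba`, `sign_bhba`, `vip_nefa`, `sign_nefa`, `class`, ordered by
#'   class then name.
#' @export
classify_metabolites <- function(bhba_model, nefa_model,
                                 annotations = default_annotations(),
                                 threshold = 1) {
  stopifnot(!is.null(bhba_model$ppm), !is.null(nefa_model$ppm))
  if (!isTRUE(all.equal(bhba_model$ppm, nefa_model$ppm)))
    stop("models do not share the retained axis")
  mets <- unique(annotations$metabolite)
  rows <- lapply(mets, function(m) {
    w <- annotations[annotations$metabolite == m, , drop = FALSE]
    b <- .max_vip_in_windows(bhba_model, w)
    n <- .max_vip_in_windows(nefa_model, w)
    sig_b <- !is.na(b$vip) && b$vip > threshold && b$sign != 0
    sig_n <- !is.na(n$vip) && n$vip > threshold && n$sign != 0
    cls <- if (sig_b && sig_n) {
      if (b$sign == n$sign) {
        if (b$sign > 0) "shared-positive" else "shared-negative"
      } else "opposite"
    } else if (sig_b) "bhba-only" else if (sig_n) "nefa-only" else "neither"
    data.frame(metabolite = m, vip_bhba = b$vip, sign_bhba = b$sign,
               vip_nefa = n$vip, sign_nefa = n$sign, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$class, out$metabolite), ]
  rownames(out) <- NULL
  class(out) <- c("fingerprint", "data.frame")
  out
}

#' Assemble and serialize the fingerprint report
#'
#' One row per annotated metabolite (VIP and direction per model, class),
#' plus model-quality metrics; ordering is deterministic (class, then
#' name) so reruns on identical inputs are byte-identical.
#'
#' @param entries a `fingerprint` from [classify_metabolites()].
#' @param reports optional named list of `validation_report`s included as
#'   model-quality metadata.
#' @param path optional JSON output path.
#' @return the report list, invisibly when written.
#' @export
fingerprint_report <- function(entries, reports = NULL, path = NULL) {
  counts <- table(factor(entries$class,
                         levels = c("shared-positive", "shared-negative",
                                    "opposite", "bhba-only", "nefa-only",
                                    "neither")))
  rep <- list(
    entries = as.data.frame(entries),
    class_counts = as.list(counts),
    n_significant = sum(entries$class != "neither"),
    model_quality = lapply(reports, function(r)
      list(context = r$context, r2 = r$r2, rmse = r$rmse, nrmse = r$nrmse,
           n = r$n)))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(rep))
  }
  rep
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("metabolomic fingerprint (", sum(x$class != "neither"),
      " significant metabolites):\n", sep = "")
  print.data.frame(x, digits = 3)
  invisible(x)
}
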