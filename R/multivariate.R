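## Unsupervised screening: PCA with a Hotelling T2 95% ellipse for
## advisory outlier flagging, and ANOVA-simultaneous component analysis
## (ASCA) quantifying the share of spectral variation attributable to the
## study's fixed effects (days in milk, age, herd).

#' Principal component analysis of a centered spectral matrix
#'
#' SVD-based, deterministic sign convention (the largest-magnitude element
#' of each loading is positive).
#'
#' @param X centered matrix or centered `spectra_set`.
#' @param n_pc number of components to keep, at most `min(n - 1, K)`.
#' @return an object of class `pca_model`: `loadings` (K x n_pc,
#'   orthonormal columns), `scores` (n x n_pc), `var_frac` (per-component
#'   fraction of total variance), `sdev`.
#' @export
fit_pca <- function(X, n_pc = 2) {
  if (inherits(X, "spectra_set")) X <- X$intensities
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_pc > min(n - 1, ncol(X))) stop("n_pc exceeds min(n - 1, K)")
  sv <- svd(X, nu = n_pc, nv = n_pc)
  tot <- sum(X^2)
  for (a in seq_len(n_pc)) {
    j <- which.max(abs(sv$v[, a]))
    if (sv$v[j, a] < 0) { sv$v[, a] <- -sv$v[, a]; sv$u[, a] <- -sv$u[, a] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc)
  structure(list(loadings = sv$v, scores = scores,
                 var_frac = sv$d[seq_len(n_pc)]^2 / tot,
                 sdev = sv$d[seq_len(n_pc)] / sqrt(n - 1), n = n),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA: %d components; variance fractions %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$var_frac), collapse = ", ")))
  invisible(x)
}

#' Hotelling T2 outlier flags on the PC1-PC2 plane
#'
#' `T2_i = sum_a t_ia^2 / lambda_a` over the first two components; a
#' sample is flagged when T2 exceeds the F-distribution ellipse limit
#' `[2 (n-1)(n+1) / (n (n-2))] F_{2, n-2}(alpha)`. Flags are advisory:
#' removal mirrors the manual-review step of the emulated study and is a
#' user decision.
#'
#' @param m a `pca_model` with >= 2 components.
#' @param alpha confidence level of the ellipse (default 0.95).
#' @return list with `t2`, `limit` and logical `flagged`.
#' @export
hotelling_flags <- function(m, alpha = 0.95) {
  if (ncol(m$scores) < 2) stop("need at least 2 components")
  n <- m$n
  lambda <- m$sdev[1:2]^2
  t2 <- m$scores[, 1]^2 / lambda[1] + m$scores[, 2]^2 / lambda[2]
  limit <- 2 * (n - 1) * (n + 1) / (n * (n - 2)) *
    stats::qf(alpha, 2, n - 2)
  list(t2 = t2, limit = limit, flagged = t2 > limit)
}

#' ANOVA-simultaneous component analysis
#'
#' Decomposes a centered matrix into per-factor effect matrices (rows =
#' the sample's factor-level mean spectrum) plus residual; the share of
#' each factor is `100 ||X_f||_F^2 / ||X||_F^2`. Significance per factor
#' by permutation of that factor's labels with the add-one rule, seeded.
#' Main effects only; unbalanced designs are accepted and the residual is
#' defined as total minus the sum of effects.
#'
#' @param X centered matrix or centered `spectra_set`.
#' @param design data frame of factors (one column per fixed effect).
#' @param n_perm number of permutations (study default 1000).
#' @param seed RNG seed for the permutations.
#' @return an `asca_result`: data frame `effects` (factor, percent,
#'   p_value), `residual_percent`, `total_ss`.
#' @export
asca <- function(X, design, n_perm = 1000, seed = 1L) {
  if (inherits(X, "spectra_set")) X <- X$intensities
  X <- as.matrix(X)
  design <- as.data.frame(design)
  stopifnot(nrow(design) == nrow(X))
  keep <- vapply(design, function(f) length(unique(f)) >= 2, logical(1))
  if (!all(keep)) {
    warning("factor(s) with a single level excluded: ",
            paste(names(design)[!keep], collapse = ", "))
    design <- design[, keep, drop = FALSE]
  }
  if (ncol(design) == 0) stop("no usable factors")
  X <- sweep(X, 2, colMeans(X))  # idempotent on centered input
  tot <- sum(X^2)
  ## ||X_f||_F^2 = sum_g n_g ||mean_g||^2 = sum_g ||colsum_g||^2 / n_g
  eff_ss <- function(f, M) {
    f <- as.character(f)
    sm <- rowsum(M, f)
    sum(sm^2 / as.vector(table(f)))
  }
  percent <- p_value <- numeric(ncol(design))
  with_seed(seed, {
    for (j in seq_len(ncol(design))) {
      obs <- eff_ss(design[[j]], X)
      percent[j] <- 100 * obs / tot
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(nrow(X))
        if (eff_ss(design[[j]][perm], X) >= obs) exceed <- exceed + 1L
      }
      p_value[j] <- (1 + exceed) / (n_perm + 1)
    }
  })
  structure(list(effects = data.frame(factor = names(design),
                                      percent = percent, p_value = p_value,
                                      stringsAsFactors = FALSE),
                 residual_percent = 100 - sum(percent),
                 total_ss = tot, n_perm = n_perm),
            class = "asca_result")
}

#' @export
print.asca_result <- function(x, ...) {
  cat("ASCA variance partition (", x$n_perm, " permutations):\n", sep = "")
  for (i in seq_len(nrow(x$effects)))
    cat(sprintf("  %-10s %6.2f%%  p = %.4g\n", x$effects$factor[i],
                x$effects$percent[i], x$effects$p_value[i]))
  cat(sprintf("  %-10s %6.2f%%\n", "residual", x$residual_percent))
  invisible(x)
}

#' Build the default ASCA design from a cohort table
#'
#' Days in milk is split at 16 d (median of the 4-30 d range), age into
#' 2, 3 and >= 4 years; herd is used as-is. ASCA needs categorical
#' factors and the emulated study does not state its coding.
#'
#' @param cohort a `cohort_table`.
#' @return data frame with factors `dim_class`, `age_class`, `herd`.
#' @export
asca_design <- function(cohort) {
  data.frame(
    dim_class = ifelse(cohort$dim_days <= 16, "early", "late"),
    age_class = ifelse(cohort$age_years >= 4, "4plus",
                       as.character(cohort$age_years)),
    herd = as.character(cohort$herd),
    stringsAsFactors = FALSE)
}
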