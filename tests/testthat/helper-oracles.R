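## Independent reference implementations ("oracles") used to cross-check
## the package's algorithms, plus small shared fixtures. Everything here
## is deliberately written with a different algorithm or a brute-force
## strategy so that agreement is evidence, not tautology.

## ---- SIMPLS (de Jong 1993) for a single response -----------------------
## Returns the regression vector for centered X against y. Used as a
## second-algorithm oracle for the NIPALS PLS1 coefficients.
simpls_coef <- function(X, y, A) {
  X <- as.matrix(X)
  X <- sweep(X, 2, colMeans(X))
  y <- y - mean(y)
  K <- ncol(X)
  s <- drop(crossprod(X, y))
  R <- matrix(0, K, A)
  V <- matrix(0, K, A)
  qvec <- numeric(A)
  for (a in seq_len(A)) {
    r <- s
    t <- drop(X %*% r)
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    t <- t / nt
    r <- r / nt
    p <- drop(crossprod(X, t))
    qvec[a] <- sum(y * t)
    v <- p
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - drop(Vp %*% crossprod(Vp, p))
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * drop(crossprod(v, s))
    R[, a] <- r
    V[, a] <- v
  }
  drop(R %*% qvec)
}

## ---- Brute-force COW objective -----------------------------------------
## Enumerates every feasible placement of the interior boundaries
## (endpoints fixed, each interior boundary displaced by u in -slack:slack)
## and returns the best achievable sum of per-segment Pearson correlations
## with the reference. Segment interpolation mirrors the definition in the
## package but is written independently with stats::approx.
cow_exhaustive_best <- function(y, ref, b, slack) {
  seg_score <- function(x0, x1, b0, b1) {
    m <- b1 - b0
    pos <- x0 + (0:m) * (x1 - x0) / m
    v <- stats::approx(seq_along(y), y, pos)$y
    r <- ref[b0:b1]
    if (stats::sd(v) == 0 || stats::sd(r) == 0) return(0)
    stats::cor(v, r)
  }
  n_int <- length(b) - 2L
  us <- (-slack):slack
  grids <- rep(list(us), n_int)
  combos <- as.matrix(do.call(expand.grid, grids))
  best <- -Inf
  for (i in seq_len(nrow(combos))) {
    x <- b + c(0L, combos[i, ], 0L)
    sc <- 0
    for (k in seq_len(length(b) - 1L))
      sc <- sc + seg_score(x[k], x[k + 1L], b[k], b[k + 1L])
    if (sc > best) best <- sc
  }
  best
}

## ---- Type-7 quartile oracle --------------------------------------------
## Linear-interpolation quantile computed by direct index arithmetic.
quartile_oracle <- function(y, prob) {
  ys <- sort(y)
  n <- length(ys)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  ys[lo] + (h - lo) * (ys[hi] - ys[lo])
}

## ---- Shared fixtures ----------------------------------------------------
## The default full-scale study is expensive (~6 min); it is run once and
## memoized so every test file can assert against the same result.
.fixture_cache <- new.env(parent = emptyenv())

get_default_study <- function() {
  if (!exists("default_study", envir = .fixture_cache)) {
    res <- suppressWarnings(run_study(run_config()))
    assign("default_study", res, envir = .fixture_cache)
  }
  get("default_study", envir = .fixture_cache)
}

## A small rendered cohort (n = 60, 2048 bins) reused by permutation-test
## and STOCSY-style checks; kept far cheaper than the full study.
get_small_cohort <- function() {
  if (!exists("small_cohort", envir = .fixture_cache)) {
    sp <- cohort_spec(n_samples = 60, seed = 404L)
    ct <- draw_cohort(sp)
    sx <- render_spectra(ct, default_library(), sp,
                         axis = default_axis(n = 2048))
    assign("small_cohort", list(spec = sp, cohort = ct, spectra = sx),
           envir = .fixture_cache)
  }
  get("small_cohort", envir = .fixture_cache)
}

## The planted fingerprint of the default generator: per metabolite, the
## model(s) it should be significant in and the loading sign it should
## carry. This is ground-truth bookkeeping for the synthetic design.
planted_fingerprint <- function() {
  data.frame(
    metabolite = c("glucose", "lactate", "alanine", "valine",
                   "glycine", "phosphocholine", "ldl", "vldl", "nag",
                   "acetate", "creatine",
                   "betaine", "dmso2",
                   "isoleucine", "leucine", "hippurate"),
    class = c(rep("shared-negative", 4), rep("shared-positive", 5),
              rep("opposite", 2), rep("bhba-only", 2), rep("nefa-only", 3)),
    sign_bhba = c(rep(-1, 4), rep(1, 5), 1, 1, 1, -1, 0, 0, 0),
    sign_nefa = c(rep(-1, 4), rep(1, 5), -1, -1, 0, 0, 1, -1, -1),
    stringsAsFactors = FALSE)
}
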