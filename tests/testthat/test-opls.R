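## Unit and property tests for the PLS1 building block and the OPLS
## estimator, including the independent SIMPLS coefficient oracle.

centered <- function(n, K, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * K), n, K)
  sweep(X, 2, colMeans(X))
}

test_that("PLS1 solves the exact linear case and matches SIMPLS", {
  ## exact linear case at full rank
  X <- centered(30, 5, 1)
  beta <- c(1, -2, 0.5, 3, -1)
  y <- drop(X %*% beta) + 2
  m <- pls1(X, y, ncomp = 5)
  expect_lt(max(abs(drop(X %*% m$b) + m$y_mean - y)), 1e-8)

  ## first weight proportional to X'y
  m1 <- pls1(X, y, ncomp = 1)
  w_ref <- drop(crossprod(X, y - mean(y)))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_lt(max(abs(m1$W[, 1] - w_ref)), 1e-12)

  ## SIMPLS oracle: coefficients at A = 2 on a seeded 20 x 10 instance
  X2 <- centered(20, 10, 42)
  set.seed(43)
  y2 <- rnorm(20)
  m2 <- pls1(X2, y2, ncomp = 2)
  expect_lt(max(abs(m2$b - simpls_coef(X2, y2, 2))), 1e-6)
})

test_that("OPLS components satisfy the orthogonality invariants", {
  X <- centered(50, 200, 2)
  set.seed(3)
  y <- rnorm(50)
  m <- opls(X, y, n_orth = 3)
  for (a in 1:3) {
    expect_lt(abs(sum(m$w_p * m$W_o[, a])), 1e-8)
    expect_lt(abs(sum(m$t_p * m$T_o[, a])) /
                (sqrt(sum(m$t_p^2)) * sqrt(sum(m$T_o[, a]^2))), 1e-8)
    expect_lt(abs(sqrt(sum(m$W_o[, a]^2)) - 1), 1e-12)
  }
  expect_lt(abs(sqrt(sum(m$w_p^2)) - 1), 1e-12)
  expect_gte(cor(m$t_p, y), 0)
})

test_that("predictions ignore model-orthogonal directions and reproduce training fit", {
  X <- centered(40, 60, 4)
  set.seed(5)
  y <- rnorm(40) + X[, 1]
  m <- opls(X, y, n_orth = 2)
  expect_equal(predict(m, X), fitted(m), tolerance = 1e-12)

  ## the orthogonal filter subtracts (w_o'x) p_o, so adding any multiple
  ## of an orthogonal *loading* leaves the prediction unchanged exactly
  xrow <- X[7, , drop = FALSE]
  for (a in 1:2) {
    bumped <- xrow + 5 * m$P_o[, a]
    expect_lt(abs(predict(m, bumped) - predict(m, xrow)), 1e-8)
  }
})

test_that("an orthogonal structured component is filtered, improving cross-validation", {
  set.seed(6)
  n <- 80; K <- 120
  y <- rnorm(n)
  a_dir <- rnorm(K); a_dir <- a_dir / sqrt(sum(a_dir^2))
  p_dir <- rnorm(K); p_dir <- p_dir - a_dir * sum(a_dir * p_dir)
  p_dir <- p_dir / sqrt(sum(p_dir^2))
  t_o <- rnorm(n)                # y-orthogonal structured variation
  X <- outer(y, a_dir) + 6 * outer(t_o, p_dir) +
    0.1 * matrix(rnorm(n * K), n, K)
  r2_0 <- cross_validate(X, y, n_orth = 0)$report$r2
  r2_1 <- cross_validate(X, y, n_orth = 1)$report$r2
  expect_gt(r2_1, r2_0)

  ## auto-selection picks one orthogonal component here
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(select_n_orth(Xc, y, max_orth = 3)$n_orth, 1L)
})

test_that("auto-selection is parsimonious on pure noise", {
  picks <- integer(20)
  for (r in 1:20) {
    X <- centered(200, 50, 100 + r)
    set.seed(200 + r)
    y <- rnorm(200)
    picks[r] <- select_n_orth(X, y, max_orth = 3)$n_orth
  }
  expect_gte(sum(picks == 0L), 18L)

  sel <- select_n_orth(centered(40, 20, 9), rnorm(40), max_orth = 4)
  expect_length(sel$rmsecv, 5L)
})

test_that("VIP is invariant to positive response scaling and degenerate deflation errors are informative", {
  X <- centered(30, 40, 10)
  set.seed(11)
  y <- rnorm(30)
  m1 <- opls(X, y, n_orth = 1)
  m2 <- opls(X, 7.5 * y, n_orth = 1)
  expect_equal(vip(m1), vip(m2), tolerance = 1e-10)
  expect_equal(sum(vip(m1)^2), ncol(X), tolerance = 1e-9)

  ## rank-1 X cannot support an orthogonal component
  Xr <- outer(rnorm(20), rnorm(15))
  Xr <- sweep(Xr, 2, colMeans(Xr))
  yr <- drop(Xr[, 1]) + rnorm(20, 0, 1e-3)
  expect_error(opls(Xr, yr, n_orth = 1), "max feasible n_orth: 0")
})

test_that("models round-trip through JSON and the S3 methods are coherent", {
  sc <- get_small_cohort()
  pp <- suppressWarnings(run_preprocess(sc$spectra, preprocess_config()))
  y <- sc$cohort$bhba_mmol_l
  m <- opls(pp$spectra, y, n_orth = 1)

  f <- tempfile(fileext = ".json")
  write_opls_json(m, f)
  m2 <- read_opls_json(f)
  Xnew <- pp$spectra$intensities[1:5, ]
  expect_equal(predict(m2, Xnew), predict(m, Xnew), tolerance = 1e-12)
  expect_equal(m2$vip, m$vip, tolerance = 1e-12)
  expect_equal(m2$ppm, m$ppm, tolerance = 1e-12)

  expect_equal(coef(m), m$b)
  expect_equal(residuals(m), y - fitted(m))
  s <- summary(m)
  expect_s3_class(s, "summary.opls")
  expect_equal(s$n, length(y))
  expect_output(print(m), "OPLS model")

  sims <- simulate(m, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(y), 3L))
  expect_identical(sims, simulate(m, nsim = 3, seed = 1))

  sc2 <- opls_scores(m, pp$spectra)
  expect_equal(sc2$t_p, m$t_p, tolerance = 1e-8)
})
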