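## Unit tests for the six-step preprocessing chain and its provenance.

make_set <- function(X, ppm = seq(0, 10, length.out = ncol(X))) {
  spectra_set(X, ppm, sprintf("s%02d", seq_len(nrow(X))))
}

test_that("region deletion removes exactly the enumerated bins", {
  ppm <- seq(0, 10, by = 0.5)
  X <- matrix(seq_along(ppm), nrow = 2, ncol = length(ppm), byrow = TRUE)
  s <- make_set(X, ppm)

  d <- delete_regions(s, list(c(4.68, 5.00)))
  inside <- which(ppm >= 4.68 & ppm <= 5.00)   # brute-force scan
  expect_equal(length(inside), 1L)             # only the 5.0 bin
  expect_equal(ncol(d$intensities), length(ppm) - 1L)
  expect_false(any(d$ppm == 5.0))

  expect_identical(delete_regions(s, list()), s)

  ## closed intervals: endpoints are deleted
  d2 <- delete_regions(s, list(c(2.0, 3.0)))
  expect_false(any(d2$ppm >= 2.0 & d2$ppm <= 3.0))
})

test_that("total-area normalization is exact and idempotent", {
  s <- make_set(matrix(c(2, 2, 4, 1, 1, 2), 2, 3, byrow = TRUE))
  n1 <- normalize_total_area(s)
  expect_equal(n1$intensities[1, ], c(0.25, 0.25, 0.5))
  expect_true(all(abs(rowSums(n1$intensities) - 1) < 1e-12))
  n2 <- normalize_total_area(n1)
  expect_equal(n2$intensities, n1$intensities, tolerance = 1e-15)
  expect_error(normalize_total_area(make_set(matrix(0, 1, 3))), "zero total")
})

test_that("COW aligns the reference to itself with an identity warp", {
  set.seed(12)
  x <- seq(0, 1, length.out = 400)
  ref <- exp(-(x - 0.3)^2 / 0.002) + 0.5 * exp(-(x - 0.7)^2 / 0.001)
  s <- make_set(rbind(ref, ref), x)
  al <- cow_align(s, cow_config(segment_length = 80, slack = 5),
                  reference = ref)
  expect_lt(max(abs(al$spectra$intensities - rbind(ref, ref))), 1e-12)
  expect_true(all(al$paths == matrix(al$boundaries, 2, length(al$boundaries),
                                     byrow = TRUE)))
})

test_that("COW never moves a boundary beyond the slack", {
  set.seed(13)
  x <- seq(0, 1, length.out = 400)
  X <- t(replicate(4, {
    rowSums(sapply(1:4, function(j)
      runif(1, 0.5, 2) * exp(-(x - runif(1))^2 / runif(1, 5e-4, 5e-3))))
  }))
  s <- make_set(X, x)
  cfg <- cow_config(segment_length = 80, slack = 5)
  al <- cow_align(s, cfg)
  dev <- sweep(al$paths, 2, al$boundaries)
  expect_lte(max(abs(dev)), cfg$slack)
  expect_true(all(al$paths[, 1] == 1))                # endpoints fixed
  expect_true(all(al$paths[, ncol(al$paths)] == 400))
})

test_that("baseline correction removes smooth drift and keeps peaks", {
  x <- seq(0, 1, length.out = 500)

  ## stiffness appropriate to a 500-point grid (the pipeline default is
  ## tuned for the 8192-bin axis)
  cfg <- baseline_config(lambda = 1e3)

  ## pure smooth quadratic, no peaks -> output ~ 0
  quad <- 2 + 3 * x - 4 * x^2
  s <- make_set(matrix(quad, 1), x)
  out <- suppressWarnings(baseline_correct(s, cfg))
  expect_lt(max(abs(out$spectra$intensities)), 0.01 * diff(range(quad)))

  ## flat zero baseline + one Lorentzian -> apex preserved within 5%
  peak <- (0.005 / pi) / (0.005^2 + (x - 0.5)^2)
  sp <- make_set(matrix(peak, 1), x)
  outp <- suppressWarnings(baseline_correct(sp, cfg))
  expect_lt(abs(max(outp$spectra$intensities) - max(peak)), 0.05 * max(peak))

  ## offset invariance: adding a constant is absorbed by the baseline
  c0 <- 50
  so <- make_set(matrix(peak + c0, 1), x)
  outo <- suppressWarnings(baseline_correct(so, cfg))
  expect_lt(max(abs(outo$spectra$intensities - outp$spectra$intensities)),
            1e-6 * c0)
})

test_that("mean centering computes, applies and inverts correctly", {
  s <- make_set(matrix(c(1, 3, 3, 5), 2, 2, byrow = TRUE), c(1, 2))
  mc <- mean_center(s)
  expect_equal(mc$means, c(2, 4))
  expect_equal(unname(mc$spectra$intensities),
               matrix(c(-1, -1, 1, 1), 2, 2, byrow = TRUE))
  expect_lt(max(abs(colMeans(mc$spectra$intensities))), 1e-12)

  ## validation centering with stored means is invertible
  v <- make_set(matrix(c(10, 20), 1), c(1, 2))
  vc <- mean_center(v, mc$means)
  expect_equal(sweep(vc$spectra$intensities, 2, mc$means, `+`),
               v$intensities)
})

test_that("the full chain logs six steps in order and disabling all steps is the identity", {
  sc <- get_small_cohort()
  pp <- suppressWarnings(run_preprocess(sc$spectra, preprocess_config()))
  steps <- vapply(pp$state$log, `[[`, character(1), "step")
  expect_equal(steps, c("delete_water", "cow_align", "normalize_total_area",
                        "delete_solvent_downfield", "baseline_correct",
                        "mean_center"))

  off <- preprocess_config(water = list(), cow = NULL, normalize = FALSE,
                           solvent = list(), max_ppm = Inf, baseline = NULL,
                           center = FALSE)
  id <- run_preprocess(sc$spectra, off)
  expect_identical(id$spectra$intensities, sc$spectra$intensities)
  expect_length(id$state$log, 0L)
})

test_that("deletion and normalization are row-permutation equivariant", {
  set.seed(19)
  X <- matrix(abs(rnorm(5 * 40)) + 0.1, 5, 40)
  s <- make_set(X)
  perm <- c(3, 1, 5, 2, 4)
  sp <- make_set(X[perm, ])

  d <- delete_regions(s, list(c(2, 4)))
  dp <- delete_regions(sp, list(c(2, 4)))
  expect_equal(unname(dp$intensities), unname(d$intensities[perm, ]))

  n <- normalize_total_area(s)
  np <- normalize_total_area(sp)
  expect_equal(unname(np$intensities), unname(n$intensities[perm, ]))
})

test_that("preprocessing state round-trips through JSON", {
  sc <- get_small_cohort()
  pp <- suppressWarnings(run_preprocess(sc$spectra, preprocess_config()))
  f <- tempfile(fileext = ".json")
  write_preprocess_state(pp$state, f)
  st <- read_preprocess_state(f)
  expect_s3_class(st, "preprocess_state")
  expect_equal(st$config$cow$segment_length, 80L)
  expect_equal(st$config$baseline$lambda, 1e5)
  expect_equal(st$retained_ppm, pp$state$retained_ppm, tolerance = 1e-12)
  expect_equal(st$means, pp$state$means, tolerance = 1e-12)
  expect_equal(st$cow_reference, pp$state$cow_reference, tolerance = 1e-12)
})
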