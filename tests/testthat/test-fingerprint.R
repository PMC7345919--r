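## Unit tests for STOCSY, VIP-significant regions and the four-way
## metabolite classification.

fake_model <- function(ppm, vip, p_p) {
  structure(list(ppm = ppm, vip = vip, p_p = p_p), class = "opls")
}

test_that("STOCSY is exact at the driver and on duplicated columns", {
  set.seed(41)
  X <- matrix(rnorm(30 * 20), 30, 20)
  X[, 8] <- X[, 3]                          # duplicated column
  ppm <- seq(1, 2, length.out = 20)
  tr <- stocsy(X, ppm[3], ppm = ppm)
  expect_equal(tr$driver_ppm, ppm[3])
  expect_lt(abs(tr$r[3] - 1), 1e-9)
  expect_lt(abs(tr$r[8] - 1), 1e-9)
  expect_true(all(abs(tr$r) <= 1 + 1e-12))
  expect_error(stocsy(X, 5.0, ppm = ppm), "not on the retained axis")
})

test_that("STOCSY links peaks of one molecule and stays low across independent ones", {
  set.seed(42)
  n <- 248
  ppm <- seq(0, 1, length.out = 300)
  f1 <- exp(-(ppm - 0.25)^2 / 2e-4)
  f2 <- exp(-(ppm - 0.55)^2 / 2e-4)
  f3 <- exp(-(ppm - 0.85)^2 / 2e-4)
  a <- rlnorm(n, 0, 0.3)
  b <- rlnorm(n, 0, 0.3)                    # independent of a

  ## noise-free: two peaks of the same metabolite correlate >= 0.999
  X0 <- outer(a, f1 + f2)
  tr0 <- stocsy(X0, 0.25, ppm = ppm)
  expect_gte(tr0$r[which.min(abs(ppm - 0.55))], 0.999)

  ## noise on: cross-peak between independent metabolites stays < 0.2
  X <- outer(a, f1 + f2) + outer(b, f3) +
    matrix(rnorm(n * 300, 0, 0.05), n, 300)
  tr <- stocsy(X, 0.25, ppm = ppm)
  expect_lt(abs(tr$r[which.min(abs(ppm - 0.85))]), 0.2)
})

test_that("significant regions follow the run-length and threshold rules", {
  ppm <- c(1, 2, 3, 4)
  none <- significant_regions(c(0.5, 0.9, 0.2, 1.0), c(1, 1, 1, 1), ppm)
  expect_equal(nrow(none), 0L)

  two <- significant_regions(c(2, 2, 0, 2), c(0.3, -0.1, 0.2, -0.4), ppm)
  expect_equal(nrow(two), 2L)
  expect_equal(two$low_ppm, c(1, 4))
  expect_equal(two$high_ppm, c(2, 4))
  expect_equal(two$sign, c(1, -1))          # sign at each region's max-VIP bin

  ## raising the threshold never adds windows
  set.seed(43)
  for (r in 1:20) {
    v <- runif(50, 0, 3)
    l <- rnorm(50)
    p <- seq_len(50)
    n1 <- nrow(significant_regions(v, l, p, threshold = 1))
    n2 <- nrow(significant_regions(v, l, p, threshold = 1.5))
    keep1 <- sum(v > 1)
    keep2 <- sum(v > 1.5)
    expect_lte(keep2, keep1)
    if (n2 > 0) {
      w2 <- significant_regions(v, l, p, threshold = 1.5)
      ## every higher-threshold window lies inside a lower-threshold one
      w1 <- significant_regions(v, l, p, threshold = 1)
      inside <- vapply(seq_len(nrow(w2)), function(i)
        any(w1$low_ppm <= w2$low_ppm[i] & w1$high_ppm >= w2$high_ppm[i]),
        logical(1))
      expect_true(all(inside))
    }
  }
})

test_that("the classification rule table is exact and swap-symmetric", {
  ppm <- seq(1, 4, length.out = 40)
  ann <- data.frame(metabolite = c("m_pp", "m_opp", "m_bonly", "m_none"),
                    low_ppm = c(1.0, 1.8, 2.6, 3.4),
                    high_ppm = c(1.4, 2.2, 3.0, 3.8))
  in_win <- function(lo, hi) ppm >= lo & ppm <= hi
  v_b <- v_n <- rep(0.1, 40)
  l_b <- l_n <- rep(0.5, 40)
  v_b[in_win(1.0, 1.4)] <- 1.5; v_n[in_win(1.0, 1.4)] <- 1.5   # shared-positive
  v_b[in_win(1.8, 2.2)] <- 2.0; v_n[in_win(1.8, 2.2)] <- 2.0   # opposite
  l_n[in_win(1.8, 2.2)] <- -0.5
  v_b[in_win(2.6, 3.0)] <- 1.2                                  # bhba-only
  mb <- fake_model(ppm, v_b, l_b)
  mn <- fake_model(ppm, v_n, l_n)

  fp <- classify_metabolites(mb, mn, ann)
  cls <- setNames(fp$class, fp$metabolite)
  expect_equal(cls[["m_pp"]], "shared-positive")
  expect_equal(cls[["m_opp"]], "opposite")
  expect_equal(cls[["m_bonly"]], "bhba-only")
  expect_equal(cls[["m_none"]], "neither")

  ## swapping the models maps bhba-only <-> nefa-only, keeps the rest
  sw <- classify_metabolites(mn, mb, ann)
  cls2 <- setNames(sw$class, sw$metabolite)
  expect_equal(cls2[["m_pp"]], "shared-positive")
  expect_equal(cls2[["m_opp"]], "opposite")
  expect_equal(cls2[["m_bonly"]], "nefa-only")
  expect_equal(cls2[["m_none"]], "neither")

  ## ordering is deterministic: class then name
  expect_equal(fp$metabolite, fp$metabolite[order(fp$class, fp$metabolite)])
})

test_that("annotation windows cover the fingerprint metabolites and respect exclusions", {
  ann <- default_annotations()
  expect_false(any(ann$metabolite %in% c("bhba", "formate")))
  expect_true("glucose" %in% ann$metabolite)
  expect_false(any(c("glucose_alpha", "glucose_beta") %in% ann$metabolite))
  expect_equal(sort(unique(ann$metabolite)),
               sort(planted_fingerprint()$metabolite))
  expect_true(all(ann$low_ppm < ann$high_ppm))
  expect_true(all(ann$low_ppm > 0.2 & ann$high_ppm < 9.0))
})

test_that("the fingerprint report is deterministic and complete", {
  ppm <- seq(1, 4, length.out = 40)
  ann <- data.frame(metabolite = c("x", "y"),
                    low_ppm = c(1.0, 2.0), high_ppm = c(1.4, 2.4))
  v <- rep(0.1, 40); v[ppm <= 1.4] <- 1.5
  m1 <- fake_model(ppm, v, rep(1, 40))
  m2 <- fake_model(ppm, rep(0.1, 40), rep(1, 40))
  fp <- classify_metabolites(m1, m2, ann)
  expect_equal(nrow(fp), 2L)                # one row per annotated metabolite

  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  fingerprint_report(fp, path = f1)
  fingerprint_report(fp, path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  rep <- fingerprint_report(fp)
  expect_equal(rep$n_significant, 1L)
  expect_equal(rep$class_counts[["bhba-only"]], 1L)
  expect_equal(rep$class_counts[["neither"]], 1L)
})
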