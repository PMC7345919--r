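## Generator contracts: signature library content, cohort draws, spectral
## rendering, and ground-truth recovery on the full-scale study fixture.

test_that("the signature library carries the expected assignments", {
  lib <- default_library()
  expect_gte(length(lib), 18L)

  d <- lib[["dmso2"]]
  expect_equal(nrow(d), 1L)
  expect_equal(d$pattern, "singlet")
  expect_equal(d$center_ppm, 3.14)

  g <- lib[["nag"]]
  expect_equal(nrow(g), 1L)
  expect_equal(g$center_ppm, 2.03)

  for (m in names(lib))
    expect_lt(abs(sum(lib[[m]]$rel_area) - 1), 1e-9)
})

test_that("cohort draws match the planted biomarker moments and correlation", {
  sp <- cohort_spec(n_samples = 100000, biomarker_correlation = 0.45,
                    seed = 1L)
  ct <- draw_cohort(sp)
  r <- cor(ct$bhba_mmol_l, ct$nefa_mmol_l)
  expect_gte(r, 0.40)
  expect_lte(r, 0.50)

  sp2 <- cohort_spec(n_samples = 248, seed = 5L)
  ct2 <- draw_cohort(sp2)
  expect_lt(abs(mean(ct2$bhba_mmol_l) - 0.55), 3 * 0.21 / sqrt(248))
  expect_lt(abs(mean(ct2$nefa_mmol_l) - 0.75), 3 * 0.32 / sqrt(248))
  expect_true(all(ct2$bhba_mmol_l > 0))
  expect_true(all(ct2$nefa_mmol_l > 0))
  expect_true(all(ct2$dim_days >= 4 & ct2$dim_days <= 30))
  expect_false(any(duplicated(ct2$sample_id)))
})

test_that("zero planted effects leave concentrations uncorrelated with the biomarkers", {
  eff <- default_effects()
  eff$r_bhba <- 0
  eff$r_nefa <- 0
  sp <- cohort_spec(n_samples = 300, effects = eff, seed = 8L)
  ct <- draw_cohort(sp)
  for (m in eff$metabolite) {
    cc <- log(ct[[paste0("conc.", m)]])
    expect_lt(abs(cor(cc, log(ct$bhba_mmol_l))), 3 / sqrt(300))
    expect_lt(abs(cor(cc, log(ct$nefa_mmol_l))), 3 / sqrt(300))
  }
})

test_that("the planted effect table carries the reported sign pattern", {
  eff <- default_effects()
  e <- function(m, col) eff[eff$metabolite == m, col]
  expect_gt(e("acetate", "r_bhba"), 0)
  expect_lt(e("acetate", "r_nefa"), 0)
  expect_gt(e("creatine", "r_bhba"), 0)
  expect_lt(e("creatine", "r_nefa"), 0)
  for (m in c("glucose_alpha", "glucose_beta", "lactate", "alanine",
              "valine")) {
    expect_lt(e(m, "r_bhba"), 0)
    expect_lt(e(m, "r_nefa"), 0)
  }
  for (m in c("glycine", "phosphocholine", "ldl", "vldl", "nag")) {
    expect_gt(e(m, "r_bhba"), 0)
    expect_gt(e(m, "r_nefa"), 0)
  }
  expect_gt(e("betaine", "r_bhba"), 0)
  expect_equal(e("betaine", "r_nefa"), 0)
  expect_lt(e("dmso2", "r_bhba"), 0)
  expect_equal(e("dmso2", "r_nefa"), 0)
  expect_gt(e("isoleucine", "r_nefa"), 0)
  expect_equal(e("isoleucine", "r_bhba"), 0)
  expect_lt(e("leucine", "r_nefa"), 0)
  expect_equal(e("formate", "r_bhba"), 0)
  expect_equal(e("formate", "r_nefa"), 0)
})

test_that("rendering is linear in concentration and area-faithful", {
  ## isolate one metabolite by differencing two renders that share the
  ## whole nuisance draw (same seed, same RNG consumption)
  mk_cohort <- function(conc) {
    ct <- data.frame(sample_id = "s1", dataset = "calibration",
                     conc.dmso2 = conc, stringsAsFactors = FALSE)
    class(ct) <- c("cohort_table", "data.frame")
    ct
  }
  sp <- cohort_spec(n_samples = 2, clutter = NULL, seed = 21L)
  axis <- default_axis()
  lib <- default_library()["dmso2"]
  class(lib) <- "signature_library"
  r0 <- render_spectra(mk_cohort(0), lib, sp, axis)
  r1 <- render_spectra(mk_cohort(1), lib, sp, axis)
  r2 <- render_spectra(mk_cohort(2), lib, sp, axis)

  pure <- r1$intensities[1, ] - r0$intensities[1, ]
  h <- diff(axis)[1]
  expect_lt(abs(sum(pure) * h - 1), 0.01)          # unit area at conc 1
  expect_equal(r2$intensities[1, ] - r0$intensities[1, ], 2 * pure,
               tolerance = 1e-9)                   # linearity

  ## bit-reproducibility of a full render
  sc <- get_small_cohort()
  again <- render_spectra(sc$cohort, default_library(), sc$spec,
                          axis = default_axis(n = 2048))
  expect_identical(again$intensities, sc$spectra$intensities)
})

test_that("a two-cohort study has the right shape and is seed-sensitive", {
  axis <- default_axis(n = 1024)
  st <- generate_study(seed = 5L, n_cal = 8, n_val = 4, axis = axis)
  expect_equal(nrow(st$calibration$spectra$intensities), 8L)
  expect_equal(nrow(st$validation$spectra$intensities), 4L)
  expect_equal(st$calibration$cohort$dataset[1], "calibration")
  expect_equal(st$validation$cohort$dataset[1], "validation")

  st2 <- generate_study(seed = 6L, n_cal = 8, n_val = 4, axis = axis)
  expect_false(identical(st$calibration$spectra$intensities,
                         st2$calibration$spectra$intensities))
})

test_that("integrated signal regions recover the true concentrations at study scale", {
  res <- get_default_study()
  st <- res$study
  raw <- st$calibration$spectra
  ct <- st$calibration$cohort
  lines <- nmrfp:::.library_lines(st$library)
  mets <- unique(lines$metabolite)
  cors <- vapply(mets, function(m) {
    pos <- lines$pos[lines$metabolite == m]
    idx <- rep(FALSE, length(raw$ppm))
    for (p in pos) idx <- idx | abs(raw$ppm - p) <= 0.01
    integral <- rowSums(raw$intensities[, idx, drop = FALSE])
    cor(integral, ct[[paste0("conc.", m)]])
  }, numeric(1))
  ## crowded multiplet regions (isoleucine under the leucine/valine
  ## envelope) and single weak lines near the clutter floor (formate)
  ## bound the attainable raw-integral correlation below the clean-region
  ## value, so the per-metabolite floor is looser than the bulk
  expect_true(all(cors > 0.8))
  expect_gt(median(cors), 0.93)
})

test_that("cohort tables round-trip through the TSV writers", {
  sp <- cohort_spec(n_samples = 6, seed = 3L)
  ct <- draw_cohort(sp)
  meta <- tempfile(fileext = ".tsv")
  truth <- tempfile(fileext = ".tsv")
  write_cohort_tsv(ct, meta, truth)
  back <- read_cohort_tsv(meta, truth)
  expect_equal(back$sample_id, ct$sample_id)
  expect_equal(back$bhba_mmol_l, ct$bhba_mmol_l, tolerance = 1e-12)
  expect_equal(back$conc.glycine, ct$conc.glycine, tolerance = 1e-12)
})

test_that("background resonances stay clear of annotated lines", {
  cl <- clutter_library()
  named <- nmrfp:::.library_lines(default_library())$pos
  expect_equal(nrow(cl), 800L)
  mind <- vapply(cl$pos, function(p) min(abs(named - p)), numeric(1))
  expect_true(all(mind > 0.035))
  expect_identical(cl, clutter_library())  # deterministic in its seed
})
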