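## Synthetic serum 1H NMR cohort generator. Emulates a two-cohort
## early-lactation dairy study: biomarkers (BHBA, NEFA) drawn from a
## moment-matched bivariate lognormal, metabolite concentrations tied to
## the biomarkers through planted marginal correlations, spectra rendered
## as Lorentzian multiplets with per-sample peak jitter, baseline drift,
## solvent artifacts and noise.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Planted marginal correlations between each metabolite's log
## concentration and the standardized biomarkers. The signs reproduce the
## reported fingerprint: glucose/lactate/alanine/valine negative for both
## biomarkers; glycine/phosphocholine/LDL/VLDL/glycoprotein positive for
## both; acetate and creatine positive-BHBA/negative-NEFA; betaine
## positive and dimethyl sulfone negative for BHBA only; isoleucine
## positive, leucine and hippurate negative for NEFA only. BHBA's own
## resonances track the BHBA assay almost exactly (it is the measured
## analyte); formate is a planted null. Magnitudes are a calibration of
## the generator, not reported values.
default_effects <- function() {
  ## base_conc values put the tallest line of every metabolite on a
  ## comparable intensity scale (broad envelopes carry more total area),
  ## as in protein-depleted serum where no single resolved resonance
  ## dwarfs the rest of the profile.
  tab <- rbind(
    bhba           = c( 0.97,  0.44, 1.55),
    glucose_alpha  = c(-0.66, -0.60, 2.00),
    glucose_beta   = c(-0.66, -0.60, 2.00),
    lactate        = c(-0.55, -0.50, 1.25),
    alanine        = c(-0.55, -0.50, 1.35),
    valine         = c(-0.52, -0.48, 2.00),
    glycine        = c( 0.55,  0.50, 0.50),
    phosphocholine = c( 0.55,  0.50, 0.67),
    ldl            = c( 0.55,  0.54, 6.00),
    vldl           = c( 0.55,  0.54, 6.00),
    nag            = c( 0.52,  0.50, 4.00),
    acetate        = c( 0.55, -0.46, 0.50),
    creatine       = c( 0.55, -0.42, 0.85),
    betaine        = c( 0.55,  0.00, 0.63),
    dmso2          = c(-0.55,  0.00, 0.50),
    isoleucine     = c( 0.00,  0.54, 1.00),
    leucine        = c( 0.00, -0.54, 1.45),
    hippurate      = c( 0.00, -0.48, 3.35),
    formate        = c( 0.00,  0.00, 0.63)
  )
  data.frame(metabolite = rownames(tab), r_bhba = tab[, 1], r_nefa = tab[, 2],
             base_conc = tab[, 3], log_cv = 0.30, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Unassigned background resonances
#'
#' Real serum spectra carry hundreds of resonances beyond the annotated
#' metabolites, many weakly coupled to the metabolic state. This library
#' plants such a background: singlet lines at fixed positions (kept clear
#' of every annotated multiplet line), each with its own median intensity
#' and small random marginal correlations with the standardized log
#' biomarkers. The background gives the spectra a realistic dense
#' covariance structure; without it the VIP normalization is dominated by
#' a handful of sparse peaks and the conventional VIP > 1 cutoff loses its
#' meaning. The library is deterministic in its seed and is shared by the
#' calibration and validation cohorts (it is chemistry, not sampling).
#'
#' @param n number of background resonances.
#' @param seed library seed (fixed by default; this is part of the
#'   generative design, not of a cohort draw).
#' @param ppm_range positions are drawn uniformly over this range.
#' @param min_gap minimum distance (ppm) to any annotated library line.
#' @param lib annotated signature library to keep clear of.
#' @return data frame `pos`, `base_conc`, `r_bhba`, `r_nefa`, `log_cv`,
#'   `hwhm`.
#' @export
clutter_library <- function(n = 800, seed = 42L, ppm_range = c(0.65, 8.95),
                            min_gap = 0.035, lib = default_library()) {
  named <- .library_lines(lib)$pos
  with_seed(seed, {
    pos <- numeric(0)
    while (length(pos) < n) {
      cand <- stats::runif(n, ppm_range[1], ppm_range[2])
      ok <- vapply(cand, function(p) all(abs(named - p) > min_gap),
                   logical(1))
      pos <- c(pos, cand[ok])
    }
    data.frame(pos = pos[seq_len(n)],
               base_conc = 0.5 * exp(stats::rnorm(n, 0, 0.35)),
               r_bhba = pmin(pmax(stats::rnorm(n, 0, 0.38), -0.45), 0.45),
               r_nefa = pmin(pmax(stats::rnorm(n, 0, 0.28), -0.45), 0.45),
               log_cv = 0.30, hwhm = 0.0015)
  })
}

#' Specification of one synthetic cohort
#'
#' Defaults reproduce the calibration-cohort conditions of the study the
#' generator emulates: BHBA mean 0.55 sd 0.21 mmol/L, NEFA mean 0.75 sd
#' 0.32 mmol/L, natural-scale Pearson correlation 0.45 between them.
#'
#' @param n_samples number of animals (>= 2).
#' @param bhba_mean,bhba_sd,nefa_mean,nefa_sd natural-scale biomarker
#'   moments (mmol/L); the bivariate lognormal is moment-matched to them.
#' @param biomarker_correlation target natural-scale Pearson correlation,
#'   |r| < 1.
#' @param effects data frame with columns `metabolite`, `r_bhba`,
#'   `r_nefa` (planted marginal correlations of log concentration with the
#'   standardized log biomarkers), `base_conc` (median concentration,
#'   arbitrary units) and `log_cv` (log-scale concentration sd).
#' @param clutter unassigned-background library from [clutter_library()],
#'   or `NULL` for clean spectra with annotated resonances only.
#' @param jitter_global_sd sd of the per-sample whole-spectrum shift (ppm).
#' @param jitter_local_sd sd of the smooth local shift field (ppm); three
#'   random-phase cosine terms (Gaussian quadrature pairs), exercising the
#'   warping step. Like the concentration residuals, the per-sample shift
#'   coefficients are orthogonalized in-sample against the biomarker
#'   scores: misalignment is nuisance, not signal.
#' @param baseline_order,baseline_coef_sd polynomial baseline drift order
#'   and coefficient sd (intensity units).
#' @param noise_sd iid Gaussian intensity noise sd.
#' @param dataset label written into the cohort table.
#' @param seed RNG seed for this cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 248,
                        bhba_mean = 0.55, bhba_sd = 0.21,
                        nefa_mean = 0.75, nefa_sd = 0.32,
                        biomarker_correlation = 0.45,
                        effects = default_effects(),
                        clutter = clutter_library(),
                        jitter_global_sd = 0.002,
                        jitter_local_sd = 0.004,
                        baseline_order = 2,
                        baseline_coef_sd = 0.3,
                        noise_sd = 0.6,
                        dataset = "calibration",
                        seed = 1L) {
  stopifnot(n_samples >= 2, abs(biomarker_correlation) < 1,
            bhba_sd >= 0, nefa_sd >= 0, jitter_global_sd >= 0,
            jitter_local_sd >= 0, baseline_coef_sd >= 0, noise_sd >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 bhba_mean = bhba_mean, bhba_sd = bhba_sd,
                 nefa_mean = nefa_mean, nefa_sd = nefa_sd,
                 biomarker_correlation = biomarker_correlation,
                 effects = effects, clutter = clutter,
                 jitter_global_sd = jitter_global_sd,
                 jitter_local_sd = jitter_local_sd,
                 baseline_order = baseline_order,
                 baseline_coef_sd = baseline_coef_sd,
                 noise_sd = noise_sd, dataset = dataset,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Lognormal parameters matched to natural-scale mean m and sd s.
.lnorm_match <- function(m, s) {
  sig2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sig2 / 2, sigma = sqrt(sig2))
}

## Log-scale correlation that produces natural-scale Pearson r for a
## bivariate lognormal with log sds s1, s2.
.lnorm_logcor <- function(r, s1, s2) {
  arg <- 1 + r * sqrt(expm1(s1^2) * expm1(s2^2))
  if (arg <= 0) stop("implied covariance is not positive definite")
  rl <- log(arg) / (s1 * s2)
  if (abs(rl) >= 1) stop("implied covariance is not positive definite")
  rl
}

#' Draw a synthetic cohort table
#'
#' Biomarkers come from a bivariate lognormal whose natural-scale moments
#' match `spec`; true metabolite log concentrations are linear in the
#' standardized log biomarkers with planted marginal correlations plus
#' biological noise orthogonalized in-sample against the biomarker scores
#' (so the planted couplings, including the nulls, are exact in the drawn
#' cohort rather than holding only in expectation). Days in milk are
#' uniform on 4..30; age and herd are categorical.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort_table` data frame with columns `sample_id`,
#'   `dataset`, `bhba_mmol_l`, `nefa_mmol_l`, `dim_days`, `age_years`,
#'   `herd`, and `conc.<metabolite>` ground-truth columns.
#' @export
draw_cohort <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_samples
    pb <- .lnorm_match(spec$bhba_mean, spec$bhba_sd)
    pn <- .lnorm_match(spec$nefa_mean, spec$nefa_sd)
    rl <- .lnorm_logcor(spec$biomarker_correlation, pb$sigma, pn$sigma)
    z1 <- stats::rnorm(n)
    z2 <- rl * z1 + sqrt(1 - rl^2) * stats::rnorm(n)
    bhba <- exp(pb$mu + pb$sigma * z1)
    nefa <- exp(pn$mu + pn$sigma * z2)

    eff <- spec$effects
    S <- matrix(c(1, rl, rl, 1), 2)
    Sinv <- solve(S)
    ## biological residuals are orthogonalized in-sample against the
    ## realized biomarker scores, so the planted marginal correlations are
    ## the cohort's ground truth (planted-null couplings are exactly zero,
    ## not merely zero in expectation)
    Q <- qr.Q(qr(cbind(1, z1, z2)))
    conc <- matrix(NA_real_, n, nrow(eff),
                   dimnames = list(NULL, eff$metabolite))
    for (k in seq_len(nrow(eff))) {
      m <- c(eff$r_bhba[k], eff$r_nefa[k])
      beta <- drop(Sinv %*% m)
      expl <- drop(m %*% Sinv %*% m)
      if (expl > 1 - 1e-9) expl <- 1 - 1e-9
      e <- stats::rnorm(n)
      e <- e - drop(Q %*% crossprod(Q, e))
      e <- e / stats::sd(e)
      u <- beta[1] * z1 + beta[2] * z2 + sqrt(1 - expl) * e
      conc[, k] <- eff$base_conc[k] * exp(eff$log_cv[k] * u)
    }

    out <- data.frame(
      sample_id = sprintf("%s_%03d", substr(spec$dataset, 1, 3), seq_len(n)),
      dataset = spec$dataset,
      bhba_mmol_l = bhba, nefa_mmol_l = nefa,
      dim_days = sample(4:30, n, replace = TRUE),
      age_years = sample(c(2, 3, 4, 5), n, replace = TRUE,
                         prob = c(0.3, 0.3, 0.25, 0.15)),
      herd = paste0("herd", sample(1:5, n, replace = TRUE)),
      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(conc)[
      , , drop = FALSE])
    names(out)[-(1:7)] <- paste0("conc.", eff$metabolite)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Default chemical-shift axis
#'
#' @param from,to axis limits (ppm).
#' @param n number of bins.
#' @return ascending numeric ppm vector.
#' @export
default_axis <- function(from = 0.20, to = 9.00, n = 8192) {
  seq(from, to, length.out = n)
}

## Area-normalized Lorentzian evaluated on the axis.
.lorentz <- function(ppm, center, hwhm) {
  (hwhm / pi) / (hwhm^2 + (ppm - center)^2)
}

## Smooth per-sample shift field: global offset plus three random-phase
## cosines over the axis span. Each cosine is parameterized as a Gaussian
## quadrature pair a cos + b sin (equivalent to a Rayleigh amplitude and a
## uniform phase), so the field is linear in its coefficients.
.shift_field <- function(ppm, coef, axis_range) {
  x <- (ppm - axis_range[1]) / diff(axis_range)
  f <- coef[1]
  for (j in 1:3)
    f <- f + coef[1 + j] * cos(2 * pi * j * x) +
      coef[4 + j] * sin(2 * pi * j * x)
  f
}

## Per-sample shift-field coefficients: column 1 global offset, columns
## 2-4 cosine and 5-7 sine quadrature coefficients. When the biomarker
## scores are supplied (and n permits), coefficients are orthogonalized
## in-sample against them so peak positions carry no sampling correlation
## with the responses: misalignment is nuisance, not signal.
.jitter_coefs <- function(n, global_sd, local_sd, Q = NULL) {
  J <- cbind(stats::rnorm(n, 0, global_sd),
             matrix(stats::rnorm(6 * n, 0, local_sd / sqrt(3)), n, 6))
  if (!is.null(Q) && n > ncol(Q) + 1) {
    for (j in seq_len(ncol(J))) {
      s <- stats::sd(J[, j])
      if (s > 0) {
        e <- J[, j] - drop(Q %*% crossprod(Q, J[, j]))
        J[, j] <- e * (s / stats::sd(e))
      }
    }
  }
  J
}

#' Render synthetic spectra for a cohort
#'
#' Each metabolite contributes Lorentzian multiplets (binomial line
#' intensities) scaled by its true concentration; peak positions are
#' perturbed by a per-sample global shift plus a smooth local shift field;
#' unassigned background resonances (see [clutter_library()]; their
#' concentrations are drawn here, coupled to the biomarkers through the
#' library's planted marginals), a polynomial baseline, a broad
#' macromolecular background hump, residual water (4.68-5.00 ppm) and
#' methanol (3.32-3.36 ppm) artifact peaks and iid Gaussian noise are
#' added. Randomness is seeded from `spec$seed + 1` so rendering is
#' reproducible independently of [draw_cohort()].
#'
#' @param cohort a `cohort_table` from [draw_cohort()].
#' @param lib a [default_library()]-style signature library.
#' @param spec the [cohort_spec()] used for the cohort.
#' @param axis ascending ppm axis covering every library peak.
#' @return a [spectra_set()].
#' @export
render_spectra <- function(cohort, lib = default_library(), spec,
                           axis = default_axis()) {
  lines <- .library_lines(lib)
  rng <- range(axis)
  out <- lines$pos < rng[1] | lines$pos > rng[2]
  if (any(out))
    stop("library peak outside axis for metabolite: ",
         paste(unique(lines$metabolite[out]), collapse = ", "))
  lines <- lines[paste0("conc.", lines$metabolite) %in% names(cohort), ,
                 drop = FALSE]
  n <- nrow(cohort)
  nb <- length(axis)
  cl <- spec$clutter
  if (!is.null(cl)) cl <- cl[cl$pos >= rng[1] & cl$pos <= rng[2], ,
                             drop = FALSE]
  ## biomarker z-scores recovered from the cohort table (when present):
  ## used for the background-resonance couplings and to orthogonalize the
  ## per-sample nuisance draws in-sample against the responses
  Q <- NULL; z1 <- z2 <- NULL
  if (all(c("bhba_mmol_l", "nefa_mmol_l") %in% names(cohort))) {
    pb <- .lnorm_match(spec$bhba_mean, spec$bhba_sd)
    pn <- .lnorm_match(spec$nefa_mean, spec$nefa_sd)
    z1 <- (log(cohort$bhba_mmol_l) - pb$mu) / pb$sigma
    z2 <- (log(cohort$nefa_mmol_l) - pn$mu) / pn$sigma
    if (n >= 4) Q <- qr.Q(qr(cbind(1, z1, z2)))
  }
  with_seed(spec$seed + 1L, {
    ## background-resonance concentrations: same planted-marginal scheme
    ## as draw_cohort
    Cc <- NULL
    if (!is.null(cl) && nrow(cl) > 0 && !is.null(z1)) {
      rl <- .lnorm_logcor(spec$biomarker_correlation, pb$sigma, pn$sigma)
      Sinv <- solve(matrix(c(1, rl, rl, 1), 2))
      Cc <- matrix(NA_real_, n, nrow(cl))
      for (k in seq_len(nrow(cl))) {
        m <- c(cl$r_bhba[k], cl$r_nefa[k])
        beta <- drop(Sinv %*% m)
        expl <- min(drop(m %*% Sinv %*% m), 1 - 1e-9)
        u <- beta[1] * z1 + beta[2] * z2 + sqrt(1 - expl) * stats::rnorm(n)
        Cc[, k] <- cl$base_conc[k] * exp(cl$log_cv[k] * u)
      }
    }
    J <- .jitter_coefs(n, spec$jitter_global_sd, spec$jitter_local_sd, Q)
    X <- matrix(0, n, nb)
    xs <- 2 * (axis - min(axis)) / diff(range(axis)) - 1
    arange <- range(axis)
    for (i in seq_len(n)) {
      sh <- .shift_field(lines$pos, J[i, ], arange)
      row <- numeric(nb)
      conc <- as.numeric(cohort[i, paste0("conc.", lines$metabolite)])
      amp <- conc * lines$area
      for (k in seq_len(nrow(lines)))
        row <- row + amp[k] * .lorentz(axis, lines$pos[k] + sh[k], lines$hwhm[k])
      if (!is.null(Cc)) {
        sh_c <- .shift_field(cl$pos, J[i, ], arange)
        for (k in seq_len(nrow(cl)))
          row <- row + Cc[i, k] * .lorentz(axis, cl$pos[k] + sh_c[k],
                                           cl$hwhm[k])
      }
      ## stable broad macromolecular background hump
      bg <- exp(stats::rnorm(1, 0, 0.05))
      row <- row + bg * 60 * .lorentz(axis, 2.2, 1.4)
      ## residual water and methanol artifacts
      row <- row + exp(stats::rnorm(1, 0, 0.5)) * 8 * .lorentz(axis, 4.84, 0.08)
      row <- row + exp(stats::rnorm(1, 0, 0.5)) * 0.5 * .lorentz(axis, 3.34, 0.004)
      ## polynomial baseline drift
      coefs <- stats::rnorm(spec$baseline_order + 1, 0, spec$baseline_coef_sd)
      row <- row + drop(outer(xs, 0:spec$baseline_order, `^`) %*% coefs)
      if (spec$noise_sd > 0)
        row <- row + stats::rnorm(nb, 0, spec$noise_sd)
      X[i, ] <- row
    }
    spectra_set(X, axis, cohort$sample_id)
  })
}

## Flatten a signature library into one line table:
## metabolite | pos | area (rel_area * line weight) | hwhm.
.library_lines <- function(lib) {
  rows <- lapply(names(lib), function(m) {
    g <- lib[[m]]
    per <- lapply(seq_len(nrow(g)), function(j) {
      ml <- .multiplet_lines(g[j, ])
      data.frame(metabolite = m, pos = ml$pos,
                 area = g$rel_area[j] * ml$wt,
                 hwhm = g$width_ppm[j], stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  })
  do.call(rbind, rows)
}

#' Generate the full synthetic two-cohort study
#'
#' Calibration (n = 248) and validation (n = 50) cohorts under identical
#' generative settings but independent draws, mirroring the study design
#' the package emulates.
#'
#' @param seed master seed; cohort seeds are derived from it.
#' @param n_cal,n_val cohort sizes.
#' @param axis ppm axis passed to [render_spectra()].
#' @param lib signature library.
#' @param ... overrides forwarded to [cohort_spec()] for both cohorts.
#' @return list with `calibration` and `validation`, each holding
#'   `spectra` (a `spectra_set`), `cohort` (a `cohort_table`) and `spec`;
#'   plus `library` and `axis`.
#' @export
generate_study <- function(seed = 20200615L, n_cal = 248, n_val = 50,
                           axis = default_axis(), lib = default_library(),
                           ...) {
  seed <- as.integer(seed)
  make <- function(n, label, sd_offset) {
    sp <- cohort_spec(n_samples = n, dataset = label,
                      seed = (seed + sd_offset) %% .Machine$integer.max, ...)
    ct <- draw_cohort(sp)
    list(spectra = render_spectra(ct, lib, sp, axis), cohort = ct, spec = sp)
  }
  list(calibration = make(n_cal, "calibration", 0L),
       validation = make(n_val, "validation", 104729L),
       library = lib, axis = axis)
}

#' Write a cohort table as TSV
#'
#' The main metadata file mirrors a real study (no ground truth); true
#' metabolite concentrations go to a separate `*_truth.tsv` file.
#'
#' @param cohort a `cohort_table`.
#' @param path output path for the metadata TSV.
#' @param truth_path optional path for the ground-truth concentrations.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path, truth_path = NULL) {
  meta_cols <- c("sample_id", "dataset", "bhba_mmol_l", "nefa_mmol_l",
                 "dim_days", "age_years", "herd")
  utils::write.table(cohort[, meta_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth_path)) {
    tc <- c("sample_id", grep("^conc\\.", names(cohort), value = TRUE))
    utils::write.table(cohort[, tc], truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort table written by [write_cohort_tsv()]
#' @param path metadata TSV path.
#' @param truth_path optional ground-truth TSV path to merge back.
#' @return a `cohort_table`.
#' @export
read_cohort_tsv <- function(path, truth_path = NULL) {
  ct <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!is.null(truth_path)) {
    tr <- utils::read.table(truth_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    ct <- merge(ct, tr, by = "sample_id", sort = FALSE)
  }
  class(ct) <- c("cohort_table", "data.frame")
  ct
}
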