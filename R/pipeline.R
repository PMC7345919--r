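## End-to-end study runner: simulate (or load) -> preprocess -> PCA screen
## -> OPLS models for both biomarkers -> cross/external validation ->
## permutation tests -> ASCA -> fingerprint, with a fixed artifact layout
## and a manifest of seeds and file hashes.

#' Configuration for a full study run
#'
#' @param seed master seed for the synthetic study and all stochastic
#'   stages.
#' @param n_cal,n_val cohort sizes.
#' @param axis ppm axis for rendering.
#' @param preprocess a [preprocess_config()].
#' @param n_orth orthogonal-component policy: a count or `"auto"`.
#' @param max_orth bound scanned by the auto rule.
#' @param n_splits cross-validation fold count.
#' @param n_perm_model y-permutation iterations per model.
#' @param n_perm_asca ASCA permutations.
#' @param strict_cv when `TRUE`, cross-validation re-runs the full
#'   preprocessing chain per fold ([cross_validate_strict()]); default
#'   re-estimates only the centering means per fold.
#' @param exclude sample ids removed after the PCA screen (manual-review
#'   decision; flags alone never remove samples).
#' @param out_dir artifact directory, or `NULL` to skip writing.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 20200615L, n_cal = 248, n_val = 50,
                       axis = default_axis(),
                       preprocess = preprocess_config(),
                       n_orth = "auto", max_orth = 3, n_splits = 10,
                       n_perm_model = 50, n_perm_asca = 1000,
                       strict_cv = FALSE,
                       exclude = character(0), out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_cal = as.integer(n_cal),
                 n_val = as.integer(n_val),
                 axis = axis, preprocess = preprocess,
                 n_orth = if (identical(n_orth, "auto")) "auto"
                          else as.integer(n_orth),
                 max_orth = as.integer(max_orth),
                 n_splits = as.integer(n_splits),
                 n_perm_model = as.integer(n_perm_model),
                 n_perm_asca = as.integer(n_perm_asca),
                 strict_cv = isTRUE(strict_cv),
                 exclude = exclude, out_dir = out_dir),
            class = "run_config")
}

#' Run the full fingerprinting study
#'
#' Executes the complete workflow on a synthetic two-cohort study (or on
#' supplied data): PCA screening with Hotelling flags, preprocessing with
#' stored state, OPLS models for BHBA and NEFA, venetian-blind
#' cross-validation, external validation, y-permutation testing, ASCA of
#' the fixed effects, and the four-way metabolite fingerprint. When
#' `cfg$out_dir` is set, every artifact is written (tables as TSV, state,
#' models and reports as JSON) together with a manifest of seeds and md5
#' hashes.
#'
#' @param cfg a [run_config()].
#' @param study optional pre-generated study (as from [generate_study()]);
#'   generated from `cfg` when omitted.
#' @return a `study_result` list: `models`, `cv`, `external`,
#'   `permutation`, `asca`, `screen`, `fingerprint`, `state`, `processed`
#'   (the preprocessed calibration `spectra_set`), `study`, `manifest`.
#' @export
run_study <- function(cfg = run_config(), study = NULL) {
  if (is.null(study))
    study <- generate_study(seed = cfg$seed, n_cal = cfg$n_cal,
                            n_val = cfg$n_val, axis = cfg$axis)
  cal <- study$calibration
  val <- study$validation

  ## preprocess calibration, store state, replay on validation
  pp <- run_preprocess(cal$spectra, cfg$preprocess)

  ## PCA screen on the processed calibration data (advisory flags)
  pca <- fit_pca(pp$spectra, n_pc = 2)
  flags <- hotelling_flags(pca, 0.95)
  screen <- list(pca = pca, flags = flags,
                 flagged_ids = cal$spectra$sample_ids[flags$flagged])

  ## manual-review exclusions, then refit preprocessing without them
  keep <- !cal$spectra$sample_ids %in% cfg$exclude
  if (!all(keep)) {
    cal$spectra <- cal$spectra[keep, ]
    cal$cohort <- cal$cohort[keep, , drop = FALSE]
    pp <- run_preprocess(cal$spectra, cfg$preprocess)
  }
  Xc <- pp$spectra
  folds <- venetian_blinds(nrow(Xc$intensities), cfg$n_splits)

  fit_one <- function(response) {
    y <- cal$cohort[[response]]
    n_orth <- cfg$n_orth
    if (identical(n_orth, "auto"))
      n_orth <- select_n_orth(Xc$intensities, y, cfg$n_splits,
                              cfg$max_orth)$n_orth
    model <- opls(Xc, y, n_orth = n_orth)
    cv <- if (cfg$strict_cv)
      cross_validate_strict(cal$spectra, y, cfg$preprocess, n_orth, folds)
    else cross_validate(Xc$intensities, y, n_orth, folds)
    ext <- external_validate(model, pp$state, val$spectra,
                             val$cohort[[response]])
    perm <- permutation_test(Xc$intensities, y, n_orth, folds,
                             n_iter = cfg$n_perm_model,
                             seed = cfg$seed + 7L)
    list(model = model, cv = cv$report, cv_pred = cv$predictions,
         external = ext, permutation = perm, n_orth = n_orth)
  }
  bh <- fit_one("bhba_mmol_l")
  ne <- fit_one("nefa_mmol_l")

  asca_res <- asca(Xc$intensities, asca_design(cal$cohort),
                   n_perm = cfg$n_perm_asca, seed = cfg$seed + 11L)

  ann <- default_annotations(study$library)
  fp <- classify_metabolites(bh$model, ne$model, ann)
  report <- fingerprint_report(fp, reports = list(
    bhba_cv = bh$cv, bhba_external = bh$external,
    nefa_cv = ne$cv, nefa_external = ne$external))

  res <- list(models = list(bhba = bh$model, nefa = ne$model),
              cv = list(bhba = bh$cv, nefa = ne$cv),
              external = list(bhba = bh$external, nefa = ne$external),
              permutation = list(bhba = bh$permutation,
                                 nefa = ne$permutation),
              asca = asca_res, screen = screen, fingerprint = fp,
              report = report, state = pp$state, processed = Xc,
              study = study, config = cfg)
  if (!is.null(cfg$out_dir)) res$manifest <- .write_artifacts(res, cfg)
  class(res) <- "study_result"
  res
}

#' Serialize a run configuration to JSON
#'
#' The full configuration, including the ppm axis and nested preprocessing
#' settings, round-trips exactly: `read_run_config(write_run_config(cfg,
#' path))` reproduces `cfg` (up to the classed sub-configs, which are
#' rebuilt). `out_dir` is stored as given.
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `path`, invisibly (writer); a `run_config` (reader).
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  lst <- strip(cfg)
  ## encode axis doubles as shortest-exact strings; plain JSON numbers
  ## lose the last two significant digits in serialization
  lst$axis <- sprintf("%.17g", cfg$axis)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(seed = j$seed, n_cal = j$n_cal, n_val = j$n_val,
             axis = as.numeric(j$axis),
             preprocess = .rebuild_preprocess_config(j$preprocess),
             n_orth = if (identical(j$n_orth, "auto")) "auto"
                      else as.numeric(j$n_orth),
             max_orth = j$max_orth, n_splits = j$n_splits,
             n_perm_model = j$n_perm_model, n_perm_asca = j$n_perm_asca,
             strict_cv = isTRUE(j$strict_cv),
             exclude = as.character(j$exclude),
             out_dir = j$out_dir)
}

.write_artifacts <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$out_dir, ...)
  st <- res$study
  write_spectra_tsv(st$calibration$spectra, p("calibration_spectra.tsv"))
  write_spectra_tsv(st$validation$spectra, p("validation_spectra.tsv"))
  write_cohort_tsv(st$calibration$cohort, p("calibration_meta.tsv"),
                   p("calibration_truth.tsv"))
  write_cohort_tsv(st$validation$cohort, p("validation_meta.tsv"),
                   p("validation_truth.tsv"))
  write_preprocess_state(res$state, p("preprocess_state.json"))
  write_opls_json(res$models$bhba, p("model_bhba.json"))
  write_opls_json(res$models$nefa, p("model_nefa.json"))
  val_sum <- lapply(c(bhba = "bhba", nefa = "nefa"), function(k) list(
    cv = unclass(res$cv[[k]]),
    external = unclass(res$external[[k]])[c("r2", "rmse", "nrmse",
                                            "context", "n")],
    permutation = list(observed_r2 = res$permutation[[k]]$observed_r2,
                       empirical_p = res$permutation[[k]]$empirical_p,
                       wilcoxon_p = res$permutation[[k]]$wilcoxon_p)))
  jsonlite::write_json(val_sum, p("validation.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(effects = res$asca$effects,
                            residual_percent = res$asca$residual_percent),
                       p("asca.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  fingerprint_report(res$fingerprint, reports = list(
    bhba_cv = res$cv$bhba, bhba_external = res$external$bhba,
    nefa_cv = res$cv$nefa, nefa_external = res$external$nefa),
    path = p("fingerprint.json"))
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(seed = cfg$seed,
                   n_cal = cfg$n_cal, n_val = cfg$n_val,
                   n_orth = list(bhba = res$models$bhba$n_orth,
                                 nefa = res$models$nefa$n_orth),
                   exclude = cfg$exclude,
                   hashes = as.list(tools::md5sum(file.path(cfg$out_dir,
                                                            files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:\n")
  cat(sprintf("  BHBA: CV R2 = %.3f, external R2 = %.3f, NRMSE = %.3f, perm p = %.3g\n",
              x$cv$bhba$r2, x$external$bhba$r2, x$external$bhba$nrmse,
              x$permutation$bhba$empirical_p))
  cat(sprintf("  NEFA: CV R2 = %.3f, external R2 = %.3f, NRMSE = %.3f, perm p = %.3g\n",
              x$cv$nefa$r2, x$external$nefa$r2, x$external$nefa$nrmse,
              x$permutation$nefa$empirical_p))
  cat(sprintf("  ASCA fixed effects: %.2f%% of spectral variation\n",
              sum(x$asca$effects$percent)))
  cat(sprintf("  fingerprint: %d significant metabolites (%s)\n",
              sum(x$fingerprint$class != "neither"),
              paste(names(table(x$fingerprint$class)), collapse = ", ")))
  invisible(x)
}
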