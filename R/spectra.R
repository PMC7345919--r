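#' Spectra set container
#'
#' A `spectra_set` binds a sample-by-bin intensity matrix to a shared,
#' strictly monotone chemical-shift axis (ppm) and a vector of sample ids.
#' Every pipeline stage (region deletion, alignment, normalization,
#' baseline correction, centering) consumes and returns this container so
#' the axis and the matrix can never drift apart.
#'
#' @param intensities numeric matrix, one row per sample, one column per
#'   chemical-shift bin (arbitrary intensity units).
#' @param ppm numeric vector of bin positions in ppm, strictly monotone,
#'   length equal to `ncol(intensities)`.
#' @param sample_ids character vector of unique sample identifiers, length
#'   equal to `nrow(intensities)`. Defaults to existing rownames or
#'   `s1, s2, ...`.
#' @return An object of class `spectra_set` with elements `intensities`,
#'   `ppm` and `sample_ids`.
#' @export
spectra_set <- function(intensities, ppm, sample_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  ppm <- as.numeric(ppm)
  if (length(ppm) != ncol(intensities))
    stop("length(ppm) must equal ncol(intensities)")
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(intensities)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(intensities)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities))
    stop("sample_ids length must equal nrow(intensities)")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (anyNA(intensities))
    stop("intensity matrix contains NA")
  rownames(intensities) <- sample_ids
  structure(list(intensities = intensities, ppm = ppm, sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d bins, ppm %.4f .. %.4f\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$intensities)

#' Subset a spectra set
#'
#' @param x a `spectra_set`.
#' @param i sample (row) index.
#' @param j bin (column) index.
#' @param ... unused.
#' @return a `spectra_set` restricted to the selected samples and bins.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_along(x$ppm)
  spectra_set(x$intensities[i, j, drop = FALSE], x$ppm[j], x$sample_ids[i])
}

#' Write a spectra set as tab-separated text
#'
#' Header row holds the ppm axis (6 decimal places); first column the
#' sample id; one row per sample.
#'
#' @param s a `spectra_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_tsv <- function(s, path) {
  df <- data.frame(sample_id = s$sample_ids, s$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", sprintf("%.6f", s$ppm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectra set written by [write_spectra_tsv()]
#'
#' @param path input file path.
#' @return a `spectra_set`.
#' @export
read_spectra_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ppm <- as.numeric(colnames(df)[-1])
  spectra_set(as.matrix(df[, -1, drop = FALSE]), ppm, df[[1]])
}
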