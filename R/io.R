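#' Read a labelled spectral matrix
#'
#' The canonical on-disk format is a UTF-8 comma-delimited matrix: the label
#' columns `spectrum_id`, `patient_id`, `sample_id`, `t_stage`, `n_stage`,
#' `grade` followed by one column per wavenumber (header = the Raman shift in
#' decimal cm^-1), one spectrum per row. The `two_column_dir` dialect instead
#' reads a directory of per-spectrum two-column files (wavenumber, intensity)
#' whose labels come from a side table.
#'
#' @param path file (matrix_csv) or directory (two_column_dir).
#' @param dialect one of `"matrix_csv"`, `"two_column_dir"`.
#' @param labels optional side table (data frame or CSV path) supplying the
#'   label columns; required for `two_column_dir`, optional override for
#'   `matrix_csv`.
#' @param scheme a [label_scheme()] used for validation.
#' @return a [raman_dataset()]; row order of the file is preserved.
#' @export
read_spectra_matrix <- function(path, dialect = c("matrix_csv", "two_column_dir"),
                                labels = NULL, scheme = label_scheme()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.character(labels))
    labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
  if (dialect == "matrix_csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    label_cols <- c("spectrum_id", "patient_id", "sample_id",
                    "t_stage", "n_stage", "grade")
    have <- intersect(label_cols, names(df))
    spec_cols <- setdiff(names(df), label_cols)
    wn <- suppressWarnings(as.numeric(spec_cols))
    if (anyNA(wn))
      stop("malformed header: non-numeric wavenumber column(s): ",
           paste(utils::head(spec_cols[is.na(wn)], 3L), collapse = ", "),
           call. = FALSE)
    if (is.unsorted(wn, strictly = TRUE))
      stop("malformed header: wavenumber columns must be strictly ascending",
           call. = FALSE)
    mat <- as.matrix(df[, spec_cols, drop = FALSE])
    dimnames(mat) <- NULL
    if (is.null(labels)) {
      if (!length(have))
        stop("no label columns present and no side table supplied",
             call. = FALSE)
      labels <- df[, have, drop = FALSE]
    }
  } else {
    if (is.null(labels))
      stop("two_column_dir requires a label side table with spectrum_id",
           call. = FALSE)
    files <- file.path(path, paste0(labels$spectrum_id, ".txt"))
    miss <- !file.exists(files)
    if (any(miss))
      stop("missing spectrum file(s): ",
           paste(utils::head(basename(files[miss]), 3L), collapse = ", "),
           call. = FALSE)
    specs <- lapply(files, function(f) {
      m <- as.matrix(utils::read.table(f, col.names = c("wn", "y")))
      m
    })
    wn <- specs[[1L]][, 1L]
    same <- vapply(specs, function(m) length(m[, 1L]) == length(wn) &&
                     isTRUE(all.equal(m[, 1L], wn)), logical(1L))
    if (!all(same))
      stop("all spectra in a directory must share one wavenumber axis",
           call. = FALSE)
    mat <- do.call(rbind, lapply(specs, function(m) m[, 2L]))
  }
  labels <- complete_labels(labels)
  raman_dataset(mat, wn, labels, scheme)
}

# fill optional id columns so minimal tables are accepted
complete_labels <- function(labels) {
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  n <- nrow(labels)
  if (is.null(labels$spectrum_id))
    labels$spectrum_id <- sprintf("S%05d", seq_len(n))
  if (is.null(labels$patient_id)) labels$patient_id <- labels$spectrum_id
  if (is.null(labels$sample_id)) labels$sample_id <- labels$patient_id
  labels
}

#' Write a labelled spectral matrix
#'
#' Inverse of [read_spectra_matrix()] for the `matrix_csv` dialect. Intensities
#' are written with full double precision so a write/read round trip is the
#' identity up to floating-point text representation.
#'
#' @param ds a [raman_dataset()].
#' @param path output CSV path.
#' @export
write_spectra_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "raman_dataset"))
  # 17 significant digits: doubles survive the text round trip bit-exactly
  mat <- as.data.frame(matrix(sprintf("%.17g", ds$intensities),
                              nrow(ds$intensities)))
  names(mat) <- format(ds$wavenumbers, digits = 17, trim = TRUE,
                       scientific = FALSE)
  out <- cbind(ds$labels[c("spectrum_id", "patient_id", "sample_id",
                           "t_stage", "n_stage", "grade")], mat)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Persist a cross-validation metrics report
#'
#' Serialises an [mtn_cv()] report (cumulative confusion matrices, per-round
#' and aggregate metrics, ROC points) as JSON so it can be archived and
#' re-read losslessly with [read_report()].
#'
#' @param report an object of class `mtn_report`.
#' @param path output path (`.json`).
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "mtn_report"))
    stop("report must be an 'mtn_report'", call. = FALSE)
  if (!length(report$tasks))
    stop("empty report", call. = FALSE)
  ok <- tryCatch({
    jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor", null = "null", na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a metrics report written by [write_report()]
#' @param path JSON path.
#' @return an `mtn_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (tk in names(x$tasks)) {
    x$tasks[[tk]]$confusion <- as.matrix(x$tasks[[tk]]$confusion)
    storage.mode(x$tasks[[tk]]$confusion) <- "integer"
    dimnames(x$tasks[[tk]]$confusion) <-
      list(truth = x$tasks[[tk]]$classes, predicted = x$tasks[[tk]]$classes)
  }
  class(x) <- "mtn_report"
  x
}
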