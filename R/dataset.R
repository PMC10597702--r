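#' Construct a labelled Raman dataset
#'
#' Bundles a spectral matrix (one spectrum per row, shared wavenumber axis)
#' with the three per-spectrum categorical targets (T stage, N stage,
#' histological grade) and patient/sample identifiers.
#'
#' @param intensities numeric matrix, rows = spectra, columns = points on the
#'   shared axis.
#' @param wavenumbers numeric vector of Raman shifts (cm^-1), strictly
#'   ascending, length = `ncol(intensities)`.
#' @param labels data frame with one row per spectrum and columns
#'   `spectrum_id`, `patient_id`, `sample_id`, `t_stage`, `n_stage`, `grade`.
#' @param scheme a [label_scheme()]; all label values are validated against it.
#' @return An object of class `raman_dataset`.
#' @seealso [read_spectra_matrix()], [simulate_dataset()]
#' @export
raman_dataset <- function(intensities, wavenumbers, labels,
                          scheme = label_scheme()) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavenumbers <- as.double(wavenumbers)
  if (ncol(intensities) != length(wavenumbers))
    stop("wavenumber axis length must equal ncol(intensities)", call. = FALSE)
  if (is.unsorted(wavenumbers, strictly = TRUE))
    stop("wavenumber axis must be strictly ascending", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("all intensities must be finite", call. = FALSE)
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "patient_id", "sample_id",
            "t_stage", "n_stage", "grade")
  miss <- setdiff(need, names(labels))
  if (length(miss))
    stop("labels is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(labels) != nrow(intensities))
    stop("labels must have one row per spectrum", call. = FALSE)
  for (col in c("t_stage", "n_stage", "grade")) {
    labels[[col]] <- as.character(labels[[col]])
    lv <- switch(col, t_stage = scheme$t_classes, n_stage = scheme$n_classes,
                 grade = scheme$grade_classes)
    bad <- setdiff(unique(labels[[col]]), lv)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  rownames(intensities) <- labels$spectrum_id
  structure(list(intensities = intensities, wavenumbers = wavenumbers,
                 labels = labels, scheme = scheme),
            class = "raman_dataset")
}

#' @export
print.raman_dataset <- function(x, ...) {
  cat(sprintf("<raman_dataset> %d spectra x %d points, %.1f-%.1f cm^-1\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat("  grades: ",
      paste(sprintf("%s=%d", names(table(x$labels$grade)),
                    as.integer(table(x$labels$grade))), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.raman_dataset <- function(object, ...) {
  out <- list(
    n_spectra = nrow(object$intensities),
    n_points = ncol(object$intensities),
    range = range(object$wavenumbers),
    t_stage = table(factor(object$labels$t_stage, object$scheme$t_classes)),
    n_stage = table(factor(object$labels$n_stage, object$scheme$n_classes)),
    grade = table(factor(object$labels$grade, object$scheme$grade_classes)),
    n_patients = length(unique(object$labels$patient_id)))
  class(out) <- "summary.raman_dataset"
  out
}

#' @export
print.summary.raman_dataset <- function(x, ...) {
  cat(sprintf("%d spectra (%d patients), %d points, %.1f-%.1f cm^-1\n",
              x$n_spectra, x$n_patients, x$n_points, x$range[1], x$range[2]))
  cat("T stage counts:\n"); print(x$t_stage)
  cat("N stage counts:\n"); print(x$n_stage)
  cat("Grade counts:\n"); print(x$grade)
  invisible(x)
}

#' Subset a dataset by spectrum index
#' @param x a `raman_dataset`.
#' @param i integer or logical index over spectra.
#' @param ... ignored.
#' @export
`[.raman_dataset` <- function(x, i, ...) {
  raman_dataset(x$intensities[i, , drop = FALSE], x$wavenumbers,
                x$labels[i, , drop = FALSE], x$scheme)
}

#' Number of spectra in a dataset
#' @param ds a `raman_dataset`.
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' Extract one spectrum from a dataset
#' @param ds a `raman_dataset`.
#' @param i spectrum index.
#' @return a [raman_spectrum()].
#' @export
get_spectrum <- function(ds, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nrow(ds$intensities))
  raman_spectrum(ds$wavenumbers, ds$intensities[i, ],
                 meta = as.list(ds$labels[i, ]))
}

#' @export
plot.raman_dataset <- function(x, by = c("grade", "t_stage", "n_stage"),
                               ...) {
  by <- match.arg(by)
  cls <- unique(x$labels[[by]])
  cols <- grDevices::hcl.colors(max(3L, length(cls)), "Dark 3")
  means <- t(vapply(cls, function(cl)
    colMeans(x$intensities[x$labels[[by]] == cl, , drop = FALSE]),
    numeric(ncol(x$intensities))))
  graphics::matplot(x$wavenumbers, t(means), type = "l", lty = 1,
                    col = cols[seq_along(cls)],
                    xlab = expression(paste("Raman shift (", cm^-1, ")")),
                    ylab = "Mean intensity (a.u.)", ...)
  graphics::legend("topright", legend = cls, col = cols[seq_along(cls)],
                   lty = 1, bty = "n")
  invisible(x)
}

# internal: labels as 1-based integer indices into the scheme
label_indices <- function(ds) {
  list(t = match(ds$labels$t_stage, ds$scheme$t_classes),
       n = match(ds$labels$n_stage, ds$scheme$n_classes),
       g = match(ds$labels$grade, ds$scheme$grade_classes))
}

# internal: joint class key per spectrum
joint_class <- function(labels)
  paste(labels$t_stage, labels$n_stage, labels$grade, sep = "|")
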