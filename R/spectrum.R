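#' Construct a single Raman spectrum
#'
#' A spectrum couples a strictly ascending Raman-shift axis (cm^-1) with one
#' intensity trace (arbitrary detector units) and free-form acquisition
#' metadata (sample id, patient id, integration time, ...).
#'
#' @param wavenumbers numeric vector of Raman shifts in cm^-1, strictly
#'   ascending.
#' @param intensities numeric vector of intensities, same length as
#'   `wavenumbers`; all values must be finite.
#' @param meta named list of metadata.
#' @return An object of class `raman_spectrum`.
#' @examples
#' s <- raman_spectrum(400:1400, exp(-((400:1400 - 1004) / 6)^2))
#' s
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.double(wavenumbers)
  intensities <- as.double(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have the same length", call. = FALSE)
  if (length(wavenumbers) == 0L)
    stop("empty spectrum", call. = FALSE)
  if (any(!is.finite(wavenumbers)) || is.unsorted(wavenumbers, strictly = TRUE))
    stop("wavenumber axis must be finite and strictly ascending", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("all intensities must be finite", call. = FALSE)
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = as.list(meta)),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

#' @export
plot.raman_spectrum <- function(x, ...,
                                xlab = expression(paste("Raman shift (", cm^-1, ")")),
                                ylab = "Intensity (a.u.)", type = "l") {
  graphics::plot(x$wavenumbers, x$intensities, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Label scheme for the three diagnostic tasks
#'
#' Enumerates the class names of the three classification heads: seven T-stage
#' classes, five N-stage classes and five histological grades. Non-lesion
#' tissue carries the `health` (and benign/dysplastic the `BOD`) label in all
#' three tasks, which is how a 7/5/5-way head structure covers the cohort.
#'
#' @param t_classes,n_classes,grade_classes character vectors of ordered class
#'   names; lengths must be 7, 5 and 5.
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(t_classes = c("health", "BOD", "Tis", "T1", "T2", "T3", "T4"),
                         n_classes = c("health", "BOD", "N0", "N1", "N2"),
                         grade_classes = c("health", "BOD", "WD", "MD", "PD")) {
  if (length(t_classes) != 7L)
    stop("t_classes must contain exactly 7 class names", call. = FALSE)
  if (length(n_classes) != 5L)
    stop("n_classes must contain exactly 5 class names", call. = FALSE)
  if (length(grade_classes) != 5L)
    stop("grade_classes must contain exactly 5 class names", call. = FALSE)
  if (anyDuplicated(t_classes) || anyDuplicated(n_classes) ||
      anyDuplicated(grade_classes))
    stop("class names must be unique within a task", call. = FALSE)
  structure(list(t_classes = as.character(t_classes),
                 n_classes = as.character(n_classes),
                 grade_classes = as.character(grade_classes)),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme>\n")
  cat("  T stage:", paste(x$t_classes, collapse = ", "), "\n")
  cat("  N stage:", paste(x$n_classes, collapse = ", "), "\n")
  cat("  grade:  ", paste(x$grade_classes, collapse = ", "), "\n")
  invisible(x)
}
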