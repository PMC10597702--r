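#' Crop a spectrum or dataset to a wavenumber window
#'
#' Keeps all points with `lo <= wavenumber <= hi` (closed interval; both
#' endpoints are retained when present on the axis).
#'
#' @param x a [raman_spectrum()] or [raman_dataset()].
#' @param lo,hi window bounds in cm^-1 (defaults 400 and 1400, the analysis
#'   window for oral-tissue fingerprint spectra).
#' @return object of the same class restricted to the window.
#' @export
crop_range <- function(x, lo = 400, hi = 1400) UseMethod("crop_range")

#' @export
crop_range.raman_spectrum <- function(x, lo = 400, hi = 1400) {
  keep <- crop_keep(x$wavenumbers, lo, hi)
  raman_spectrum(x$wavenumbers[keep], x$intensities[keep], x$meta)
}

#' @export
crop_range.raman_dataset <- function(x, lo = 400, hi = 1400) {
  keep <- crop_keep(x$wavenumbers, lo, hi)
  raman_dataset(x$intensities[, keep, drop = FALSE], x$wavenumbers[keep],
                x$labels, x$scheme)
}

crop_keep <- function(wn, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  keep <- wn >= lo & wn <= hi
  if (!any(keep))
    stop(sprintf("window [%g, %g] does not overlap the axis [%g, %g]",
                 lo, hi, min(wn), max(wn)), call. = FALSE)
  keep
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()]. A
#' window of `window` points and fit order `polyorder` reproduces any
#' polynomial of degree `<= polyorder` exactly while attenuating
#' high-frequency noise.
#'
#' @param x a [raman_spectrum()] or [raman_dataset()].
#' @param window odd window length in points (> `polyorder`).
#' @param polyorder polynomial order of the local fits.
#' @export
savitzky_golay <- function(x, window = 11L, polyorder = 3L)
  UseMethod("savitzky_golay")

#' @export
savitzky_golay.raman_spectrum <- function(x, window = 11L, polyorder = 3L) {
  raman_spectrum(x$wavenumbers,
                 sg_core(x$intensities, window, polyorder), x$meta)
}

#' @export
savitzky_golay.raman_dataset <- function(x, window = 11L, polyorder = 3L) {
  y <- t(apply(x$intensities, 1L, sg_core, window = window,
               polyorder = polyorder))
  raman_dataset(y, x$wavenumbers, x$labels, x$scheme)
}

sg_core <- function(y, window, polyorder) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window <= polyorder)
    stop("window must be odd and greater than polyorder", call. = FALSE)
  if (length(y) < window)
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  signal::sgolayfilt(y, p = polyorder, n = window)
}

#' Iterative polynomial baseline correction
#'
#' Removes the broad fluorescence background by a modified-polynomial
#' least-squares fit: a degree-`degree` polynomial is fitted to the trace,
#' points above the fit (beyond one residual standard deviation) are clipped
#' down to it, and the fit is repeated until the fitted curve changes by
#' less than `tol` (relative L2) or `max_iter` iterations. Clipping stops
#' Raman peaks from dragging the baseline upward, so peak heights survive
#' while the smooth background is subtracted.
#'
#' @param x a [raman_spectrum()] or [raman_dataset()].
#' @param degree polynomial degree (default 5: flexible enough for the broad
#'   fluorescence hump over a 1000 cm^-1 window without chasing peaks).
#' @param max_iter maximum clip/refit iterations.
#' @param tol relative change of the fitted baseline at which to stop.
#' @return the input with the estimated baseline subtracted.
#' @export
baseline_correct <- function(x, degree = 5L, max_iter = 100L, tol = 1e-4)
  UseMethod("baseline_correct")

#' @export
baseline_correct.raman_spectrum <- function(x, degree = 5L, max_iter = 100L,
                                            tol = 1e-4) {
  qrV <- baseline_design(x$wavenumbers, degree)
  raman_spectrum(x$wavenumbers,
                 x$intensities - baseline_fit(x$intensities, qrV,
                                              max_iter, tol),
                 x$meta)
}

#' @export
baseline_correct.raman_dataset <- function(x, degree = 5L, max_iter = 100L,
                                           tol = 1e-4) {
  qrV <- baseline_design(x$wavenumbers, degree)
  y <- t(apply(x$intensities, 1L, function(r)
    r - baseline_fit(r, qrV, max_iter, tol)))
  raman_dataset(y, x$wavenumbers, x$labels, x$scheme)
}

baseline_design <- function(wn, degree) {
  degree <- as.integer(degree)
  if (length(wn) <= degree + 1L)
    stop("spectrum too short for the requested baseline degree", call. = FALSE)
  u <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1  # [-1, 1] for conditioning
  V <- outer(u, 0:degree, `^`)
  qrV <- qr(V)
  if (qrV$rank < ncol(V))
    stop("singular baseline design (degenerate axis)", call. = FALSE)
  qrV
}

baseline_fit <- function(y, qrV, max_iter, tol) {
  w <- y
  fit_prev <- NULL
  for (i in seq_len(max_iter)) {
    fit <- qr.fitted(qrV, w)
    if (any(!is.finite(fit)))
      stop("baseline fit did not converge (non-finite solution)",
           call. = FALSE)
    if (!is.null(fit_prev)) {
      denom <- sqrt(sum(fit_prev^2))
      if (denom == 0 || sqrt(sum((fit - fit_prev)^2)) / denom < tol) break
    }
    fit_prev <- fit
    # deviation-guarded clipping: only points more than one residual
    # standard deviation above the fit are pulled down, so peaks are
    # flattened onto the background while genuine baseline points are not
    # dragged below it (removes the downward bias of plain clipping)
    w <- pmin(w, fit + stats::sd(w - fit))
  }
  fit
}

#' Min-max intensity normalisation
#'
#' Affine rescaling `(y - min) / (max - min)` so every spectrum spans exactly
#' \[0, 1\], making intensities comparable across acquisitions.
#'
#' @param x a [raman_spectrum()] or [raman_dataset()].
#' @export
minmax_normalize <- function(x) UseMethod("minmax_normalize")

#' @export
minmax_normalize.raman_spectrum <- function(x) {
  raman_spectrum(x$wavenumbers, minmax_core(x$intensities), x$meta)
}

#' @export
minmax_normalize.raman_dataset <- function(x) {
  y <- t(apply(x$intensities, 1L, minmax_core))
  raman_dataset(y, x$wavenumbers, x$labels, x$scheme)
}

minmax_core <- function(y) {
  rng <- range(y)
  # degenerate also when the span is only round-off on the trace magnitude
  if (rng[2] - rng[1] <= 1e-12 * max(abs(rng[1]), abs(rng[2]), 1))
    stop("constant spectrum cannot be min-max normalised", call. = FALSE)
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Class-balancing block averaging
#'
#' Replaces consecutive non-overlapping blocks of `k` spectra by their
#' pointwise mean, reducing over-represented classes. A trailing remainder
#' block of fewer than `k` spectra is dropped, so `n` inputs yield
#' `floor(n / k)` outputs. On a dataset, blocks are formed within each joint
#' (T, N, grade) class in row order so labels stay unambiguous.
#'
#' @param x a numeric matrix (rows = spectra) or a [raman_dataset()].
#' @param k averaging factor (`k >= 1`; `k = 1` returns the input spectra).
#' @return same type as `x`; an `"averaging_log"` attribute records the
#'   contributing spectrum indices/ids of every output block.
#' @export
average_reduce <- function(x, k) UseMethod("average_reduce")

#' @export
average_reduce.matrix <- function(x, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- nrow(x)
  m <- n %/% k
  used <- seq_len(m * k)
  grp <- rep(seq_len(m), each = k)
  out <- if (m == 0L) x[0L, , drop = FALSE]
         else rowsum(x[used, , drop = FALSE], grp, reorder = TRUE) / k
  attr(out, "averaging_log") <-
    lapply(seq_len(m), function(i) used[grp == i])
  out
}

#' @export
average_reduce.raman_dataset <- function(x, k) {
  avg_by_class(x, function(cls) k)
}

# internal: per-class block averaging with a class -> k resolver
avg_by_class <- function(ds, k_of_class) {
  cls <- joint_class(ds$labels)
  ord_classes <- unique(cls)
  mats <- list(); labs <- list(); log <- list()
  for (cl in ord_classes) {
    idx <- which(cls == cl)
    k <- as.integer(k_of_class(ds$labels[idx[1L], ]))
    m <- length(idx) %/% k
    if (m == 0L) {
      warning(sprintf("class %s has %d spectra < k = %d; dropped from output",
                      cl, length(idx), k), call. = FALSE)
      next
    }
    sub <- average_reduce(ds$intensities[idx, , drop = FALSE], k)
    first <- ds$labels[idx[seq(1L, by = k, length.out = m)], , drop = FALSE]
    first$spectrum_id <- sprintf("avg_%s_%03d", gsub("\\|", ".", cl),
                                 seq_len(m))
    mats[[cl]] <- sub
    labs[[cl]] <- first
    log[[cl]] <- lapply(attr(sub, "averaging_log"),
                        function(b) ds$labels$spectrum_id[idx[b]])
  }
  if (!length(mats))
    stop("no class retained any complete averaging block", call. = FALSE)
  out <- raman_dataset(do.call(rbind, mats), ds$wavenumbers,
                       do.call(rbind, labs), ds$scheme)
  attr(out, "averaging_log") <- log
  out
}

#' Remove abnormal spectra by correlation screening
#'
#' Flags spectra whose Pearson correlation with the pointwise median spectrum
#' of their joint (T, N, grade) class falls below `min_corr`. An auditable
#' surrogate for manual removal of visibly abnormal acquisitions: genuinely
#' aberrant traces (fiber glints, saturations, sign flips) decorrelate from
#' their class consensus.
#'
#' @param ds a [raman_dataset()].
#' @param min_corr correlation threshold in \[-1, 1\] (default 0.8).
#' @return the filtered dataset; attribute `"removal_log"` is a data frame of
#'   dropped spectra with their class and correlation.
#' @export
remove_outliers <- function(ds, min_corr = 0.8) {
  stopifnot(inherits(ds, "raman_dataset"))
  cls <- joint_class(ds$labels)
  keep <- rep(TRUE, nrow(ds$intensities))
  corr <- rep(NA_real_, nrow(ds$intensities))
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    med <- apply(ds$intensities[idx, , drop = FALSE], 2L, stats::median)
    r <- suppressWarnings(
      as.vector(stats::cor(t(ds$intensities[idx, , drop = FALSE]), med)))
    r[is.na(r)] <- 1  # zero-variance rows: identical class, keep
    corr[idx] <- r
    keep[idx] <- r >= min_corr
  }
  log <- data.frame(spectrum_id = ds$labels$spectrum_id[!keep],
                    class = cls[!keep], corr = corr[!keep],
                    stringsAsFactors = FALSE)
  if (!any(keep))
    warning("all spectra removed by the outlier screen", call. = FALSE)
  out <- ds[keep]
  attr(out, "removal_log") <- log
  out
}

#' Resample onto a uniform wavenumber grid
#'
#' Linear interpolation onto `target_length` evenly spaced points spanning the
#' existing axis; endpoints are preserved exactly. Used to bring spectra to
#' the fixed input length the network expects.
#'
#' @param x a [raman_spectrum()] or [raman_dataset()].
#' @param target_length number of output points (>= 2; default 2076, the
#'   network's native input length).
#' @export
resample_spectrum <- function(x, target_length = 2076L)
  UseMethod("resample_spectrum")

#' @export
resample_spectrum.raman_spectrum <- function(x, target_length = 2076L) {
  grid <- resample_grid(x$wavenumbers, target_length)
  raman_spectrum(grid, stats::approx(x$wavenumbers, x$intensities,
                                     xout = grid)$y, x$meta)
}

#' @export
resample_spectrum.raman_dataset <- function(x, target_length = 2076L) {
  grid <- resample_grid(x$wavenumbers, target_length)
  y <- t(apply(x$intensities, 1L, function(r)
    stats::approx(x$wavenumbers, r, xout = grid)$y))
  raman_dataset(y, grid, x$labels, x$scheme)
}

resample_grid <- function(wn, target_length) {
  target_length <- as.integer(target_length)
  if (target_length < 2L) stop("target_length must be >= 2", call. = FALSE)
  if (length(wn) < 2L) stop("need at least 2 points to resample",
                            call. = FALSE)
  seq(min(wn), max(wn), length.out = target_length)
}
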