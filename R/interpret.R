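#' Grad-CAM importance heatmap for one spectrum
#'
#' Gradient-weighted class activation mapping on the last backbone
#' convolutional feature map: per-channel weights are the global average of
#' the target-class score's gradient over positions, the weighted channel sum
#' is clipped at zero (only evidence *for* the class is kept), linearly
#' upsampled to the input resolution and normalised to a maximum of 1. With
#' a global-average-pooling neck the position-averaged gradient equals the
#' head's feature gradient, which is computed analytically by backpropagation
#' through the selected head alone.
#'
#' @param model a (typically trained) `mtn_model`.
#' @param s a preprocessed [raman_spectrum()] or numeric vector whose length
#'   matches the model input.
#' @param task one of `"t"`, `"n"`, `"g"`.
#' @param target_class class name (under `scheme`) or 1-based index.
#' @param scheme [label_scheme()] used to resolve class names.
#' @return an object of class `raman_heatmap` with fields `wavenumbers`,
#'   `importance` (in \[0, 1\]), `task`, `target_class` and `degenerate`
#'   (`TRUE` for an all-zero map, returned unnormalised).
#' @export
grad_cam <- function(model, s, task = c("g", "t", "n"), target_class,
                     scheme = label_scheme()) {
  task <- match.arg(task)
  stopifnot(inherits(model, "mtn_model"))
  if (inherits(s, "raman_spectrum")) {
    wn <- s$wavenumbers
    x <- s$intensities
  } else {
    x <- as.numeric(s)
    wn <- seq_len(length(x))
  }
  if (length(x) != model$config$input_length)
    stop("spectrum length does not match the model input length",
         call. = FALSE)
  cls_names <- switch(task, t = scheme$t_classes, n = scheme$n_classes,
                      g = scheme$grade_classes)
  if (is.character(target_class)) {
    ci <- match(target_class, cls_names)
    if (is.na(ci)) stop("unknown class: ", target_class, call. = FALSE)
  } else ci <- as.integer(target_class)
  K <- model$config$n_classes[[task]]
  if (ci < 1L || ci > K) stop("class index out of range", call. = FALSE)
  fw <- mtn_forward(model, matrix(x, nrow = 1L), training = FALSE)
  dlog <- matrix(0, 1L, K)
  dlog[1L, ci] <- 1
  dl <- list(); dl[[task]] <- dlog
  dfeats <- heads_bwd(model, fw$cache, dl)$dfeats
  dfeats <- bn_bwd(dfeats, fw$cache$neck)$dX  # through the neck normaliser
  L5 <- fw$stage5$L
  cam <- as.vector(fw$stage5$x %*% t(dfeats)) / L5
  cam <- pmax(cam, 0)
  pos5 <- seq(wn[1L], wn[length(wn)], length.out = L5)
  up <- stats::approx(pos5, cam, xout = wn)$y
  degenerate <- max(up) <= 0
  if (!degenerate) up <- up / max(up)
  structure(list(wavenumbers = wn, importance = up, task = task,
                 target_class = cls_names[ci], degenerate = degenerate),
            class = "raman_heatmap")
}

#' @export
print.raman_heatmap <- function(x, ...) {
  cat(sprintf("<raman_heatmap> task %s, class %s, %d points%s\n", x$task,
              x$target_class, length(x$importance),
              if (x$degenerate) " (degenerate: all-zero)" else ""))
  if (!x$degenerate)
    cat(sprintf("  peak importance at %.1f cm^-1\n",
                x$wavenumbers[which.max(x$importance)]))
  invisible(x)
}

#' @export
plot.raman_heatmap <- function(x, spectrum = NULL, ...) {
  graphics::plot(x$wavenumbers, x$importance, type = "h",
                 col = grDevices::hcl.colors(100, "Reds",
                                             rev = TRUE)[pmax(1L,
                   ceiling(99 * x$importance) + 1L)],
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Grad-CAM importance", ylim = c(0, 1), ...)
  if (!is.null(spectrum)) {
    y <- spectrum$intensities
    y <- (y - min(y)) / max(1e-12, diff(range(y)))
    graphics::lines(spectrum$wavenumbers, y, col = "grey30")
  }
  invisible(x)
}

#' Class-mean Grad-CAM heatmap
#'
#' Pointwise mean of the per-spectrum heatmaps over every dataset member of
#' the target class, renormalised to a maximum of 1.
#'
#' @param model an `mtn_model`.
#' @param ds a preprocessed [raman_dataset()].
#' @param task one of `"t"`, `"n"`, `"g"`.
#' @param target_class class name or index under the dataset's scheme.
#' @return a `raman_heatmap`.
#' @export
class_mean_heatmap <- function(model, ds, task = c("g", "t", "n"),
                               target_class) {
  task <- match.arg(task)
  stopifnot(inherits(ds, "raman_dataset"))
  col <- switch(task, t = "t_stage", n = "n_stage", g = "grade")
  cls_names <- switch(task, t = ds$scheme$t_classes,
                      n = ds$scheme$n_classes, g = ds$scheme$grade_classes)
  if (!is.character(target_class)) target_class <- cls_names[target_class]
  idx <- which(ds$labels[[col]] == target_class)
  if (!length(idx))
    stop("no spectra of class ", target_class, " in the dataset",
         call. = FALSE)
  acc <- NULL
  for (i in idx) {
    h <- grad_cam(model, get_spectrum(ds, i), task, target_class,
                  scheme = ds$scheme)
    acc <- if (is.null(acc)) h$importance else acc + h$importance
  }
  imp <- acc / length(idx)
  degenerate <- max(imp) <= 0
  if (!degenerate) imp <- imp / max(imp)
  structure(list(wavenumbers = ds$wavenumbers, importance = imp,
                 task = task, target_class = target_class,
                 degenerate = degenerate),
            class = "raman_heatmap")
}

#' Report the most important spectral bands
#'
#' Thresholds the heatmap at half its maximum, merges contiguous
#' above-threshold regions separated by less than 10 cm^-1, ranks regions by
#' peak importance (ties broken toward lower wavenumber) and annotates each
#' with the band-table assignments whose shifts fall inside it.
#'
#' @param h a `raman_heatmap`.
#' @param table a band table, see [raman_band_table()].
#' @param k maximum number of regions to report.
#' @return data frame with one row per region: `rank`, `wn_lo`, `wn_hi`,
#'   `peak_wn`, `importance`, `assignments`; empty for an all-zero heatmap.
#' @export
top_bands <- function(h, table = raman_band_table(), k = 3L) {
  stopifnot(inherits(h, "raman_heatmap"), k >= 1L)
  empty <- data.frame(rank = integer(), wn_lo = double(), wn_hi = double(),
                      peak_wn = double(), importance = double(),
                      assignments = character(),
                      stringsAsFactors = FALSE)
  if (h$degenerate || max(h$importance) <= 0) return(empty)
  above <- h$importance >= 0.5 * max(h$importance)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(regions)) return(empty)
  # merge regions whose gap is under 10 cm^-1
  merged <- regions[1L, , drop = FALSE]
  if (nrow(regions) > 1L) for (i in 2:nrow(regions)) {
    gap <- h$wavenumbers[regions$start[i]] -
      h$wavenumbers[merged$end[nrow(merged)]]
    if (gap < 10) merged$end[nrow(merged)] <- regions$end[i]
    else merged <- rbind(merged, regions[i, ])
  }
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    ix <- merged$start[i]:merged$end[i]
    pk <- ix[which.max(h$importance[ix])]
    lo <- h$wavenumbers[merged$start[i]]
    hi <- h$wavenumbers[merged$end[i]]
    hit <- table$shift_hi >= lo & table$shift_lo <= hi
    data.frame(wn_lo = lo, wn_hi = hi, peak_wn = h$wavenumbers[pk],
               importance = h$importance[pk],
               assignments = paste(table$assignment[hit], collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$importance, out$wn_lo), ]
  out <- utils::head(out, k)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
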