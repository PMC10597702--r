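#' Read a single spectrum from a JCAMP-DX file
#'
#' Minimal reader for the two tabular JCAMP-DX data layouts that Raman
#' spectrometers commonly export: `(XY..XY)` pairs and `(X++(Y..Y))` with
#' `FIRSTX`/`DELTAX`/`YFACTOR`. Compressed (DIF/DUP/SQZ) encodings are not
#' supported; use the CSV matrix format for pipeline work.
#'
#' @param path path to a `.jdx`/`.dx` file.
#' @return a [raman_spectrum()] with title/units carried in `meta`.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lab <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]+=", "", hit[1L]))
  }
  start <- grep("^##(XYDATA|XYPOINTS|PEAK TABLE)=", lines, ignore.case = TRUE)
  if (!length(start))
    stop("no XYDATA/XYPOINTS block found in ", path, call. = FALSE)
  form <- toupper(sub("^##[^=]+=", "", lines[start[1L]]))
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- end[end > start[1L]][1L]
  if (is.na(end)) end <- length(lines) + 1L
  body <- lines[(start[1L] + 1L):(end - 1L)]
  body <- body[!grepl("^\\$\\$|^##", body) & nzchar(trimws(body))]
  num <- function(s) {
    v <- lab(s)
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  if (grepl("X\\+\\+", form)) {
    firstx <- num("FIRSTX"); deltax <- num("DELTAX")
    yfac <- num("YFACTOR"); xfac <- num("XFACTOR")
    if (!is.finite(yfac)) yfac <- 1
    if (!is.finite(xfac)) xfac <- 1
    rows <- lapply(body, function(l) {
      v <- as.numeric(strsplit(trimws(l), "[ ,\t]+")[[1L]])
      if (anyNA(v)) stop("unsupported/compressed JCAMP line: ", l,
                         call. = FALSE)
      v
    })
    if (!is.finite(deltax)) {
      x1 <- rows[[1L]][1L] * xfac
      x2 <- if (length(rows) > 1L) rows[[2L]][1L] * xfac else NA_real_
      npts1 <- length(rows[[1L]]) - 1L
      deltax <- (x2 - x1) / npts1
    } else deltax <- deltax * xfac
    xs <- ys <- list()
    for (i in seq_along(rows)) {
      y <- rows[[i]][-1L] * yfac
      x0 <- rows[[i]][1L] * xfac
      xs[[i]] <- x0 + deltax * (seq_along(y) - 1L)
      ys[[i]] <- y
    }
    wn <- unlist(xs); y <- unlist(ys)
  } else {
    v <- as.numeric(unlist(strsplit(trimws(body), "[ ,;\t]+")))
    if (anyNA(v) || length(v) %% 2L)
      stop("malformed XY pair data in ", path, call. = FALSE)
    wn <- v[seq(1L, length(v), 2L)]
    y <- v[seq(2L, length(v), 2L)]
  }
  o <- order(wn)
  raman_spectrum(wn[o], y[o],
                 meta = list(title = lab("TITLE"), xunits = lab("XUNITS"),
                             yunits = lab("YUNITS"), source = path))
}
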