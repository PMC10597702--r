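#' Simulator configuration
#'
#' Defines the acquisition axis, cohort composition and stochastic components
#' of the synthetic oral-tissue Raman generator. Spectra are sums of
#' Lorentzian bands (half-width at half-maximum 6 cm^-1, the probe's spectral
#' resolution) on a concave fluorescence background with additive Gaussian
#' shot-like noise. Class differences enter as multiplicative amplitude steps
#' applied cumulatively along the progression chains Tis -> TI -> TII,
#' N0 -> N1 -> N2 and WD -> MD -> PD at the transition bands of the study.
#'
#' @param axis_lo,axis_hi axis range in cm^-1 (default 400-1400, the
#'   fingerprint analysis window).
#' @param n_points points on the simulated axis (default 1001, ~1 cm^-1
#'   spacing).
#' @param seed integer master seed; every spectrum derives its own stream.
#' @param composition data frame (`t_stage`, `n_stage`, `grade`, `n`) of
#'   spectrum counts per joint class; default [default_composition()].
#' @param amplitude_step fractional amplitude change per stage transition
#'   (default 0.25).
#' @param within_class_jitter fractional s.d. of per-spectrum peak-amplitude
#'   variation (default 0.05).
#' @param noise_sd additive Gaussian noise s.d. on the simulator amplitude
#'   scale, whose maximum band amplitude is 0.9 (default 0.02).
#' @param peak_hwhm Lorentzian half-width at half-maximum in cm^-1.
#' @param peak_shape `"lorentzian"` (natural Raman lineshape) or
#'   `"gaussian"`.
#' @param baseline_scale fluorescence background amplitude as a multiple of
#'   the maximum band amplitude (default 5: fluorescence-dominated raw
#'   spectra, as the baseline-correction stage expects).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(axis_lo = 400, axis_hi = 1400, n_points = 1001L,
                       seed = 1L, composition = default_composition(),
                       amplitude_step = 0.25, within_class_jitter = 0.05,
                       noise_sd = 0.02, peak_hwhm = 6,
                       peak_shape = c("lorentzian", "gaussian"),
                       baseline_scale = 5) {
  peak_shape <- match.arg(peak_shape)
  stopifnot(axis_lo < axis_hi, n_points >= 2L, all(composition$n >= 0),
            within_class_jitter >= 0, within_class_jitter < 1,
            noise_sd >= 0, peak_hwhm > 0, amplitude_step >= 0)
  structure(list(axis_lo = axis_lo, axis_hi = axis_hi,
                 n_points = as.integer(n_points), seed = as.integer(seed),
                 composition = composition, amplitude_step = amplitude_step,
                 within_class_jitter = within_class_jitter,
                 noise_sd = noise_sd, peak_hwhm = peak_hwhm,
                 peak_shape = peak_shape, baseline_scale = baseline_scale),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %g-%g cm^-1 (%d pts), %d spectra in %d classes\n",
              x$axis_lo, x$axis_hi, x$n_points, sum(x$composition$n),
              nrow(x$composition)))
  cat(sprintf("  step %.2f, jitter %.2f, noise %.3f, HWHM %g (%s)\n",
              x$amplitude_step, x$within_class_jitter, x$noise_sd,
              x$peak_hwhm, x$peak_shape))
  invisible(x)
}

# how many cumulative transitions of each chain apply to a class
chain_level <- function(value, chain) {
  switch(chain,
         t = switch(value, Tis = 0L, T1 = 1L, T2 = 1L, T3 = 2L, T4 = 2L, 0L),
         n = switch(value, N0 = 0L, N1 = 1L, N2 = 2L, 0L),
         g = switch(value, WD = 0L, MD = 1L, PD = 2L, 0L))
}

#' Build the default class-conditional spectral profiles
#'
#' One profile per joint class in `cfg$composition`. All classes share a base
#' band set: the union of every transition band, the annotated band table,
#' and three generic tissue bands (1004, 1250, 1330 cm^-1). Healthy tissue
#' carries the band table's healthy intensity codes, malignant tissue the
#' lesional codes, and benign/dysplastic (BOD) tissue the midpoint of the
#' two (an intermediate band pattern); tumor classes then have each transition band's amplitude
#' multiplied by `(1 + amplitude_step)` (Increase) or `(1 - amplitude_step)`
#' (Decrease), cumulatively along the three progression chains. A transition
#' band missing from the base set would be added at amplitude
#' `amplitude_step` (with a message) rather than raising an error.
#'
#' @param cfg a [sim_config()].
#' @return named list of `class_profile` objects.
#' @export
build_default_profiles <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  bt <- raman_band_table()
  tr <- stage_transitions()
  ta <- transition_assignments()
  tr_centers <- sort(unique(unlist(lapply(unlist(tr, recursive = FALSE),
                                          unlist))))
  generic <- c(1004, 1250, 1330)
  centers <- sort(unique(c(tr_centers, bt$center, generic)))
  base_amp <- function(kind) {
    amp <- rep(0.5, length(centers))
    a_h <- code_amplitude[bt$code_health]
    a_l <- code_amplitude[bt$code_lesion]
    amp[match(bt$center, centers)] <- switch(kind,
      health = a_h,
      BOD = (a_h + a_l) / 2,  # benign/dysplastic: intermediate band pattern
      a_l)
    amp
  }
  assign_of <- function(cn) {
    i <- match(cn, bt$center)
    if (!is.na(i)) return(bt$assignment[i])
    a <- ta[as.character(cn)]
    if (!is.na(a)) return(unname(a))
    "Generic tissue band"
  }
  apply_chain <- function(amp, ctrs, chain, level) {
    steps <- tr[[chain]]
    for (s in seq_len(level)) {
      st <- steps[[s]]
      for (cn in st$inc) {
        i <- match(cn, ctrs)
        if (is.na(cn <- cn) || is.na(i)) {
          message("adding transition band ", cn, " absent from base set")
          ctrs <- c(ctrs, cn); amp <- c(amp, cfg$amplitude_step)
        } else amp[i] <- amp[i] * (1 + cfg$amplitude_step)
      }
      for (cn in st$dec) {
        i <- match(cn, ctrs)
        if (is.na(i)) {
          message("adding transition band ", cn, " absent from base set")
          ctrs <- c(ctrs, cn); amp <- c(amp, cfg$amplitude_step)
        } else amp[i] <- amp[i] * (1 - cfg$amplitude_step)
      }
    }
    list(amp = amp, ctrs = ctrs)
  }
  A <- max(code_amplitude)
  profiles <- list()
  for (r in seq_len(nrow(cfg$composition))) {
    row <- cfg$composition[r, ]
    kind <- if (row$t_stage %in% c("health", "BOD")) row$t_stage
            else "tumor"
    amp <- base_amp(kind); ctrs <- centers
    if (!(row$t_stage %in% c("health", "BOD"))) {
      res <- apply_chain(amp, ctrs, "t", chain_level(row$t_stage, "t"))
      res <- apply_chain(res$amp, res$ctrs, "n", chain_level(row$n_stage, "n"))
      res <- apply_chain(res$amp, res$ctrs, "g", chain_level(row$grade, "g"))
      amp <- res$amp; ctrs <- res$ctrs
    }
    o <- order(ctrs)
    peaks <- data.frame(center = ctrs[o], amplitude = amp[o],
                        width = cfg$peak_hwhm, shape = cfg$peak_shape,
                        assignment = vapply(ctrs[o], assign_of,
                                            character(1L)),
                        stringsAsFactors = FALSE)
    key <- paste(row$t_stage, row$n_stage, row$grade, sep = "|")
    profiles[[key]] <- structure(
      list(label_triplet = c(t_stage = row$t_stage, n_stage = row$n_stage,
                             grade = row$grade),
           peaks = peaks,
           baseline_coeffs = c(cfg$baseline_scale * A, 0,
                               -cfg$baseline_scale * A),
           noise_sd = cfg$noise_sd, n_spectra = row$n),
      class = "class_profile")
  }
  profiles
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf("<class_profile> %s: %d bands, noise sd %.3f, n = %d\n",
              paste(x$label_triplet, collapse = "|"), nrow(x$peaks),
              x$noise_sd, x$n_spectra))
  invisible(x)
}

peak_shape_eval <- function(wn, center, amplitude, width, shape) {
  u <- (wn - center) / width
  if (shape == "lorentzian") amplitude / (1 + u^2)
  else amplitude * exp(-log(2) * u^2)
}

# evaluate the deterministic (noise- and jitter-free) class mean of a profile
profile_mean_spectrum <- function(profile, cfg) {
  wn <- seq(cfg$axis_lo, cfg$axis_hi, length.out = cfg$n_points)
  y <- numeric(length(wn))
  for (i in seq_len(nrow(profile$peaks)))
    y <- y + peak_shape_eval(wn, profile$peaks$center[i],
                             profile$peaks$amplitude[i],
                             profile$peaks$width[i], profile$peaks$shape[i])
  u <- 2 * (wn - cfg$axis_lo) / (cfg$axis_hi - cfg$axis_lo) - 1
  b <- profile$baseline_coeffs
  y + b[1] + b[2] * u + b[3] * u^2
}

# run expr with a private RNG stream; caller's RNG state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate one spectrum from a class profile
#'
#' Intensities are the sum of the profile's bands (amplitudes jittered by
#' `cfg$within_class_jitter`), the polynomial fluorescence background, and
#' i.i.d. Gaussian noise of s.d. `profile$noise_sd`. Bit-identical for a
#' given seed.
#'
#' @param profile a `class_profile` from [build_default_profiles()].
#' @param cfg the [sim_config()].
#' @param seed integer seed for this spectrum.
#' @return a [raman_spectrum()].
#' @export
simulate_spectrum <- function(profile, cfg, seed) {
  stopifnot(inherits(profile, "class_profile"), inherits(cfg, "sim_config"))
  wn <- seq(cfg$axis_lo, cfg$axis_hi, length.out = cfg$n_points)
  with_seed(seed, {
    k <- nrow(profile$peaks)
    amp <- profile$peaks$amplitude *
      pmax(0, 1 + stats::rnorm(k) * cfg$within_class_jitter)
    y <- numeric(length(wn))
    for (i in seq_len(k))
      y <- y + peak_shape_eval(wn, profile$peaks$center[i], amp[i],
                               profile$peaks$width[i],
                               profile$peaks$shape[i])
    u <- 2 * (wn - cfg$axis_lo) / (cfg$axis_hi - cfg$axis_lo) - 1
    b <- profile$baseline_coeffs
    y <- y + b[1] + b[2] * u + b[3] * u^2
    if (profile$noise_sd > 0)
      y <- y + stats::rnorm(length(wn), sd = profile$noise_sd)
    raman_spectrum(wn, y, meta = c(as.list(profile$label_triplet),
                                   list(seed = seed)))
  })
}

#' Simulate a labelled cohort
#'
#' Draws `n` spectra per joint class of `cfg$composition` (or of custom
#' `profiles`), each from its own seed derived from `cfg$seed`, and attaches
#' labels. Synthetic patient ids are assigned in blocks of 90 spectra — one
#' simulated sample corresponds to 90 repeated probe measurements.
#'
#' @param cfg a [sim_config()].
#' @param profiles optional named list of `class_profile`s overriding
#'   [build_default_profiles()].
#' @return a [raman_dataset()].
#' @export
simulate_dataset <- function(cfg = sim_config(),
                             profiles = build_default_profiles(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  wn <- seq(cfg$axis_lo, cfg$axis_hi, length.out = cfg$n_points)
  total <- sum(vapply(profiles, function(p) p$n_spectra, numeric(1L)))
  mat <- matrix(0, nrow = total, ncol = length(wn))
  labs <- vector("list", length(profiles))
  counter <- 0L
  ri <- 0L
  for (key in names(profiles)) {
    p <- profiles[[key]]
    ri <- ri + 1L
    n <- p$n_spectra
    if (n == 0L) { labs[[ri]] <- NULL; next }
    rows <- counter + seq_len(n)
    for (j in seq_len(n)) {
      s <- simulate_spectrum(p, cfg,
                             seed = (cfg$seed + 9973 * (counter + j)) %%
                               .Machine$integer.max)
      mat[counter + j, ] <- s$intensities
    }
    labs[[ri]] <- data.frame(
      spectrum_id = sprintf("sim_%02d_%05d", ri, seq_len(n)),
      patient_id = sprintf("P%02d_%03d", ri, (seq_len(n) - 1L) %/% 90L + 1L),
      sample_id = sprintf("P%02d_%03d", ri, (seq_len(n) - 1L) %/% 90L + 1L),
      t_stage = p$label_triplet[["t_stage"]],
      n_stage = p$label_triplet[["n_stage"]],
      grade = p$label_triplet[["grade"]],
      stringsAsFactors = FALSE)
    counter <- counter + n
  }
  labs <- do.call(rbind, labs)
  if (is.null(labs) || !nrow(labs)) {
    return(raman_dataset(matrix(0, 0L, length(wn)), wn,
                         data.frame(spectrum_id = character(),
                                    patient_id = character(),
                                    sample_id = character(),
                                    t_stage = character(),
                                    n_stage = character(),
                                    grade = character())))
  }
  raman_dataset(mat[seq_len(nrow(labs)), , drop = FALSE], wn, labs)
}

#' Separable desk-scale benchmark cohort
#'
#' A 900-spectrum cohort of six well-separated joint classes (healthy, BOD,
#' and four tumor classes covering all five N-stage and grade labels and five
#' mutually distinguishable T labels), simulated with a strong transition
#' step (0.5) and low noise (0.005). Used for end-to-end recovery testing of
#' the network at reduced scale.
#'
#' @param seed master seed.
#' @param n_per_class spectra per joint class (default 150).
#' @param amplitude_step,noise_sd,n_points see [sim_config()].
#' @return a [sim_config()].
#' @export
sim_benchmark_config <- function(seed = 1L, n_per_class = 150L,
                                 amplitude_step = 0.5, noise_sd = 0.005,
                                 n_points = 1001L) {
  comp <- data.frame(
    t_stage = c("health", "BOD", "Tis", "T1", "T3", "T3"),
    n_stage = c("health", "BOD", "N0", "N0", "N1", "N2"),
    grade = c("health", "BOD", "WD", "WD", "MD", "PD"),
    n = rep(as.integer(n_per_class), 6L),
    stringsAsFactors = FALSE)
  sim_config(seed = seed, composition = comp, amplitude_step = amplitude_step,
             noise_sd = noise_sd, n_points = n_points)
}

#' Two-class single-band benchmark
#'
#' Two classes identical in every band except one discriminative peak whose
#' amplitude differs by `amplitude_ratio`; used to test that Grad-CAM
#' attribution localises the class evidence.
#'
#' @param cfg a [sim_config()] whose composition has exactly two rows.
#' @param peak discriminative band center in cm^-1 (must be a base-set band;
#'   default 1080).
#' @param amplitude_ratio multiplier applied to the second class's peak.
#' @return named list of two `class_profile`s.
#' @export
two_class_profiles <- function(cfg, peak = 1080, amplitude_ratio = 2) {
  stopifnot(nrow(cfg$composition) == 2L)
  base <- build_default_profiles(
    sim_config(axis_lo = cfg$axis_lo, axis_hi = cfg$axis_hi,
               n_points = cfg$n_points, seed = cfg$seed,
               composition = cfg$composition[1L, , drop = FALSE],
               amplitude_step = 0, within_class_jitter = cfg$within_class_jitter,
               noise_sd = cfg$noise_sd, peak_hwhm = cfg$peak_hwhm,
               peak_shape = cfg$peak_shape,
               baseline_scale = cfg$baseline_scale))[[1L]]
  i <- match(peak, base$peaks$center)
  if (is.na(i)) stop("peak must be one of the base-set band centers",
                     call. = FALSE)
  p1 <- base; p2 <- base
  p2$peaks$amplitude[i] <- p2$peaks$amplitude[i] * amplitude_ratio
  for (r in 1:2) {
    row <- cfg$composition[r, ]
    p <- if (r == 1L) p1 else p2
    p$label_triplet <- c(t_stage = row$t_stage, n_stage = row$n_stage,
                         grade = row$grade)
    p$n_spectra <- row$n
    if (r == 1L) p1 <- p else p2 <- p
  }
  out <- list(p1, p2)
  names(out) <- paste(cfg$composition$t_stage, cfg$composition$n_stage,
                      cfg$composition$grade, sep = "|")
  out
}
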