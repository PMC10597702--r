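# shared fixtures: everything is generated in code at test time

# small labelled dataset with two separable joint classes
tiny_dataset <- function(n_per_class = 10L, n_points = 64L, seed = 1L,
                         noise = 0.02) {
  set.seed(seed)
  wn <- seq(400, 1400, length.out = n_points)
  base <- 0.5 + 0.4 * sin(wn / 150)
  bump <- exp(-((wn - 900) / 30)^2)
  classes <- list(
    list(t = "health", n = "health", g = "health", shape = base),
    list(t = "T1", n = "N0", g = "WD", shape = base + 0.6 * bump))
  mats <- list(); labs <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[[ci]]
    m <- matrix(rep(cl$shape, each = n_per_class), n_per_class,
                byrow = FALSE) +
      matrix(rnorm(n_per_class * n_points, sd = noise), n_per_class)
    mats[[ci]] <- m
    labs[[ci]] <- data.frame(
      spectrum_id = sprintf("c%d_%02d", ci, seq_len(n_per_class)),
      patient_id = sprintf("p%d_%d", ci, (seq_len(n_per_class) - 1L) %/% 5L),
      sample_id = sprintf("p%d_%d", ci, (seq_len(n_per_class) - 1L) %/% 5L),
      t_stage = cl$t, n_stage = cl$n, grade = cl$g,
      stringsAsFactors = FALSE)
  }
  raman_dataset(abs(do.call(rbind, mats)), wn, do.call(rbind, labs))
}

# narrow model configuration for fast unit tests (full ResNet-50 topology)
tiny_mtn_config <- function(input_length = 64L) {
  mtn_config(input_length = input_length, stem_channels = 4L,
             stage_channels = c(8L, 16L, 32L, 64L))
}

# single-peak class profile built by hand
single_peak_profile <- function(center = 1000, amplitude = 1, width = 5,
                                n = 1L, noise_sd = 0,
                                triplet = c(t_stage = "T1", n_stage = "N0",
                                            grade = "WD")) {
  structure(list(
    label_triplet = triplet,
    peaks = data.frame(center = center, amplitude = amplitude,
                       width = width, shape = "lorentzian",
                       assignment = "test band",
                       stringsAsFactors = FALSE),
    baseline_coeffs = c(0, 0, 0), noise_sd = noise_sd, n_spectra = n),
    class = "class_profile")
}
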