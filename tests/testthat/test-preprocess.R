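test_that("crop keeps the closed interval and rejects empty overlap", {
  s <- raman_spectrum(c(399, 400, 700, 1400, 1401), c(1, 2, 3, 4, 5))
  out <- crop_range(s, 400, 1400)
  expect_equal(out$wavenumbers, c(400, 700, 1400))
  expect_equal(out$intensities, c(2, 3, 4))
  one <- crop_range(s, 700, 700)
  expect_equal(one$wavenumbers, 700)
  expect_error(crop_range(s, 2000, 3000), "overlap")
})

test_that("Savitzky-Golay reproduces polynomials up to its order", {
  x <- seq(0, 10, length.out = 101)
  # constant input is returned unchanged
  cs <- raman_spectrum(x, rep(5, 101))
  expect_equal(savitzky_golay(cs, 11, 2)$intensities, rep(5, 101))
  # quadratic reproduced at machine precision; oracle = per-window OLS fit
  q <- 2 + 0.5 * x - 0.3 * x^2
  sm <- savitzky_golay(raman_spectrum(x, q), 11, 2)$intensities
  interior <- 6:96
  expect_equal(sm[interior], q[interior], tolerance = 1e-10)
  oracle <- vapply(interior, function(i) {
    w <- (i - 5):(i + 5)
    fit <- lm(y ~ poly(t, 2, raw = TRUE),
              data = data.frame(t = x[w], y = q[w]))
    unname(predict(fit, data.frame(t = x[i])))
  }, numeric(1L))
  expect_equal(sm[interior], oracle, tolerance = 1e-8)
  # every degree up to the fit order is preserved
  for (deg in 0:3) {
    p <- x^deg
    out <- savitzky_golay(raman_spectrum(x, p), 11, 3)$intensities
    expect_equal(out[interior], p[interior], tolerance = 1e-9)
  }
  expect_error(savitzky_golay(cs, 10, 2), "odd")
  expect_error(savitzky_golay(raman_spectrum(1:5, rnorm(5)), 11, 2),
               "shorter")
})

test_that("Savitzky-Golay attenuates white noise in the interior", {
  set.seed(42)
  n <- 2e4
  noise <- rnorm(n)
  sm <- sg_core(noise, 11, 2)
  interior <- 100:(n - 100)
  expect_lt(var(sm[interior]), var(noise[interior]))
})

test_that("iterative polynomial baseline removes backgrounds, keeps peaks", {
  x <- seq(400, 1400, length.out = 501)
  u <- (x - 900) / 500
  cubic <- 10 + 3 * u - 4 * u^2 + 2 * u^3
  out <- baseline_correct(raman_spectrum(x, cubic), degree = 3)$intensities
  expect_lt(max(abs(out)), 1e-6 * diff(range(cubic)))
  # cubic + tall narrow Gaussian: height kept within 5%, residual < 2%
  peak <- 5 * exp(-((x - 1000) / 10)^2)
  out2 <- baseline_correct(raman_spectrum(x, cubic + peak),
                           degree = 3)$intensities
  ipk <- which.min(abs(x - 1000))
  expect_lt(abs(out2[ipk] - 5) / 5, 0.05)
  off <- abs(x - 1000) > 80
  expect_lt(max(abs(out2[off])), 0.02 * 5)
  # all-zero input stays zero
  expect_equal(baseline_correct(raman_spectrum(x, numeric(501)),
                                degree = 5)$intensities, numeric(501))
  # baseline-only inputs vanish for every degree up to the configured one
  for (deg in 0:5) {
    poly_in <- rowSums(outer(u, 0:deg, `^`))
    res <- baseline_correct(raman_spectrum(x, poly_in),
                            degree = 5)$intensities
    expect_lt(max(abs(res)), 1e-6 * max(diff(range(poly_in)), 1))
  }
  expect_error(baseline_correct(raman_spectrum(1:3, 1:3), degree = 5),
               "too short")
})

test_that("min-max normalisation maps onto [0, 1] exactly", {
  s <- raman_spectrum(1:3, c(2, 4, 6))
  expect_equal(minmax_normalize(s)$intensities, c(0, 0.5, 1))
  # idempotent on an already-normalised trace
  expect_equal(minmax_normalize(minmax_normalize(s))$intensities,
               c(0, 0.5, 1))
  set.seed(3)
  v <- rnorm(50)
  r <- minmax_normalize(raman_spectrum(1:50, v))$intensities
  expect_identical(min(r), 0)
  expect_identical(max(r), 1)
  expect_equal(order(r), order(v))  # affine map preserves ordering
  expect_error(minmax_normalize(raman_spectrum(1:3, rep(1, 3))),
               "constant")
})

test_that("block averaging reduces counts by floor(n/k) and conserves means", {
  m <- matrix(rep(c(1, 2, 3), each = 10), nrow = 10)
  out <- average_reduce(m, 5L)
  expect_equal(dim(out), c(2L, 3L))
  expect_equal(unname(out[1, ]), c(1, 2, 3))
  m2 <- matrix(c(0, 2, 4), nrow = 3, ncol = 4)
  expect_equal(unname(average_reduce(m2, 3L)[1, ]), rep(2, 4))
  # published-scale count: 3510 raw spectra at k = 5 give 702 blocks
  big <- matrix(1, nrow = 3510, ncol = 2)
  expect_equal(nrow(average_reduce(big, 5L)), 702L)
  # grand-mean conservation over the used prefix
  set.seed(9)
  r <- matrix(rnorm(17 * 6), 17)
  red <- average_reduce(r, 5L)
  expect_equal(colMeans(red), colMeans(r[1:15, ]), tolerance = 1e-12)
  expect_length(attr(red, "averaging_log"), 3L)
  expect_error(average_reduce(r, 0L), ">= 1")
})

test_that("outlier screen drops spectra decorrelated from class median", {
  wn <- seq(400, 1400, length.out = 50)
  base <- sin(wn / 100) + 2
  m <- rbind(matrix(rep(base, 10), 10, byrow = TRUE), -base + 4)
  labs <- data.frame(spectrum_id = sprintf("s%02d", 1:11),
                     patient_id = "p", sample_id = "p",
                     t_stage = "T1", n_stage = "N0", grade = "WD")
  ds <- raman_dataset(m, wn, labs)
  out <- remove_outliers(ds, 0.5)
  expect_equal(n_spectra(out), 10L)
  expect_equal(attr(out, "removal_log")$spectrum_id, "s11")
  expect_lt(attr(out, "removal_log")$corr, -0.9)
  # vacuous threshold removes nothing
  expect_equal(n_spectra(remove_outliers(ds, -1)), 11L)
  # identical spectra all survive a strict threshold
  ds2 <- raman_dataset(matrix(rep(base, 5), 5, byrow = TRUE), wn,
                       labs[1:5, ])
  expect_equal(n_spectra(remove_outliers(ds2, 0.99)), 5L)
})

test_that("resampling is exact on lines and reports the expected grid", {
  wn <- seq(400, 1400, length.out = 51)
  ramp <- 2 * wn + 1
  out <- resample_spectrum(raman_spectrum(wn, ramp), 173L)
  expect_equal(out$intensities, 2 * out$wavenumbers + 1, tolerance = 1e-9)
  expect_equal(range(out$wavenumbers), c(400, 1400))
  # identity on the original uniform grid
  s <- raman_spectrum(wn, sin(wn / 50))
  expect_equal(resample_spectrum(s, 51L)$intensities, s$intensities,
               tolerance = 1e-12)
  # the network grid: 2076 points over 400-1400 step (1400-400)/2075
  g <- resample_spectrum(s, 2076L)$wavenumbers
  expect_equal(diff(g)[1], 1000 / 2075, tolerance = 1e-9)
  expect_error(resample_spectrum(s, 1L), ">= 2")
})

test_that("full pipeline meets stage postconditions and is deterministic", {
  scfg <- sim_config(seed = 11L, n_points = 301L, composition = data.frame(
    t_stage = c("health", "T1"), n_stage = c("health", "N0"),
    grade = c("health", "WD"), n = c(25L, 12L)))
  ds <- simulate_dataset(scfg)
  cfg <- preprocess_config(target_length = 128L,
                           averaging_k = c(health = 5, T1 = 3))
  out <- preprocess(ds, cfg)
  expect_equal(ncol(out$intensities), 128L)
  expect_equal(n_spectra(out), 5L + 4L)  # floor(25/5) + floor(12/3)
  expect_true(all(abs(apply(out$intensities, 1, min)) < 1e-12))
  expect_true(all(abs(apply(out$intensities, 1, max) - 1) < 1e-12))
  out2 <- preprocess(ds, cfg)
  expect_identical(out$intensities, out2$intensities)
  # averaging provenance recorded
  expect_named(attr(out, "averaging_log"),
               c("health|health|health", "T1|N0|WD"))
})

test_that("pipeline errors carry the stage name and small classes warn", {
  ds <- tiny_dataset(n_per_class = 4L, n_points = 40L)
  ds$intensities[1, ] <- 1  # constant spectrum
  cfg <- preprocess_config(sg_window = 5L, baseline_degree = 2L,
                           target_length = 32L, averaging_k = numeric(0))
  expect_error(preprocess(ds, cfg), "\\[minmax_normalize\\]")
  # a class smaller than its averaging factor is dropped with a warning
  ds2 <- tiny_dataset(n_per_class = 4L, n_points = 40L)
  cfg2 <- preprocess_config(sg_window = 5L, baseline_degree = 2L,
                            target_length = 32L,
                            averaging_k = c(T1 = 6))
  expect_warning(out <- preprocess(ds2, cfg2), "dropped")
  expect_true(all(out$labels$t_stage == "health"))
})

test_that("preprocess_config validates its fields", {
  expect_error(preprocess_config(sg_window = 4L), "odd")
  expect_error(preprocess_config(range_lo = 1500, range_hi = 400), "<")
  expect_error(preprocess_config(averaging_k = c(T1 = 0)), ">= 1")
  expect_error(preprocess_config(outlier_min_corr = 2), "\\[-1, 1\\]")
})
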