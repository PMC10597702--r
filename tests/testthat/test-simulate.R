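test_that("every published progression direction holds between class means", {
  cfg <- sim_config(composition = data.frame(
    t_stage = c("Tis", "T1", "T3", "T3", "T3", "T1", "T1"),
    n_stage = c("N0", "N0", "N0", "N1", "N2", "N0", "N0"),
    grade = c("WD", "WD", "WD", "WD", "WD", "MD", "PD"),
    n = 1L, stringsAsFactors = FALSE))
  pr <- build_default_profiles(cfg)
  wn <- seq(cfg$axis_lo, cfg$axis_hi, length.out = cfg$n_points)
  mean_at <- function(key, shift) {
    y <- profile_mean_spectrum(pr[[key]], cfg)
    y[which.min(abs(wn - shift))]
  }
  tr <- ramanmtn:::stage_transitions()
  pairs <- list(
    list(tr$t$TI, "T1|N0|WD", "Tis|N0|WD"),
    list(tr$t$TII, "T3|N0|WD", "T1|N0|WD"),
    list(tr$n$N1, "T3|N1|WD", "T3|N0|WD"),
    list(tr$n$N2, "T3|N2|WD", "T3|N1|WD"),
    list(tr$g$MD, "T1|N0|MD", "T1|N0|WD"),
    list(tr$g$PD, "T1|N0|PD", "T1|N0|MD"))
  for (p in pairs) {
    for (shift in p[[1]]$inc)
      expect_gt(mean_at(p[[2]], shift), mean_at(p[[3]], shift))
    for (shift in p[[1]]$dec)
      expect_lt(mean_at(p[[2]], shift), mean_at(p[[3]], shift))
  }
  # specific published relations
  expect_gt(mean_at("T3|N0|WD", 484), mean_at("T1|N0|WD", 484))
  expect_lt(mean_at("T3|N2|WD", 1151), mean_at("T3|N1|WD", 1151))
})

test_that("zero amplitude step collapses all tumor stages onto one profile", {
  cfg <- sim_config(amplitude_step = 0, composition = data.frame(
    t_stage = c("Tis", "T2", "T4"), n_stage = c("N0", "N0", "N2"),
    grade = c("WD", "MD", "PD"), n = 1L))
  pr <- build_default_profiles(cfg)
  expect_equal(pr[[1]]$peaks$amplitude, pr[[2]]$peaks$amplitude)
  expect_equal(pr[[2]]$peaks$amplitude, pr[[3]]$peaks$amplitude)
})

test_that("simulated Lorentzian bands obey the half-maximum geometry", {
  cfg <- sim_config(n_points = 1001L, within_class_jitter = 0,
                    noise_sd = 0, composition = data.frame(
                      t_stage = "T1", n_stage = "N0", grade = "WD", n = 1L))
  prof <- single_peak_profile(center = 1000, amplitude = 1, width = 5)
  s <- simulate_spectrum(prof, cfg, seed = 1L)
  at <- function(w) s$intensities[which.min(abs(s$wavenumbers - w))]
  expect_equal(at(1000), 1, tolerance = 1e-6)
  expect_equal(at(1005), 0.5, tolerance = 1e-3)
  expect_equal(at(995), 0.5, tolerance = 1e-3)
})

test_that("simulation is bit-reproducible and leaves the caller's RNG alone", {
  cfg <- sim_config(seed = 5L, n_points = 201L, composition = data.frame(
    t_stage = "T1", n_stage = "N0", grade = "WD", n = 3L))
  prof <- build_default_profiles(cfg)[[1L]]
  a <- simulate_spectrum(prof, cfg, seed = 77L)
  b <- simulate_spectrum(prof, cfg, seed = 77L)
  expect_identical(a$intensities, b$intensities)
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_spectrum(prof, cfg, seed = 9L))
  expect_identical(rnorm(1), before)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$intensities, d2$intensities)
})

test_that("the additive noise model has the configured scale", {
  cfg <- sim_config(n_points = 51L, within_class_jitter = 0,
                    noise_sd = 0.01, composition = data.frame(
                      t_stage = "T1", n_stage = "N0", grade = "WD", n = 1L))
  prof <- single_peak_profile(noise_sd = 0.01)
  draws <- vapply(1:1000, function(i)
    simulate_spectrum(prof, cfg, seed = i)$intensities[25L], numeric(1L))
  expect_lt(abs(sd(draws) / 0.01 - 1), 0.1)
})

test_that("default composition reproduces the published marginals", {
  comp <- default_composition()
  grade <- tapply(comp$n, comp$grade, sum)
  expect_equal(as.vector(grade[c("health", "BOD", "WD", "MD", "PD")]),
               c(3510L, 810L, 2790L, 540L, 300L))
  expect_equal(sum(comp$n), 7950L)
  cfg <- sim_config(n_points = 21L, composition = data.frame(
    t_stage = "T1", n_stage = "N0", grade = "WD", n = 90L))
  ds <- simulate_dataset(cfg)
  expect_equal(n_spectra(ds), 90L)
  expect_equal(length(unique(ds$labels$patient_id)), 1L)  # 90 per sample
  cfg2 <- sim_config(n_points = 21L, composition = data.frame(
    t_stage = "T1", n_stage = "N0", grade = "WD", n = 181L))
  expect_equal(length(unique(simulate_dataset(cfg2)$labels$patient_id)), 3L)
  empty <- sim_config(n_points = 21L, composition = data.frame(
    t_stage = character(), n_stage = character(), grade = character(),
    n = integer()))
  expect_equal(n_spectra(simulate_dataset(empty)), 0L)
})

test_that("class separation grows monotonically with the amplitude step", {
  sep <- vapply(c(0.1, 0.3, 0.5), function(step) {
    cfg <- sim_config(amplitude_step = step, n_points = 501L,
                      composition = data.frame(
                        t_stage = c("Tis", "T1", "T3"),
                        n_stage = c("N0", "N0", "N1"),
                        grade = c("WD", "WD", "MD"), n = 1L))
    pr <- build_default_profiles(cfg)
    M <- vapply(pr, profile_mean_spectrum, numeric(501L), cfg = cfg)
    mean(dist(t(M)))
  }, numeric(1L))
  expect_true(all(diff(sep) > 0))
})

test_that("two-class profiles differ at exactly the chosen band", {
  cfg <- sim_config(n_points = 201L, amplitude_step = 0,
                    composition = data.frame(
                      t_stage = c("T1", "T1"), n_stage = c("N0", "N0"),
                      grade = c("WD", "MD"), n = 5L))
  pr <- two_class_profiles(cfg, peak = 1080, amplitude_ratio = 2)
  d <- pr[[2]]$peaks$amplitude - pr[[1]]$peaks$amplitude
  expect_equal(sum(d != 0), 1L)
  expect_equal(pr[[1]]$peaks$center[d != 0], 1080)
  expect_error(two_class_profiles(cfg, peak = 777.7), "base-set")
})

test_that("published group counts sum to the printed totals", {
  expect_equal(sum(study_group_counts("t")$n), 2127L)
  expect_equal(sum(study_group_counts("n")$n), 2127L)
  expect_equal(sum(study_group_counts("grade")$n), 3534L)
  expect_equal(sum(study_group_counts("t", "raw")$n), 3510L)
  expect_equal(sum(study_group_counts("grade", "raw")$n), 7950L)
})
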