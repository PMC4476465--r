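test_that("hourly binning sums displacements into the right bins", {
  tr <- activity_trace_events(
    "a1", data.frame(time_s = c(0.5, 1800, 4000),
                     displacement_cm = c(1.0, 2.0, 0.5)), duration_h = 2)
  expect_equal(bin_hourly(tr), c(3.0, 0.5))
  empty <- activity_trace_events(
    "a2", data.frame(time_s = numeric(0), displacement_cm = numeric(0)),
    duration_h = 3)
  expect_equal(bin_hourly(empty), c(0, 0, 0))
  # 3600 events of 0.01 cm uniformly within hour 0: direct-summation oracle
  ev <- data.frame(time_s = seq(0, 3599.5, length.out = 3600),
                   displacement_cm = rep(0.01, 3600))
  tr3 <- activity_trace_events("a3", ev, duration_h = 3)
  expect_equal(bin_hourly(tr3), c(sum(ev$displacement_cm), 0, 0))
  expect_error(
    activity_trace_events("a4", data.frame(time_s = 7205,
                                           displacement_cm = 1),
                          duration_h = 2),
    "outside")
})

test_that("percent-of-max normalization is exact and scale-invariant", {
  n <- normalize_to_max(c(12, 48, 24))
  expect_equal(n$pct_of_max, c(25, 100, 50))
  expect_equal(normalize_to_max(5)$pct_of_max, 100)
  x <- stats::runif(48, 0, 10)
  expect_equal(normalize_to_max(x)$pct_of_max,
               normalize_to_max(7 * x)$pct_of_max)
  expect_error(normalize_to_max(rep(0, 24)), class = "degenerate_trace_error")
})

test_that("cohort aggregation computes means and standard errors", {
  co <- aggregate_cohort(list(c(0, 100), c(100, 0)))
  expect_equal(co$mean_pct, c(50, 50))
  expect_equal(co$se_pct, c(50, 50))
  single <- aggregate_cohort(list(c(10, 20, 30)))
  expect_equal(single$mean_pct, c(10, 20, 30))
  expect_equal(single$se_pct, c(0, 0, 0))
  expect_error(aggregate_cohort(list(1:3, 1:4)), "unequal")
})

test_that("normalized cohort means are independent of animal scale spread", {
  m1 <- cohort_mean_profile(activity_sim_spec(
    200, 72, "LD", animal_scale_range = c(0.5, 2), noise_sd = 0.5, seed = 9))
  m2 <- cohort_mean_profile(activity_sim_spec(
    200, 72, "LD", animal_scale_range = c(5, 5), noise_sd = 0.5, seed = 10))
  expect_gt(stats::cor(m1$mean_pct, m2$mean_pct), 0.99)
})

test_that("an LD cohort mean tracks a large-cohort simulation oracle", {
  oracle <- cohort_mean_profile(activity_sim_spec(3000, 72, "LD", seed = 77))
  coh <- cohort_mean_profile(activity_sim_spec(35, 72, "LD", seed = 78))
  z <- abs(coh$mean_pct - oracle$mean_pct) / coh$se_pct
  expect_true(all(z < 3))
})

test_that("the periodogram recovers pure tones and flags constant series", {
  t <- 0:71
  pg24 <- dft_periodogram(cos(2 * pi * t / 24))
  expect_equal(pg24$dominant_period_h, 24.00)
  pg12 <- dft_periodogram(cos(2 * pi * t / 12), seq(8, 32, by = 0.01))
  expect_equal(pg12$dominant_period_h, 12.00)
  expect_true(all(pg24$power >= 0))
  const <- dft_periodogram(rep(4, 48))
  expect_true(const$degenerate)
  expect_true(is.na(const$dominant_period_h))
  expect_true(all(const$power == 0))
})

test_that("noisy tones stay within half an hour of the true period", {
  ok <- vapply(1:20, function(i) {
    set.seed(500 + i)
    x <- cos(2 * pi * (0:71) / 24) + stats::rnorm(72, 0, 0.2)
    abs(dft_periodogram(x)$dominant_period_h - 24) <= 0.5
  }, logical(1))
  expect_true(all(ok))
})

test_that("natural-grid power matches the FFT and satisfies Parseval", {
  set.seed(61)
  x <- stats::rnorm(72)
  xc <- x - mean(x)
  pg <- dft_periodogram(x, 72 / (35:1))   # natural periods 72/k, k = 35..1
  Pfft <- Mod(stats::fft(xc))^2           # independent oracle
  expect_equal(pg$power, Pfft[36:2], tolerance = 1e-9)
  # Parseval: conjugate bins twice + Nyquist once = N * sum x_t^2
  expect_equal(2 * sum(pg$power) + Pfft[37], 72 * sum(xc^2),
               tolerance = 1e-9)
})

test_that("permutation rhythm test separates tones from noise", {
  x <- 10 * cos(2 * pi * (0:71) / 24)
  rt <- test_rhythmicity(x, n_permutations = 1000, seed = 1)
  expect_lte(rt$p_value, 0.002)
  expect_true(rt$significant)
  expect_equal(rt$dominant_period_h, 24)
  flat <- test_rhythmicity(rep(2, 72), n_permutations = 200, seed = 1)
  expect_equal(flat$p_value, 1)
  expect_false(flat$significant)
})

test_that("day/night summaries split totals by schedule state", {
  sched <- ld_schedule(24)
  tr <- structure(list(animal_id = "a", hourly_cm = rep(1, 24),
                       duration_h = 24, condition = "LD"),
                  class = "activity_trace")
  s <- day_night_summary(list(tr), sched)
  expect_equal(s$mean_dark_total_cm, 12)
  expect_equal(s$mean_light_total_cm, 12)
  expect_equal(s$se_dark, 0)
  dark_only <- structure(list(animal_id = "b",
                              hourly_cm = rep(c(0, 1), each = 12),
                              duration_h = 24, condition = "LD"),
                         class = "activity_trace")
  s2 <- day_night_summary(list(dark_only), sched)
  expect_equal(s2$mean_light_total_cm, 0)
  expect_equal(s2$mean_dark_total_cm, 12)
  expect_error(day_night_summary(list(tr), ld_schedule(12)), "cover")
})

test_that("daily peaks and phase shifts recover planted and shifted phases", {
  sched <- ld_schedule(72)
  prof <- rep(cos(2 * pi * ((0:23) - 16) / 24), 3)
  expect_equal(daily_peaks(prof, sched), c(16, 16, 16))
  shifted <- c(cos(2 * pi * ((0:23) - 16) / 24),
               cos(2 * pi * ((0:23) - 14) / 24))
  expect_equal(daily_peaks(shifted, ld_schedule(48)), c(16, 14))
  # stable profile composes to all-zero shifts
  expect_equal(phase_shift(daily_peaks(prof, sched), 16)$shift_h,
               rep(0, 3))
})

test_that("phase shifts are signed circular differences with advances positive", {
  ps <- phase_shift(c(14, 8, 10), baseline_zt = 16)
  expect_equal(ps$shift_h, c(2, 8, 6))
  expect_equal(phase_shift(c(23), baseline_zt = 2)$shift_h, 3)
  expect_equal(phase_shift(c(16, 16), 16)$shift_h, c(0, 0))
  expect_true(is.na(phase_shift(c(14, NA), 16)$shift_h[2]))
  expect_error(phase_shift(numeric(0), 16), "non-empty")
})

test_that("cohort daily peaks recover the planted nocturnal peak", {
  ok <- vapply(1:100, function(i) {
    prof <- cohort_mean_profile(activity_sim_spec(35, 72, "LD",
                                                  seed = 4000 + i))
    p <- daily_peaks(prof, ld_schedule(72))
    all(circ_dist_h(p, 18) <= 1)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("dark-pulse cohorts show a phase advance after the pulse", {
  spec <- activity_sim_spec(35, 96, "dark_pulse", pulse_window = c(33, 1),
                            pulse_shift_h = 2, noise_sd = 2, seed = 55)
  prof <- cohort_mean_profile(spec)
  peaks <- daily_peaks(prof, ld_schedule(96))
  ps <- phase_shift(peaks, baseline_zt = 18)
  expect_equal(ps$shift_h[1], 0)
  expect_true(all(ps$shift_h[3:4] >= 1))
})
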