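# Filtering, minimum-jerk template, segmentation.

test_that("zero-phase low-pass keeps DC and the passband, kills the stopband", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  expect_equal(lowpass_filter(rep(2.5, length(t)), fs), rep(2.5, length(t)),
               tolerance = 1e-10)
  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass_filter(s1, fs)
  mid <- t > 0.5 & t < 3.5
  expect_lt(max(abs(f1[mid] - s1[mid])), 0.01)
  s50 <- sin(2 * pi * 50 * t)
  f50 <- lowpass_filter(s50, fs)
  expect_lt(max(abs(f50[mid])), 10^(-40 / 20)) # > 40 dB attenuation
  # idempotence on an already band-limited signal
  f11 <- lowpass_filter(f1, fs)
  expect_lt(max(abs(f11[mid] - f1[mid])) / max(abs(f1)), 1e-3)
  expect_error(lowpass_filter(rep(1, 10), fs), "too short")
})

test_that("minimum-jerk template matches its closed-form landmarks", {
  expect_equal(minjerk_velocity(0.5, a = 1, t0 = 0, tf = 1), -1.875)
  expect_equal(minjerk_velocity(c(0, 1), a = 1, t0 = 0, tf = 1), c(0, 0))
  expect_equal(minjerk_velocity(c(-0.2, 1.4), a = 3, t0 = 0, tf = 1), c(0, 0))
  # midpoint value scales as -1.875 a / (tf - t0)
  expect_equal(minjerk_velocity(1.6, a = -2, t0 = 0.4, tf = 2.8),
               -1.875 * (-2) / 2.4)
  # integral over the movement is -a; peak/mean ratio exactly 1.875
  tg <- seq(0, 1, length.out = 20001)
  v <- minjerk_velocity(tg, a = 0.7, t0 = 0.1, tf = 0.9)
  expect_equal(trapz(tg, v), -0.7, tolerance = 1e-6)
  vin <- tg >= 0.1 & tg <= 0.9
  expect_equal(velocity_ratio(v[vin], tg[vin]), 1.875, tolerance = 1e-5)
  expect_error(minjerk_velocity(0.5, 1, t0 = 1, tf = 1), "t0")
})

test_that("velocity ratio gives the textbook values for canonical profiles", {
  t <- seq(0, 1, length.out = 2001)
  expect_equal(velocity_ratio(rep(3, 2001), t), 1)
  tri <- ifelse(t < 0.5, t, 1 - t)
  expect_equal(velocity_ratio(tri, t), 2, tolerance = 1e-3)
  expect_error(velocity_ratio(rep(0, 10)), "zero")
})

test_that("marker geometry gives angles via the arccosine of unit vectors", {
  sh <- c(0, 0, 0)
  expect_equal(angle_from_markers(sh, c(2, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_from_markers(sh, c(0, 3, 0), c(1, 0, 0)), pi / 2)
  expect_equal(angle_from_markers(sh, c(-1, 0, 0), c(1, 0, 0)), pi)
  expect_equal(angle_from_markers(sh, c(1, 1, 0), c(1, 0, 0)), pi / 4)
  expect_error(angle_from_markers(sh, sh, c(1, 0, 0)), "zero-length")
})

test_that("noiseless minimum-jerk trials are recovered almost exactly", {
  tr <- minjerk_trial(a = -0.5, t0 = 0.8, tf = 1.75)
  fm <- fit_movement(tr$time, tr$angle, filter = FALSE)
  expect_identical(fm$flag, "ok")
  expect_lt(abs(fm$params$t0 - 0.8), 1e-3)
  expect_lt(abs(fm$params$tf - 1.75), 1e-3)
  expect_lt(abs(fm$params$a - (-0.5)) / 0.5, 1e-3)
  expect_gt(fm$segment$fit_r2, 0.999)
  expect_equal(fm$segment$duration_s, 0.95, tolerance = 1e-3)
  expect_equal(fm$segment$amplitude_deg, 0.5 * 180 / pi, tolerance = 0.05)
})

test_that("duration estimates survive measurement noise (20 dB SNR)", {
  set.seed(101)
  errs <- replicate(20, {
    a <- -runif(1, 0.3, 1.2)
    t0 <- runif(1, 0.5, 1.0)
    d <- runif(1, 0.7, 1.3)
    tr <- minjerk_trial(a = a, t0 = t0, tf = t0 + d, t_end = 3)
    # additive angle noise scaled to ~20 dB on the velocity signal
    vrms <- sqrt(mean(minjerk_velocity(tr$time, a, t0, t0 + d)^2))
    ang <- tr$angle + rnorm(length(tr$angle), 0, vrms * 0.1 / 250 * 3)
    fm <- fit_movement(tr$time, ang)
    abs(fm$segment$duration_s - d) / d
  })
  expect_lt(mean(errs), 0.05)
})

test_that("flat trials are flagged as containing no movement", {
  tr <- minjerk_trial()
  fm <- fit_movement(tr$time, rep(0.2, length(tr$time)) +
                       rnorm(length(tr$time), 0, 1e-5))
  expect_identical(fm$flag, "no_movement")
  expect_true(is.na(fm$segment$duration_s))
})

test_that("segmentation is symmetric in movement direction", {
  tr <- minjerk_trial(a = -0.6, t0 = 0.7, tf = 1.6)
  fmr <- fit_movement(tr$time, tr$angle, filter = FALSE)
  fml <- fit_movement(tr$time, -tr$angle, filter = FALSE)
  expect_equal(fmr$segment$duration_s, fml$segment$duration_s,
               tolerance = 1e-9)
  expect_equal(fmr$segment$amplitude_deg, fml$segment$amplitude_deg,
               tolerance = 1e-9)
})

test_that("optimal-control trajectories are well fitted by the template", {
  # trajectories from the torque+jerk cost are near-minimum-jerk; the
  # template fit should stay excellent
  arm <- arm_cohort_mean()
  sol <- solve_fixed_time(lq_problem(arm, 0.9, 1.0), n_grid = 251)
  tg <- seq(0, 2, by = 1 / 250)
  ang <- stats::approx(sol$time + 0.4, sol$angle, xout = tg, yleft = 0,
                       yright = 0.9)$y
  fm <- fit_movement(tg, ang, filter = FALSE)
  expect_gt(fm$segment$fit_r2, 0.95)
  expect_equal(fm$segment$duration_s, 1.0, tolerance = 0.08)
})
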