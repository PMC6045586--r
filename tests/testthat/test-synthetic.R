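# Synthetic cohort generator: determinism, configured distributions,
# session structure, file round trips.

test_that("identical config and seed reproduce identical cohorts and trials", {
  cfg <- tiny_config(seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  t1 <- simulate_session(c1[1, ], 1, cfg)
  t2 <- simulate_session(c1[1, ], 1, cfg)
  expect_identical(t1, t2)
  # a different seed changes the draws
  c3 <- generate_cohort(tiny_config(seed = 43))
  expect_false(isTRUE(all.equal(c1$body_mass_kg, c3$body_mass_kg)))
})

test_that("trait and anthropometry distributions match their configuration", {
  cfg <- cohort_config(n_participants = 3000, seed = 1)
  coh <- generate_cohort(cfg, identify_cot = FALSE)
  expect_lt(abs(cor(coh$boredom, coh$impulsivity) - 0.55), 0.05)
  expect_lt(abs(mean(coh$body_mass_kg) - 68.7), 0.7)
  expect_lt(abs(mean(coh$arm_length_m) - 0.721), 0.005)
  expect_true(all(coh$boredom >= 0 & coh$boredom <= 28))
  # behaviour targets live in the intended regime
  expect_lt(abs(median(coh$target_slope) - 0.0075), 0.0005)
  expect_lt(abs(mean(coh$target_intercept) - 0.63), 0.03)
  expect_gt(cor(log(coh$target_slope), coh$target_intercept), 0.6)
})

test_that("ground-truth cost-of-time parameters are identifiable and structured", {
  cfg <- cohort_config(n_participants = 25, seed = 9)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$alpha > 0 & coh$beta > 0.5 & coh$delta > 0.05))
  expect_gt(min(coh$cot_fit_r2), 0.7)
  # emergent co-variation: vigorous participants have larger alpha and beta,
  # smaller delta
  expect_gt(cor(log(coh$alpha), -log(coh$target_slope)), 0.5)
  expect_lt(cor(coh$delta, log(coh$alpha)), -0.5)
})

test_that("each block presents every amplitude twice with paired directions", {
  cfg <- tiny_config(seed = 3)
  coh <- generate_cohort(cfg)
  tr <- simulate_session(coh[2, ], 1, cfg)
  for (b in unique(tr$block_id)) {
    blk <- tr[tr$block_id == b, ]
    per_trial <- unique(blk[, c("trial_index", "stimulus_amplitude_deg",
                                "direction")])
    expect_equal(nrow(per_trial), 20)
    tab <- table(per_trial$stimulus_amplitude_deg, per_trial$direction)
    expect_true(all(tab == 1))
    expect_equal(sort(unique(per_trial$stimulus_amplitude_deg)),
                 seq(5, 95, 10))
  }
})

test_that("simulated durations increase with amplitude for every participant", {
  cfg <- cohort_config(n_participants = 5, seed = 21)
  coh <- generate_cohort(cfg)
  for (i in seq_len(nrow(coh))) {
    d <- participant_durations(coh[i, ], cfg)
    expect_false(any(attr(d, "boundary")))
    expect_true(all(diff(d) > 0))
    expect_true(all(d > 0.3 & d < 2.5))
  }
})

test_that("a zero-noise pipeline returns the model's own durations", {
  # with the pure-jerk effort the simulated trajectory is exactly the
  # template the segmentation fits, so estimated durations must match the
  # free-time model almost perfectly
  cfg <- cohort_config(n_participants = 1, sessions_per_participant = 1,
                       blocks_per_session = 1, seed = 5,
                       effort_mode = "jerk_only",
                       session_noise_sd = 0, block_noise_sd = 0,
                       trial_noise_sd = 0, angle_noise_sd = 0,
                       reaction_sd = 0)
  coh <- generate_cohort(cfg)
  nd <- participant_durations(coh[1, ], cfg)
  tr <- simulate_session(coh[1, ], 1, cfg, nominal_durations = nd)
  seg <- segment_trials(tr, filter = FALSE)
  err <- abs(seg$duration_s - nd[as.character(seg$stimulus_amplitude_deg)])
  expect_lt(max(err), 0.002)
})

test_that("trials tables survive a CSV round trip and reject bad schemas", {
  cfg <- tiny_config(seed = 2)
  coh <- generate_cohort(cfg)
  tr <- simulate_session(coh[3, ], 1, cfg)
  tr <- tr[tr$trial_index <= 2, ]
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$angle_rad, tr$angle_rad, tolerance = 1e-8)
  expect_equal(back$t_s, tr$t_s, tolerance = 1e-8)
  expect_identical(back$direction, tr$direction)
  # header-only file round trips too
  write_trials(tr[0, ], path)
  expect_equal(nrow(read_trials(path)), 0)
  # missing column is a schema error
  bad <- tr[, setdiff(names(tr), "angle_rad")]
  expect_error(write_trials(bad, path), "missing columns")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_trials(path), "missing columns")
  # non-numeric junk is reported with its line
  tr2 <- tr[1:5, ]
  tr2$t_s <- as.character(tr2$t_s)
  tr2$t_s[3] <- "oops"
  utils::write.csv(tr2, path, row.names = FALSE, quote = FALSE)
  expect_error(read_trials(path), "line 3")
})

test_that("the noise calibrator maps the vigour split to level noise", {
  cfg <- cohort_config(n_participants = 12, seed = 4)
  cal <- calibrate_duration_noise(cfg)
  expect_gt(cal$log_vigour_sd, 0.1)
  expect_equal(cal$session_noise_sd / cal$log_vigour_sd, sqrt(11 / 72),
               tolerance = 1e-10)
  expect_equal(cal$block_noise_sd / cal$log_vigour_sd, sqrt(17 / 72),
               tolerance = 1e-10)
})
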