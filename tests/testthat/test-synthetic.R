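test_that("profile validation names the offending field", {
  expect_error(gait_profile(step_frequency_hz = -1), "step_frequency_hz")
  expect_error(gait_profile(stride_time_cv = 1.2), "stride_time_cv")
  expect_error(gait_profile(com_excursion_m = 2, leg_length_m = 1),
               "com_excursion_m")
  expect_error(gait_profile(harmonic_noise_sd = NaN), "harmonic_noise_sd")
  expect_error(gait_profile(asymmetry = 1), "asymmetry")
})

test_that("zero stride-time CV gives exactly equal intervals", {
  p <- healthy_profile(stride_time_cv = 0, harmonic_noise_sd = 0,
                       step_frequency_hz = 2)
  sim <- simulate_gait_acceleration(p, 30, seed = 1)
  expect_equal(unique(round(diff(sim$truth$step_times), 12)), 0.5)
  expect_equal(unique(round(sim$truth$stride_intervals, 12)), 1)
})

test_that("inverted-pendulum closed form", {
  expect_equal(pendulum_step_length(0.05, 1.0), 2 * sqrt(2 * 1 * 0.05 - 0.05^2))
  expect_equal(round(pendulum_step_length(0.05, 1.0), 4), 0.6245)
  expect_equal(pendulum_step_length(0, 1.0), 0)
  ## simulated ground truth uses the same closed form
  p <- gait_profile(com_excursion_m = 0.05, leg_length_m = 1.0, asymmetry = 0)
  sim <- simulate_gait_acceleration(p, 10, seed = 2)
  expect_equal(unique(round(sim$truth$step_lengths_m, 10)),
               round(2 * sqrt(2 * 1 * 0.05 - 0.05^2), 10))
})

test_that("ground-truth stride CV converges to the target (>= 500 strides)", {
  p <- healthy_profile(stride_time_cv = 0.1)
  sim <- simulate_gait_acceleration(p, 540, seed = 3)
  iv <- sim$truth$stride_intervals
  expect_gte(length(iv), 500)
  cv_hat <- sd(iv) / mean(iv)
  expect_lt(abs(cv_hat - 0.1) / 0.1, 0.10)
})

test_that("double integration of the noiseless x-channel recovers h within 2%", {
  p <- healthy_profile(asymmetry = 0, harmonic_noise_sd = 0)
  sim <- simulate_gait_acceleration(p, 60, seed = 4)
  rec <- as_recording_from_simulation(sim)
  sl <- stride_length(rec, sim$truth$step_times, p$leg_length_m)
  expect_gt(sl$n_used, 50)
  expect_lt(abs(mean(sl$per_step$h_m) - p$com_excursion_m) /
              p$com_excursion_m, 0.02)
})

test_that("higher stride-time CV raises sample entropy (cv-only contrast)", {
  se_of <- function(cv, seed) {
    p <- healthy_profile(stride_time_cv = cv)
    sim <- simulate_gait_acceleration(p, 90, seed = seed)
    as.numeric(sample_entropy(sim$sensors$belt[, "x"]))
  }
  healthy <- vapply(1:3, function(s) se_of(0.02, s), 0)
  pd_like <- vapply(1:3, function(s) se_of(0.10, s), 0)
  expect_gt(mean(pd_like), mean(healthy))
})

test_that("schedules validate and label sessions correctly", {
  expect_error(activity_schedule(c(0, 50), c(60, 120),
                                 c("walking", "resting")), "contiguous")
  expect_error(activity_schedule(0, 60, "sleeping"), "labels")
  sched <- activity_schedule(c(0, 60), c(60, 120), c("walking", "resting"))
  sess <- simulate_session(sched, seed = 5)
  r <- rle(sess$labels)
  expect_equal(r$values, c("walking", "resting"))
  expect_equal(length(sess$truth$walking), 1L)
  expect_equal(sess$truth$walking[[1]]$interval, c(0, 60))
  ## walking step times stay inside the walking interval
  expect_true(all(sess$truth$walking[[1]]$step_times < 60))
})

test_that("resting sessions stay below the walking detector's threshold", {
  sess <- simulate_session(activity_schedule(0, 60, "resting"), seed = 6)
  rec <- as_recording_from_simulation(sess)
  feat <- window_features(rec)
  walk <- simulate_session(activity_schedule(0, 60, "walking"), seed = 6)
  featw <- window_features(as_recording_from_simulation(walk))
  ## separable by variance alone: every resting window is below every
  ## walking window
  expect_lt(max(feat$log_var), min(featw$log_var))
  expect_true(all(!classify_walking(feat)$walking))
})

test_that("loss model: identity case and reconnect minimum", {
  sim <- simulate_gait_acceleration(healthy_profile(), 20, seed = 7)
  none <- loss_model(disconnect_rate_per_s = 0, burst_extra_samples_mean = 0,
                     startup_burst_ms = 0, seed = 1)
  out <- apply_loss_model(sim, none)
  expect_equal(sum(lengths(out$dropped)), 0)
  expect_equal(out$streams$belt$acc_g[, 1], sim$sensors$belt[, 1],
               ignore_attr = TRUE)
  expect_equal(length(out$streams$belt$timestamp_ms), length(sim$t))
  ## zero geometric extension: every burst is exactly 64 ms
  zero_ext <- loss_model(disconnect_rate_per_s = 0.2,
                         burst_extra_samples_mean = 0, startup_burst_ms = 0,
                         seed = 2)
  out2 <- apply_loss_model(sim, zero_ext)
  for (s in names(out2$streams)) {
    gaps <- detect_gaps(out2$streams[[s]])
    if (nrow(gaps)) expect_true(all(gaps$duration_ms %% 64 == 0))
    solo <- gaps$duration_ms[gaps$duration_ms == 64]
    expect_gte(length(solo), 0)
  }
  ## bursts never remove fewer than 4 consecutive samples
  one_ev <- apply_loss_model(sim, loss_model(0.05, 0, 0, seed = 3))
  for (s in names(one_ev$dropped)) {
    d <- one_ev$dropped[[s]]
    if (length(d)) {
      runs <- rle(diff(d) == 1L)
      expect_true(all(tapply(d, cumsum(c(1L, diff(d) != 1L)), length) >= 4))
    }
  }
})

test_that("loss model is measure-consistent and reproducible", {
  sim <- simulate_gait_acceleration(healthy_profile(), 30, seed = 8)
  for (seed in 1:3) {
    lm <- loss_model(disconnect_rate_per_s = 0.3, burst_extra_samples_mean = 3,
                     startup_burst_ms = 1000, seed = seed)
    out <- apply_loss_model(sim, lm)
    for (s in names(out$streams))
      expect_equal(length(out$streams[[s]]$timestamp_ms) +
                     length(out$dropped[[s]]), out$expected_n)
  }
  a <- apply_loss_model(sim, loss_model(seed = 42))
  b <- apply_loss_model(sim, loss_model(seed = 42))
  expect_identical(a, b)
})

test_that("same seed gives bit-identical simulations", {
  p <- pd_profile()
  expect_identical(simulate_gait_acceleration(p, 15, seed = 9),
                   simulate_gait_acceleration(p, 15, seed = 9))
  sched <- random_schedule(5, seed = 10)
  expect_identical(simulate_session(sched, p, seed = 11),
                   simulate_session(sched, p, seed = 11))
})

test_that("calibrated loss model hits its target percentage in expectation", {
  sim <- simulate_gait_acceleration(healthy_profile(), 600, seed = 12)
  lm <- loss_model_for_percent(2.0, seed = 13)
  out <- apply_loss_model(sim, lm)
  realized <- 100 * length(out$dropped$belt) / out$expected_n
  expect_lt(abs(realized - 2.0), 1.0)   # Poisson scatter around the target
})
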