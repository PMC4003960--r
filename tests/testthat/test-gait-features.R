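test_that("sample entropy: degenerate, alternating and ordering cases", {
  const <- sample_entropy(rep(3, 50))
  expect_equal(as.numeric(const), 0)
  expect_true(attr(const, "degenerate"))
  ## 10-point alternating series equals the exhaustive oracle exactly
  x <- rep(c(1, 2), 5)
  expect_identical(as.numeric(sample_entropy(x, m = 2, r = 0.2)),
                   sampen_oracle(x, m = 2, r = 0.2))
  ## white noise is less regular than a same-variance periodic series
  withr::with_seed(4, noise <- rnorm(300))
  per <- sin(2 * pi * (1:300) / 25) * sd(noise) * sqrt(2)
  expect_gt(sample_entropy(noise), sample_entropy(per))
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "length")
  expect_error(sample_entropy(c(1, NA, 3, 4, 5)), "non-finite")
})

test_that("sample entropy equals the brute-force oracle on random series", {
  withr::with_seed(5, {
    for (case in 1:30) {
      n <- sample(20:150, 1)
      x <- switch(case %% 3 + 1,
                  rnorm(n),
                  as.numeric(arima.sim(list(ar = 0.8), n)),
                  sin(2 * pi * (1:n) / 17) + rnorm(n, 0, 0.3))
      m <- sample(1:3, 1)
      expect_identical(as.numeric(sample_entropy(x, m = m, r = 0.25)),
                       sampen_oracle(x, m = m, r = 0.25))
    }
  })
})

test_that("sample entropy is invariant to affine rescaling (relative r)", {
  withr::with_seed(6, x <- rnorm(150))
  expect_equal(as.numeric(sample_entropy(3.7 * x - 11)),
               as.numeric(sample_entropy(x)))
})

test_that("step detection on clean 2 Hz gait: intervals within one sample", {
  p <- healthy_profile(step_frequency_hz = 2, stride_time_cv = 0,
                       asymmetry = 0, harmonic_noise_sd = 0)
  sim <- simulate_gait_acceleration(p, 30, seed = 7)
  rec <- as_recording_from_simulation(sim)
  st <- detect_steps(rec)
  expect_false(inherits(st, "skipped"))
  iv <- diff(st)
  expect_true(all(abs(iv - 0.5) <= 1 / 62.5))
  expect_lt(abs(step_frequency(st) - 2) / 2, 0.005)
})

test_that("non-rhythmic signals are skipped with a reason", {
  sess <- simulate_session(activity_schedule(0, 30, "resting"), seed = 8)
  rec <- as_recording_from_simulation(sess)
  st <- detect_steps(rec)
  expect_s3_class(st, "skipped")
  expect_match(st$reason, "rhythm|peaks|frequency")
  gf <- gait_features(rec, NULL, leg_length_m = 0.95)
  expect_false(is.na(gf$skipped_reason))
  expect_true(is.na(gf$sample_entropy))
})

test_that("step frequency and stride CV: exact and flagged cases", {
  st <- seq(0, 5, by = 0.5)
  expect_equal(step_frequency(st), 2)
  expect_equal(stride_time_cv(st), 0)
  two <- c(0, 0.5)
  expect_true(is.na(step_frequency(two)))
  expect_match(attr(step_frequency(two), "reason"), "fewer than 4")
  expect_true(is.na(stride_time_cv(two)))
})

test_that("stride CV is recovered within 15% at >= 200 strides", {
  p <- healthy_profile(stride_time_cv = 0.10)
  sim <- simulate_gait_acceleration(p, 220, seed = 9)
  rec <- as_recording_from_simulation(sim)
  st <- detect_steps(rec)
  expect_gte(length(st), 400)       # >= 200 strides
  cv <- stride_time_cv(st)
  expect_lt(abs(cv - 0.10) / 0.10, 0.15)
})

test_that("stride length: boundary, closed form and end-to-end recovery", {
  expect_equal(pendulum_step_length(0, 1), 0)
  expect_equal(round(pendulum_step_length(0.05, 1), 4), 0.6245)
  p <- healthy_profile(asymmetry = 0, harmonic_noise_sd = 0)
  sim <- simulate_gait_acceleration(p, 60, seed = 10)
  rec <- as_recording_from_simulation(sim)
  st <- detect_steps(rec)
  sl <- stride_length(rec, st, p$leg_length_m)
  truth <- mean(sim$truth$step_lengths_m)
  expect_lt(abs(sl$mean_length_m - truth) / truth, 0.05)
  expect_equal(sl$n_dropped, 0)
})

test_that("velocity is the product and the consistency flag holds", {
  expect_equal(gait_velocity(2, 0.6), 1.2)
  expect_equal(gait_velocity(0, 0.7), 0)
  expect_true(is.na(gait_velocity(NA, 1)))
  sim <- simulate_gait_acceleration(healthy_profile(), 40, seed = 11)
  gf <- gait_features(as_recording_from_simulation(sim), NULL, 0.95)
  expect_true(gf$velocity_consistent)
  expect_equal(gf$velocity_m_s, gf$step_frequency_hz * gf$stride_length_m)
})

test_that("entropy rises with stride variability and with noise", {
  se_of <- function(cv, noise, seed) {
    p <- healthy_profile(stride_time_cv = cv, harmonic_noise_sd = noise)
    sim <- simulate_gait_acceleration(p, 60, seed = seed)
    as.numeric(sample_entropy(sim$sensors$belt[, "x"]))
  }
  cv_grid <- c(0, 0.04, 0.08, 0.12, 0.16)
  se_cv <- vapply(cv_grid, function(cv)
    mean(vapply(1:2, function(s) se_of(cv, 0.02, s), 0)), 0)
  expect_gt(cor(cv_grid, se_cv, method = "spearman"), 0)
  noise_grid <- c(0.01, 0.03, 0.05, 0.08, 0.12)
  se_nz <- vapply(noise_grid, function(nz)
    mean(vapply(1:2, function(s) se_of(0.05, nz, s), 0)), 0)
  expect_gt(cor(noise_grid, se_nz, method = "spearman"), 0)
})
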