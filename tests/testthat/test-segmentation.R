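make_recording <- function(chan_fun, duration_s = 30, fs = 62.5,
                           sensors = c("left_leg", "right_leg")) {
  n <- as.integer(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  mats <- lapply(sensors, function(s)
    cbind(x = chan_fun(t, s), y = numeric(n), z = numeric(n)))
  names(mats) <- sensors
  structure(list(fs = fs, t0_s = 0, n = n, t = t, sensors = mats,
                 observed = lapply(mats, function(m) rep(TRUE, n)),
                 filled = lapply(mats, function(m) rep(FALSE, n)),
                 normalized = FALSE),
            class = "recording")
}

test_that("window features: degenerate and pure-tone windows", {
  const <- make_recording(function(t, s) rep(1, length(t)))
  f <- window_features(const)
  expect_true(all(f$log_var == log10(1e-7)))   # variance 0
  expect_true(all(f$band_ratio == 0))
  expect_true(all(f$dom_freq_hz == 0))
  ## leg-like signal: gravity baseline plus a 2 Hz oscillation, so the
  ## magnitude stays linear in the tone instead of rectifying it
  tone <- make_recording(function(t, s) 1 + 0.5 * sin(2 * pi * 2 * t))
  ft <- window_features(tone)
  expect_true(all(abs(ft$dom_freq_hz - 2) < 0.1))
  expect_true(all(ft$band_ratio > 0.95))
  ## recording shorter than a window is flagged, not an error
  tiny <- make_recording(function(t, s) t, duration_s = 1)
  expect_true(isTRUE(attr(window_features(tiny), "too_short")))
})

test_that("walking and resting windows are separable by variance", {
  sess <- simulate_session(
    activity_schedule(c(0, 60), c(60, 120), c("walking", "resting")),
    seed = 31)
  rec <- as_recording_from_simulation(sess)
  feat <- window_features(rec)
  lab <- label_windows(sess, feat)
  ok <- !is.na(lab$walking)
  thr <- mean(c(max(feat$log_var[ok & !lab$walking]),
                min(feat$log_var[ok & lab$walking])))
  expect_true(all((feat$log_var[ok] > thr) == lab$walking[ok]))
})

test_that("classifier: trivial inputs, unknowns and symmetry", {
  zero <- data.frame(log_var = log10(1e-7), dom_freq_hz = 0,
                     band_ratio = 0, pair_corr = 0)
  expect_false(classify_walking(zero)$walking)
  nonf <- data.frame(log_var = NA_real_, dom_freq_hz = 1, band_ratio = 1,
                     pair_corr = 1)
  expect_true(is.na(classify_walking(nonf)$walking))
  ## left-right flip leaves window features (hence classification) unchanged
  sess <- simulate_session(activity_schedule(0, 40, "walking"), seed = 32)
  rec <- as_recording_from_simulation(sess)
  f1 <- window_features(rec, sensors = c("left_leg", "right_leg"))
  f2 <- window_features(rec, sensors = c("right_leg", "left_leg"))
  expect_equal(classify_walking(f1)$walking, classify_walking(f2)$walking)
})

test_that("the shipped model reproduces a fresh fit on the seeded fixture", {
  tw <- walking_training_windows()
  refit <- fit_walking_classifier(tw, tw$walking)
  shipped <- default_walking_model()
  expect_equal(refit$coef, shipped$coef, tolerance = 1e-6)
  expect_equal(refit$center, shipped$center, tolerance = 1e-6)
  expect_equal(refit$scale, shipped$scale, tolerance = 1e-6)
  ## and fits its own training set essentially perfectly
  cls <- classify_walking(tw, refit)
  expect_gt(mean(cls$walking == tw$walking), 0.99)
})

test_that("merge_windows applies run, gap and duration rules", {
  mk <- function(lab) {
    n <- length(lab)
    data.frame(start_s = (0:(n - 1)) * 1.28, end_s = (0:(n - 1)) * 1.28 + 2.56)
  }
  none <- merge_windows(mk(rep(FALSE, 10)), rep(FALSE, 10))
  expect_equal(nrow(none), 0)
  one <- merge_windows(mk(rep(TRUE, 10)), rep(TRUE, 10))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_windows, 10)
  ## +,-,+ with max_gap_windows = 1 merges into a single segment
  pat <- c(rep(TRUE, 5), FALSE, rep(TRUE, 5))
  merged <- merge_windows(mk(pat), pat, min_duration_s = 5,
                          max_gap_windows = 1)
  expect_equal(nrow(merged), 1)
  split <- merge_windows(mk(pat), pat, min_duration_s = 5,
                         max_gap_windows = 0)
  expect_equal(nrow(split), 2)
  ## segments below min duration are dropped
  short <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(nrow(merge_windows(mk(short), short, min_duration_s = 10)), 0)
})

test_that("two leg sensors meet the same accuracy bound as all five", {
  all5 <- c("belt", "left_wrist", "right_wrist", "left_leg", "right_leg")
  tw5 <- walking_training_windows(sensors = all5)
  m5 <- fit_walking_classifier(tw5, tw5$walking)
  profs <- list(healthy_profile(), pd_profile(),
                healthy_profile(step_frequency_hz = 1.6,
                                com_excursion_m = 0.04))
  acc <- function(sensors, model) {
    correct <- 0; total <- 0
    for (i in 1:3) {
      sched <- random_schedule(40, seed = 800 + i)
      sess <- simulate_session(sched, profs[[i]], seed = 900 + i)
      rec <- as_recording_from_simulation(sess)
      feat <- window_features(rec, sensors = sensors)
      lab <- label_windows(sess, feat)
      cls <- classify_walking(feat, model)
      ok <- !is.na(lab$walking) & !is.na(cls$walking)
      correct <- correct + sum(cls$walking[ok] == lab$walking[ok])
      total <- total + sum(ok)
    }
    100 * correct / total
  }
  expect_gte(acc(c("left_leg", "right_leg"), default_walking_model()), 99)
  expect_gte(acc(all5, m5), 99)
})

test_that("segment boundaries land within one window of the truth", {
  sched <- activity_schedule(c(0, 60, 120), c(60, 120, 180),
                             c("walking", "resting", "walking"))
  sess <- simulate_session(sched, seed = 33)
  rec <- as_recording_from_simulation(sess)
  segs <- segment_walking(rec)
  expect_equal(nrow(segs), 2)
  w <- 2.56
  expect_lt(abs(segs$start_s[1] - 0), w)
  expect_lt(abs(segs$end_s[1] - 60), w)
  expect_lt(abs(segs$start_s[2] - 120), w)
  expect_lt(abs(segs$end_s[2] - 180), w)
})
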