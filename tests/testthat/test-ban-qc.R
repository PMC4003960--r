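test_that("detect_gaps matches the timestamp arithmetic", {
  s1 <- packet_stream("belt", c(0, 16, 32, 48), matrix(0, 4, 3))
  expect_equal(nrow(detect_gaps(s1)), 0)
  s2 <- packet_stream("belt", c(0, 16, 32, 48, 128, 144), matrix(0, 6, 3))
  g2 <- detect_gaps(s2)
  expect_equal(g2$missing_samples, 4L)
  expect_equal(g2$duration_ms, 64)
  expect_equal(g2$start_ms, 64)
  s3 <- packet_stream("belt", c(0, 1600), matrix(0, 2, 3))
  g3 <- detect_gaps(s3)
  expect_equal(g3$missing_samples, 99L)
  expect_equal(g3$duration_ms, 1584)
})

test_that("detect_gaps includes leading and trailing loss for conservation", {
  ## first two and last three grid samples missing out of 20
  s <- stream_from_indices(3:17, 20)
  g <- detect_gaps(s)
  expect_equal(sum(g$missing_samples), 5L)
  expect_equal(length(s$timestamp_ms) + sum(g$missing_samples), 20L)
})

test_that("detect_gaps is invariant to packet order", {
  keep <- sort(sample(1:200, 150))
  s <- stream_from_indices(keep, 200)
  perm <- sample(seq_along(keep))
  s2 <- packet_stream("belt", s$timestamp_ms[perm],
                      s$acc_g[perm, , drop = FALSE],
                      expected_span_ms = s$expected_span_ms)
  expect_identical(detect_gaps(s), detect_gaps(s2))
})

test_that("loss percentage: clean stream, constructed 0.95% case, oracle", {
  clean <- stream_from_indices(1:7500, 7500)      # 120 s
  lp <- loss_percentage(clean)
  expect_equal(lp$mean_percent, 0)
  expect_equal(lp$sd_percent, 0)
  ## 10,000 expected samples, 95 missing, single 160 s window -> 0.95%
  withr::with_seed(1, drop_idx <- sample(2:9999, 95))
  s <- stream_from_indices(setdiff(1:10000, drop_idx), 10000)
  lp2 <- loss_percentage(s, window_s = 160)
  expect_equal(lp2$mean_percent, 0.95)
  expect_true(lp2$sd_undefined)
  expect_true(is.na(lp2$sd_percent))
  ## independent counting oracle: brute-force recount equals burst sum
  expect_equal(sum(detect_gaps(s)$missing_samples),
               10000L - length(s$timestamp_ms))
  expect_equal(lp2$missing_total, 95L)
})

test_that("burst statistics: mean, population sd, smallest-tie mode", {
  bs <- burst_statistics(c(64, 64, 64, 192))
  expect_equal(bs$mean_ms, 96)
  expect_equal(bs$modal_ms, 64)
  expect_equal(bs$sd_ms, sqrt(mean((c(64, 64, 64, 192) - 96)^2)))
  one <- burst_statistics(64)
  expect_equal(one$mean_ms, 64)
  expect_equal(one$sd_ms, 0)
  expect_equal(one$modal_ms, 64)
  ## tie -> smallest duration wins
  expect_equal(burst_statistics(c(80, 80, 64, 64))$modal_ms, 64)
  empty <- burst_statistics(numeric(0))
  expect_true(empty$empty)
  expect_equal(empty$n, 0L)
})

test_that("trim_startup removes the startup burst and re-bases time", {
  ## no gaps: nothing trimmed
  clean <- stream_from_indices(1:1250, 1250)
  tr <- trim_startup(clean)
  expect_true(tr$qc_pass)
  expect_equal(tr$startup_trimmed_ms, 0)
  expect_identical(tr$stream$timestamp_ms, clean$timestamp_ms)
  ## long burst before t = 5 s, stable afterwards
  keep <- c(1:60, 340:3000)      # ~4.5 s hole ending at sample 340
  s <- stream_from_indices(keep, 3000)
  tr2 <- trim_startup(s, stable_s = 10)
  expect_true(tr2$qc_pass)
  expect_equal(tr2$startup_trimmed_ms, 16 * 339)
  expect_equal(nrow(detect_gaps(tr2$stream)), 0)
  ## all-gap stream fails QC
  empty <- packet_stream("belt", numeric(0),
                         matrix(0, 0, 3), expected_span_ms = 16 * 999)
  tr3 <- trim_startup(empty)
  expect_false(tr3$qc_pass)
  expect_match(tr3$reason, "no gap-free window")
})

test_that("after trimming a default-loss stream: modal burst 64 ms, loss drops", {
  sim <- simulate_gait_acceleration(healthy_profile(), 300, seed = 21)
  lm <- loss_model(disconnect_rate_per_s = 0.1, burst_extra_samples_mean = 0,
                   startup_burst_ms = 5000, seed = 22)
  out <- apply_loss_model(sim, lm)
  s <- out$streams$belt
  pre <- loss_percentage(s)$mean_percent
  tr <- trim_startup(s)
  expect_true(tr$qc_pass)
  expect_gte(tr$startup_trimmed_ms, 5000)
  gaps <- detect_gaps(tr$stream)
  ## zero-extension model: no post-trim burst exceeds one reconnect except
  ## chance adjacency; the mode must be exactly 64 ms
  expect_equal(burst_statistics(gaps)$modal_ms, 64)
  post <- loss_percentage(tr$stream)$mean_percent
  expect_lte(post, pre)
})

test_that("qc_report aggregates per sensor and pooled", {
  sim <- simulate_gait_acceleration(healthy_profile(), 120, seed = 23)
  out <- apply_loss_model(sim, loss_model(seed = 24))
  rep <- qc_report(out$streams)
  expect_s3_class(rep, "qc_report")
  expect_equal(nrow(rep$per_sensor), 5)
  expect_true(all(rep$per_sensor$qc_pass))
  expect_true(rep$pooled$transmission_percent > 90)
  expect_output(print(rep), "Pooled")
})
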