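## Synthetic-data generator: gait acceleration, full sessions with activity
## schedules, and the wireless packet-loss process. Everything is seeded and
## returns explicit ground truth so downstream estimators can be validated
## without clinical recordings.

#' Gait profile for the synthetic walking generator
#'
#' Parameterises the statistical structure of a walker that the analysis
#' pipeline assumes: cadence, stride-timing variability, vertical
#' centre-of-mass excursion (which sets both the acceleration amplitude and,
#' through the inverted-pendulum model, the step length), pendulum (leg)
#' length, left/right amplitude asymmetry, and additive sensor noise.
#'
#' @param step_frequency_hz Mean steps per second (cadence / 60). Must be
#'   positive; typical adult walking is 1.5-2.5 Hz.
#' @param stride_time_cv Coefficient of variation of stride (two-step)
#'   intervals, a dimensionless fraction in `[0, 1)`. Healthy gait is around
#'   0.02; parkinsonian gait is substantially higher.
#' @param com_excursion_m Peak-to-trough vertical centre-of-mass displacement
#'   per step, in metres. Must lie in `(0, leg_length_m)`.
#' @param leg_length_m Pendulum length `l` in metres (greater trochanter to
#'   ground); must be positive.
#' @param asymmetry Fractional left/right amplitude difference in `[0, 1)`:
#'   left steps use `com_excursion_m * (1 + asymmetry/2)`, right steps
#'   `com_excursion_m * (1 - asymmetry/2)`.
#' @param harmonic_noise_sd Standard deviation of additive white noise on
#'   every channel, in g.
#' @return An object of class `gait_profile` (a validated named list).
#' @seealso [healthy_profile()], [pd_profile()], [simulate_gait_acceleration()]
#' @export
gait_profile <- function(step_frequency_hz = 1.9, stride_time_cv = 0.02,
                         com_excursion_m = 0.05, leg_length_m = 0.95,
                         asymmetry = 0.05, harmonic_noise_sd = 0.04) {
  assert_scalar(step_frequency_hz, "step_frequency_hz", lower = 0,
                strict_lower = TRUE)
  assert_scalar(stride_time_cv, "stride_time_cv", lower = 0, upper = 1,
                strict_upper = TRUE)
  assert_scalar(leg_length_m, "leg_length_m", lower = 0, strict_lower = TRUE)
  assert_scalar(com_excursion_m, "com_excursion_m", lower = 0,
                upper = leg_length_m, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar(asymmetry, "asymmetry", lower = 0, upper = 1,
                strict_upper = TRUE)
  assert_scalar(harmonic_noise_sd, "harmonic_noise_sd", lower = 0)
  ## asymmetric amplitudes must also stay below leg length
  if (com_excursion_m * (1 + asymmetry / 2) >= leg_length_m)
    stopf("field 'asymmetry' pushes com_excursion_m above leg_length_m")
  structure(list(step_frequency_hz = step_frequency_hz,
                 stride_time_cv = stride_time_cv,
                 com_excursion_m = com_excursion_m,
                 leg_length_m = leg_length_m,
                 asymmetry = asymmetry,
                 harmonic_noise_sd = harmonic_noise_sd),
            class = "gait_profile")
}

#' @rdname gait_profile
#' @param ... Overrides passed on to [gait_profile()].
#' @export
healthy_profile <- function(...) {
  args <- utils::modifyList(list(step_frequency_hz = 1.9,
                                 stride_time_cv = 0.02,
                                 com_excursion_m = 0.05,
                                 leg_length_m = 0.95,
                                 asymmetry = 0.05,
                                 harmonic_noise_sd = 0.04), list(...))
  do.call(gait_profile, args)
}

#' @rdname gait_profile
#' @export
pd_profile <- function(...) {
  ## Slower, shorter, more variable and more asymmetric steps with a noisier
  ## signal (tremor, dyskinesia) than the healthy default.
  args <- utils::modifyList(list(step_frequency_hz = 1.7,
                                 stride_time_cv = 0.10,
                                 com_excursion_m = 0.035,
                                 leg_length_m = 0.95,
                                 asymmetry = 0.15,
                                 harmonic_noise_sd = 0.08), list(...))
  do.call(gait_profile, args)
}

#' Inverted-pendulum step length
#'
#' Closed-form step length `s = 2 * sqrt(2 * l * h - h^2)` of the
#' inverted-pendulum model of human walking, where `l` is the pendulum (leg)
#' length and `h` the vertical centre-of-mass excursion during the step.
#'
#' @param h Vertical excursion in metres; values are clipped to `[0, l]`.
#' @param l Pendulum length in metres.
#' @return Step length in metres.
#' @export
pendulum_step_length <- function(h, l) {
  if (!is.numeric(h) || !is.numeric(l) || any(!is.finite(l)) || any(l <= 0))
    stopf("'l' must be positive and finite")
  h <- pmin(pmax(h, 0), l)
  2 * sqrt(2 * l * h - h^2)
}

## Draw stride intervals (seconds) with mean 2/f and the target CV.
## i.i.d. log-normal keeps intervals positive; cv = 0 degenerates to exact.
draw_stride_intervals <- function(n, step_frequency_hz, cv) {
  mu <- 2 / step_frequency_hz
  if (cv == 0) return(rep(mu, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate tri-axial walking acceleration for the five-sensor network
#'
#' Generates the belt and four limb sensors during continuous walking. The
#' vertical centre-of-mass displacement of each step is a raised-cosine arc
#' of amplitude `h`; the cranio-caudal (x) acceleration is its analytic
#' second derivative plus a 1 g gravity offset, so double integration
#' recovers `h` and the inverted-pendulum step length has a closed form.
#' Gait-cycle harmonics (2nd/3rd at -12 dB) enrich the anterio-posterior (z)
#' channel; the medio-lateral (y) channel sways at stride frequency. White
#' noise of sd `harmonic_noise_sd` is added to every channel.
#'
#' @param profile A [gait_profile()].
#' @param duration_s Positive duration in seconds.
#' @param fs_hz Sampling rate; must exceed twice the step frequency.
#' @param seed Integer RNG seed.
#' @return An object of class `gait_simulation`: list with `fs`, `t`
#'   (seconds), `sensors` (named list of n x 3 matrices, columns x/y/z in g)
#'   and `truth` (step times/durations/excursions/lengths, stride times and
#'   intervals, the profile).
#' @export
simulate_gait_acceleration <- function(profile, duration_s, fs_hz = BAN_FS_HZ,
                                       seed = 1L) {
  if (!inherits(profile, "gait_profile"))
    profile <- do.call(gait_profile, as.list(profile))
  assert_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar(fs_hz, "fs_hz", lower = 2 * profile$step_frequency_hz,
                strict_lower = TRUE)
  withr::with_seed(as.integer(seed), {
    sim_gait_unseeded(profile, duration_s, fs_hz)
  })
}

## Core generator, assumes RNG state already set (sessions reuse it so that
## one session seed governs everything).
sim_gait_unseeded <- function(profile, duration_s, fs_hz) {
  f <- profile$step_frequency_hz
  n_strides <- ceiling(duration_s * f / 2 * 1.6) + 4L
  strides <- draw_stride_intervals(n_strides, f, profile$stride_time_cv)
  while (sum(strides) < duration_s + 2 * 2 / f)
    strides <- c(strides, draw_stride_intervals(8L, f, profile$stride_time_cv))
  stride_starts <- cumsum(c(0, strides))
  ## two steps per stride, each half the stride interval
  step_times <- as.vector(rbind(stride_starts[-length(stride_starts)],
                                stride_starts[-length(stride_starts)] +
                                  strides / 2))
  step_bounds <- c(step_times, stride_starts[length(stride_starts)])
  n_steps_all <- length(step_times)
  step_dur <- diff(step_bounds)
  ## left (odd index) / right (even) amplitude asymmetry
  side_left <- (seq_len(n_steps_all) %% 2L) == 1L
  h_step <- profile$com_excursion_m *
    ifelse(side_left, 1 + profile$asymmetry / 2, 1 - profile$asymmetry / 2)

  n <- as.integer(round(duration_s * fs_hz))
  t <- (seq_len(n) - 1L) / fs_hz
  k <- findInterval(t, step_bounds, rightmost.closed = FALSE)
  k[k < 1L] <- 1L
  k[k > n_steps_all] <- n_steps_all
  theta <- 2 * pi * (t - step_times[k]) / step_dur[k]
  amp_ms2 <- (h_step[k] / 2) * (2 * pi / step_dur[k])^2    # m/s^2
  amp_g <- amp_ms2 / STANDARD_GRAVITY
  stride_phase <- pi * (k - 1L) + theta / 2                # flips sign per step

  nz <- function() stats::rnorm(n, 0, profile$harmonic_noise_sd)
  harm <- 10^(-12 / 20)                                    # -12 dB
  x_gait <- amp_g * cos(theta)                             # cranio-caudal, no DC
  z_belt <- 0.5 * amp_g * (sin(theta) + harm * sin(2 * theta) +
                             harm * sin(3 * theta))
  y_belt <- 0.3 * amp_g * sin(stride_phase)

  mk <- function(x, y, z) {
    m <- cbind(x = x, y = y, z = z)
    m
  }
  side_factor <- function(left) ifelse(side_left[k] == left, 1.6, 0.5)
  sensors <- list(
    belt = mk(1 + x_gait + nz(), y_belt + nz(), z_belt + nz()),
    left_wrist = mk(0.15 * amp_g * sin(stride_phase) + nz(), nz(),
                    0.1 * amp_g * cos(stride_phase) + nz()),
    right_wrist = mk(-0.15 * amp_g * sin(stride_phase) + nz(), nz(),
                     -0.1 * amp_g * cos(stride_phase) + nz()),
    left_leg = mk(1 + x_gait * side_factor(TRUE) + nz(), nz(),
                  0.8 * amp_g * cos(theta) * side_factor(TRUE) + nz()),
    right_leg = mk(1 + x_gait * side_factor(FALSE) + nz(), nz(),
                   0.8 * amp_g * cos(theta) * side_factor(FALSE) + nz())
  )
  keep <- step_times < duration_s
  stride_times <- stride_starts[stride_starts < duration_s]
  structure(list(
    fs = fs_hz, duration_s = duration_s, t = t, sensors = sensors,
    truth = list(step_times = step_times[keep],
                 step_durations = step_dur[keep],
                 step_excursions_m = h_step[keep],
                 step_lengths_m = pendulum_step_length(h_step[keep],
                                                       profile$leg_length_m),
                 stride_times = stride_times,
                 stride_intervals = diff(stride_times),
                 profile = profile)),
    class = "gait_simulation")
}

#' Activity schedule
#'
#' Ordered, non-overlapping intervals labelled `walking`, `resting` or
#' `arm_task` that tile `[0, duration]` of a simulated session.
#'
#' @param start_s,end_s,label Equal-length vectors of interval bounds
#'   (seconds) and labels.
#' @return A validated `activity_schedule` data frame.
#' @export
activity_schedule <- function(start_s, end_s, label) {
  sched <- data.frame(start_s = as.numeric(start_s),
                      end_s = as.numeric(end_s),
                      label = as.character(label),
                      stringsAsFactors = FALSE)
  if (nrow(sched) == 0L) stopf("schedule must contain at least one interval")
  if (!all(sched$label %in% c("walking", "resting", "arm_task")))
    stopf("schedule labels must be one of walking/resting/arm_task")
  if (sched$start_s[1L] != 0) stopf("schedule must start at 0 s")
  if (any(sched$end_s <= sched$start_s))
    stopf("schedule intervals must have positive length")
  if (nrow(sched) > 1L &&
      any(abs(sched$start_s[-1L] - sched$end_s[-nrow(sched)]) > 1e-9))
    stopf("schedule intervals must be contiguous and non-overlapping")
  class(sched) <- c("activity_schedule", "data.frame")
  sched
}

#' Random activity schedule with a fixed number of labelled segments
#'
#' @param n_segments Number of intervals.
#' @param labels Candidate labels sampled per segment.
#' @param dur_range_s Min/max segment duration (uniform), seconds.
#' @param seed Integer RNG seed.
#' @export
random_schedule <- function(n_segments = 200L,
                            labels = c("walking", "resting", "arm_task"),
                            dur_range_s = c(15, 40), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    durs <- stats::runif(n_segments, dur_range_s[1L], dur_range_s[2L])
    labs <- sample(labels, n_segments, replace = TRUE)
  })
  ends <- cumsum(durs)
  activity_schedule(c(0, ends[-n_segments]), ends, labs)
}

#' Simulate a full multi-activity session
#'
#' Walking intervals are produced by [simulate_gait_acceleration()]; resting
#' intervals hold near-constant gravity plus device noise on every sensor;
#' `arm_task` intervals add broadband amplitude-modulated transients to the
#' wrist sensors while the legs and belt stay quiet.
#'
#' @inheritParams simulate_gait_acceleration
#' @param schedule An [activity_schedule()].
#' @param rest_noise_sd Device-noise sd (g) outside walking.
#' @return An object of class `ban_session`: as `gait_simulation` plus
#'   per-sample `labels` and the `schedule`; `truth$walking` lists one entry
#'   per walking interval with absolute step times.
#' @export
simulate_session <- function(schedule, profile = healthy_profile(),
                             fs_hz = BAN_FS_HZ, seed = 1L,
                             rest_noise_sd = 0.015) {
  if (!inherits(schedule, "activity_schedule"))
    schedule <- activity_schedule(schedule$start_s, schedule$end_s,
                                  schedule$label)
  if (!inherits(profile, "gait_profile"))
    profile <- do.call(gait_profile, as.list(profile))
  duration_s <- schedule$end_s[nrow(schedule)]
  n <- as.integer(round(duration_s * fs_hz))
  t <- (seq_len(n) - 1L) / fs_hz
  labels <- character(n)
  sensors <- lapply(BAN_SENSORS, function(s) {
    m <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
    m
  })
  names(sensors) <- BAN_SENSORS
  walking_truth <- list()

  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(schedule))) {
      i0 <- findInterval(schedule$start_s[i] - 1e-9, t) + 1L
      i1 <- min(n, as.integer(round(schedule$end_s[i] * fs_hz)))
      idx <- i0:i1
      labels[idx] <- schedule$label[i]
      ni <- length(idx)
      ti <- t[idx] - t[idx[1L]]
      if (schedule$label[i] == "walking") {
        sim <- sim_gait_unseeded(profile, ni / fs_hz, fs_hz)
        for (s in BAN_SENSORS)
          sensors[[s]][idx, ] <- sim$sensors[[s]][seq_len(ni), ]
        tr <- sim$truth
        tr$step_times <- tr$step_times + t[idx[1L]]
        tr$stride_times <- tr$stride_times + t[idx[1L]]
        tr$interval <- c(schedule$start_s[i], schedule$end_s[i])
        walking_truth[[length(walking_truth) + 1L]] <- tr
      } else {
        for (s in BAN_SENSORS) {
          base <- if (s %in% c("belt", "left_leg", "right_leg")) 1 else 0
          sensors[[s]][idx, ] <-
            cbind(base + stats::rnorm(ni, 0, rest_noise_sd),
                  stats::rnorm(ni, 0, rest_noise_sd),
                  stats::rnorm(ni, 0, rest_noise_sd))
        }
        if (schedule$label[i] == "arm_task") {
          ## broadband transients: smoothed random envelope times white noise
          for (s in c("left_wrist", "right_wrist")) {
            env <- fft_filter(stats::rnorm(ni), fs_hz, high = 0.4)
            env <- pmax(0, env) / max(1e-9, max(abs(env)))
            burst <- 0.9 * env * stats::rnorm(ni)
            sensors[[s]][idx, "x"] <- sensors[[s]][idx, "x"] + burst
            sensors[[s]][idx, "z"] <- sensors[[s]][idx, "z"] +
              0.6 * env * stats::rnorm(ni)
          }
        }
      }
    }
  })
  structure(list(fs = fs_hz, duration_s = duration_s, t = t,
                 sensors = sensors, labels = labels, schedule = schedule,
                 truth = list(walking = walking_truth, profile = profile)),
            class = c("ban_session", "gait_simulation"))
}

#' Wireless packet-loss model
#'
#' Disconnection events arrive as a Poisson process; each removes the
#' 4-sample logger-reconnect minimum (64 ms at 62.5 Hz) plus a geometric
#' number of extra samples. A start-up burst removes the first
#' `startup_burst_ms` of every stream, emulating the long initial bursts
#' seen before all sensors are connected.
#'
#' @param disconnect_rate_per_s Poisson rate of disconnections (events/s).
#' @param burst_extra_samples_mean Mean of the geometric extension beyond
#'   the 4-sample minimum (0 gives all-64 ms bursts).
#' @param startup_burst_ms Duration of the initial pre-connection loss (ms).
#' @param seed Integer RNG seed used by [apply_loss_model()].
#' @return An object of class `loss_model`.
#' @export
loss_model <- function(disconnect_rate_per_s = 0.1,
                       burst_extra_samples_mean = 2,
                       startup_burst_ms = 5000, seed = 1L) {
  assert_scalar(disconnect_rate_per_s, "disconnect_rate_per_s", lower = 0)
  assert_scalar(burst_extra_samples_mean, "burst_extra_samples_mean",
                lower = 0)
  assert_scalar(startup_burst_ms, "startup_burst_ms", lower = 0)
  structure(list(disconnect_rate_per_s = disconnect_rate_per_s,
                 burst_extra_samples_mean = burst_extra_samples_mean,
                 startup_burst_ms = startup_burst_ms,
                 seed = as.integer(seed)),
            class = "loss_model")
}

#' Loss model calibrated to a target sporadic-loss percentage
#'
#' Sets the disconnection rate so the expected fraction of dropped samples
#' equals `loss_percent`: rate = (loss/100) * fs / (4 + extra_mean).
#'
#' @param loss_percent Target mean data loss in percent.
#' @param burst_extra_samples_mean,startup_burst_ms,seed See [loss_model()].
#' @param fs_hz Sampling rate.
#' @export
loss_model_for_percent <- function(loss_percent, burst_extra_samples_mean = 2,
                                   startup_burst_ms = 0, seed = 1L,
                                   fs_hz = BAN_FS_HZ) {
  assert_scalar(loss_percent, "loss_percent", lower = 0, upper = 100)
  loss_model(disconnect_rate_per_s =
               loss_percent / 100 * fs_hz / (4 + burst_extra_samples_mean),
             burst_extra_samples_mean = burst_extra_samples_mean,
             startup_burst_ms = startup_burst_ms, seed = seed)
}

#' Apply the packet-loss process to a simulated signal set
#'
#' Each sensor suffers an independent realisation of the loss model. Emitted
#' packets carry timestamps on the 16 ms grid; ground truth lists every
#' dropped grid index so that `packets kept + dropped = expected` always.
#'
#' @param signals A `gait_simulation` / `ban_session`.
#' @param loss A [loss_model()].
#' @param fs_hz Sampling rate (must match the nominal 16 ms grid).
#' @param seed Overrides `loss$seed` when given.
#' @return List with `streams` (named list of [packet_stream()]), `dropped`
#'   (named list of 1-based dropped grid indices) and `expected_n`.
#' @export
apply_loss_model <- function(signals, loss, fs_hz = signals$fs, seed = NULL) {
  if (!inherits(loss, "loss_model")) loss <- do.call(loss_model, as.list(loss))
  seed <- if (is.null(seed)) loss$seed else as.integer(seed)
  interval_ms <- 1000 / fs_hz
  if (abs(interval_ms - round(interval_ms)) > 1e-9)
    stopf("fs_hz must give an integer millisecond sampling interval")
  interval_ms <- as.integer(round(interval_ms))
  n <- length(signals$t)
  duration_s <- n / fs_hz
  span_ms <- interval_ms * (n - 1L)
  streams <- list()
  dropped <- list()
  withr::with_seed(seed, {
    for (s in names(signals$sensors)) {
      drop <- rep(FALSE, n)
      n_events <- stats::rpois(1L, loss$disconnect_rate_per_s * duration_s)
      if (n_events > 0L) {
        starts <- sample.int(n, n_events, replace = TRUE)
        extras <- if (loss$burst_extra_samples_mean > 0)
          stats::rgeom(n_events, 1 / (1 + loss$burst_extra_samples_mean))
        else rep(0L, n_events)
        for (e in seq_len(n_events)) {
          i1 <- min(n, starts[e] + 4L + extras[e] - 1L)
          drop[starts[e]:i1] <- TRUE
        }
      }
      if (loss$startup_burst_ms > 0) {
        ts <- interval_ms * (seq_len(n) - 1L)
        drop[ts < loss$startup_burst_ms] <- TRUE
      }
      keep <- which(!drop)
      streams[[s]] <- packet_stream(
        sensor_id = s,
        timestamp_ms = as.integer(interval_ms * (keep - 1L)),
        acc_g = signals$sensors[[s]][keep, , drop = FALSE],
        expected_span_ms = span_ms)
      dropped[[s]] <- which(drop)
    }
  })
  list(streams = streams, dropped = dropped, expected_n = n)
}
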