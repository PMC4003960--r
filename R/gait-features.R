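## Gait descriptors per walking segment: sample entropy of the cranio-caudal
## belt channel, step detection on its band-passed envelope, step frequency,
## stride-to-stride variability, inverted-pendulum stride length from
## double-integrated vertical acceleration, and walking velocity.

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of distinct length-`m`
#' templates whose Chebyshev distance is at most the tolerance and A counts
#' the same pairs still matching when extended by one point. Self-matches
#' are excluded; both counts run over the `N - m` templates that admit a
#' continuation. Lower values mean a more regular (predictable) series;
#' parkinsonian gait degrades regularity and raises SampEn.
#'
#' @param x Numeric series, length > `m + 1`.
#' @param m Template length (default 2).
#' @param r Similarity tolerance; a fraction of `sd(x)` when
#'   `relative = TRUE` (default 0.2), otherwise absolute.
#' @param relative Interpret `r` as sd-relative (default) or absolute.
#' @return Non-negative value. A constant series returns 0 with attribute
#'   `degenerate = TRUE`; if no template pair matches (A or B zero) the
#'   result is `Inf` with attribute `undefined = TRUE`.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, relative = TRUE) {
  assert_scalar(m, "m", lower = 1, integer = TRUE)
  assert_scalar(r, "r", lower = 0, strict_lower = TRUE)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stopf("sample_entropy: non-finite input")
  if (length(x) <= m + 1L)
    stopf("sample_entropy: series length must exceed m + 1")
  sdx <- stats::sd(x)
  if (sdx == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tol <- if (relative) r * sdx else r
  counts <- sampen_counts(x, as.integer(m), tol)
  B <- counts[["B"]]; A <- counts[["A"]]
  if (B == 0 || A == 0) {
    out <- Inf
    attr(out, "undefined") <- TRUE
    return(out)
  }
  -log(A / B)
}

#' Detect step events in a walking segment
#'
#' The cranio-caudal belt channel is band-passed to the 0.5-3 Hz gait band;
#' the step rate is estimated from the dominant spectral peak, and peaks at
#' least a quarter step-period apart are taken as step events (refined to
#' sub-sample precision by parabolic interpolation). Segments without a
#' clear gait rhythm (little band power concentrated at the step rate) or
#' with fewer than 4 peaks are skipped with a reason.
#'
#' @param recording A gap-free `recording`.
#' @param start_s,end_s Segment bounds in seconds (defaults: whole
#'   recording). A `walking_segments` row can be passed as `start_s`.
#' @param sensor,axis Channel to use (default belt, x).
#' @param band Gait band in Hz.
#' @param min_rhythm Minimum fraction of band power within +/-0.25 Hz of the
#'   dominant peak for the segment to count as rhythmic walking.
#' @return Numeric vector of step times (seconds, strictly increasing), or
#'   `NULL` with attribute-free explanation via the `skipped` class: a list
#'   with `reason`.
#' @export
detect_steps <- function(recording, start_s = NULL, end_s = NULL,
                         sensor = "belt", axis = "x", band = c(0.5, 3),
                         min_rhythm = 0.3) {
  stopifnot(inherits(recording, "recording"))
  if (is.data.frame(start_s)) {
    end_s <- start_s$end_s[1L]; start_s <- start_s$start_s[1L]
  }
  if (is.null(start_s)) start_s <- recording$t0_s
  if (is.null(end_s)) end_s <- recording$t0_s + recording$n / recording$fs
  fs <- recording$fs
  i0 <- max(1L, as.integer(floor((start_s - recording$t0_s) * fs)) + 1L)
  i1 <- min(recording$n, as.integer(ceiling((end_s - recording$t0_s) * fs)))
  skip <- function(reason) structure(list(reason = reason), class = "skipped")
  if (i1 - i0 + 1L < 4 * fs / band[1L])
    return(skip("segment too short for step detection"))
  ch <- recording$sensors[[sensor]][i0:i1, axis]
  if (any(is.na(ch))) return(skip("segment contains unfilled gaps"))
  bp <- fft_filter(ch - mean(ch), fs, low = band[1L], high = band[2L])
  f_est <- dominant_frequency(bp, fs, band)
  if (!is.finite(f_est) || f_est <= 0)
    return(skip("no dominant frequency in the gait band"))
  ## rhythmicity guard: resting noise has no concentrated spectral peak
  conc <- band_power_ratio(bp, fs, c(max(band[1L], f_est - 0.25),
                                     min(band[2L], f_est + 0.25))) /
    max(band_power_ratio(bp, fs, band), .Machine$double.eps)
  if (conc < min_rhythm)
    return(skip("no gait rhythm: band power not concentrated at a step rate"))
  min_dist <- max(1L, as.integer(round(0.25 / f_est * fs)))
  peaks <- find_peaks(bp, min_dist = min_dist,
                      min_height = 0.3 * stats::quantile(bp[bp > 0], 0.9))
  if (length(peaks) < 4L) return(skip("fewer than 4 step peaks"))
  times <- vapply(peaks, function(i) refine_peak(bp, i), 0)
  sort(recording$t0_s + (i0 - 1L + times - 1L) / fs)
}

#' Step frequency from step-event times
#'
#' `(n - 1) / (t_n - t_1)` in Hz. Fewer than 4 steps give `NA` with
#' attribute `reason`.
#'
#' @param step_times Strictly increasing step times in seconds.
#' @export
step_frequency <- function(step_times) {
  n <- length(step_times)
  if (n < 4L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 4 steps"
    return(out)
  }
  (n - 1) / (step_times[n] - step_times[1L])
}

#' Stride-to-stride variability (coefficient of variation)
#'
#' Stride intervals are alternate-step differences of the step times. The
#' stride parity (which step begins a stride) is unknown in measured data;
#' intervals of the wrong parity are means of adjacent strides, which
#' shrinks their CV by about 1/sqrt(2), so the parity with the larger CV is
#' reported.
#'
#' @param step_times Strictly increasing step times in seconds.
#' @return CV (sd/mean, sample sd) as a fraction; `NA` with attribute
#'   `reason` when fewer than 4 steps.
#' @export
stride_time_cv <- function(step_times) {
  n <- length(step_times)
  if (n < 4L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 4 steps"
    return(out)
  }
  cv_parity <- function(t0) {
    s <- step_times[seq.int(t0, n, by = 2L)]
    if (length(s) < 3L) return(NA_real_)
    d <- diff(s)
    stats::sd(d) / mean(d)
  }
  cvs <- c(cv_parity(1L), cv_parity(2L))
  if (all(is.na(cvs))) {
    out <- NA_real_
    attr(out, "reason") <- "too few strides per parity"
    return(out)
  }
  max(cvs, na.rm = TRUE)
}

#' Inverted-pendulum stride length from vertical acceleration
#'
#' The cranio-caudal channel (g) is converted to m/s^2, zero-phase
#' high-pass filtered at `highpass_hz` (removing gravity and integration
#' drift), integrated twice (trapezoidal, with the same high-pass after
#' each stage), and the per-step peak-to-trough vertical excursion `h` is
#' read off between consecutive step events. Step length follows from the
#' pendulum geometry `s = 2 * sqrt(2 * l * h - h^2)` with `h` clipped to
#' `(0, l]`; steps whose `h` collapses to 0 are dropped and counted. Steps
#' within `edge_trim_s` of the segment ends are excluded (filter edge
#' transients).
#'
#' @param recording A gap-free `recording`.
#' @param step_times Step-event times from [detect_steps()] (seconds).
#' @param leg_length_m Pendulum length `l` in metres (subject calibration).
#' @param sensor,axis Channel (default belt, x).
#' @param highpass_hz Drift-removal cutoff (default 0.1 Hz).
#' @param edge_trim_s Segment-edge exclusion (default 1.5 s).
#' @return List with `per_step` (data frame: `t_start_s`, `h_m`,
#'   `length_m`), `mean_length_m`, `n_used`, `n_dropped`.
#' @export
stride_length <- function(recording, step_times, leg_length_m,
                          sensor = "belt", axis = "x", highpass_hz = 0.1,
                          edge_trim_s = 1.5) {
  stopifnot(inherits(recording, "recording"))
  assert_scalar(leg_length_m, "leg_length_m", lower = 0, strict_lower = TRUE)
  fs <- recording$fs
  ch <- recording$sensors[[sensor]][, axis]
  if (any(is.na(ch))) stopf("stride_length: recording contains unfilled gaps")
  a <- fft_filter(ch * STANDARD_GRAVITY, fs, low = highpass_hz)
  v <- fft_filter(cumtrapz(a, fs), fs, low = highpass_hz)
  d <- fft_filter(cumtrapz(v, fs), fs, low = highpass_hz)
  t_lo <- recording$t0_s + edge_trim_s
  t_hi <- recording$t0_s + recording$n / fs - edge_trim_s
  n_used <- 0L; n_dropped <- 0L
  rows <- list()
  for (k in seq_len(length(step_times) - 1L)) {
    if (step_times[k] < t_lo || step_times[k + 1L] > t_hi) next
    i0 <- as.integer(floor((step_times[k] - recording$t0_s) * fs)) + 1L
    i1 <- min(recording$n,
              as.integer(ceiling((step_times[k + 1L] - recording$t0_s) * fs)))
    if (i1 - i0 < 2L) next
    h <- max(d[i0:i1]) - min(d[i0:i1])
    if (!is.finite(h) || h <= 0) { n_dropped <- n_dropped + 1L; next }
    h <- min(h, leg_length_m)
    n_used <- n_used + 1L
    rows[[n_used]] <- data.frame(t_start_s = step_times[k], h_m = h,
                                 length_m = pendulum_step_length(h, leg_length_m))
  }
  per_step <- if (n_used) do.call(rbind, rows)
              else data.frame(t_start_s = numeric(0), h_m = numeric(0),
                              length_m = numeric(0))
  list(per_step = per_step,
       mean_length_m = if (n_used) mean(per_step$length_m) else NA_real_,
       n_used = n_used, n_dropped = n_dropped)
}

#' Walking velocity
#'
#' Segment-mean walking speed: step frequency times mean step length.
#'
#' @param step_frequency_hz Steps per second.
#' @param mean_step_length_m Mean step length in metres.
#' @return Speed in m/s.
#' @export
gait_velocity <- function(step_frequency_hz, mean_step_length_m) {
  if (!is.finite(step_frequency_hz) || !is.finite(mean_step_length_m))
    return(NA_real_)
  step_frequency_hz * mean_step_length_m
}

#' Gait feature set for one walking segment
#'
#' Computes every descriptor for one segment: sample entropy of the raw
#' cranio-caudal belt channel, step frequency, stride-to-stride CV,
#' inverted-pendulum stride length and velocity. The `velocity_consistent`
#' flag checks `|v - f * s| <= 1e-9`.
#'
#' @param recording A gap-free `recording`.
#' @param segment One `walking_segments` row (or `NULL` for the whole
#'   recording).
#' @param leg_length_m Pendulum length in metres.
#' @param sampen_m,sampen_r Sample-entropy parameters (defaults m = 2,
#'   r = 0.2 sd).
#' @param sensor Sensor carrying the gait signal (default belt).
#' @return One-row data frame (class `gait_features`): segment bounds,
#'   `n_steps`, `sample_entropy`, `step_frequency_hz`, `stride_time_cv`,
#'   `stride_length_m`, `velocity_m_s`, `n_steps_dropped`,
#'   `velocity_consistent`, `skipped_reason`.
#' @export
gait_features <- function(recording, segment = NULL, leg_length_m,
                          sampen_m = 2L, sampen_r = 0.2, sensor = "belt") {
  start_s <- if (is.null(segment)) recording$t0_s else segment$start_s[1L]
  end_s <- if (is.null(segment)) recording$t0_s + recording$n / recording$fs
           else segment$end_s[1L]
  empty <- function(reason) {
    out <- data.frame(start_s = start_s, end_s = end_s, n_steps = 0L,
                      sample_entropy = NA_real_,
                      step_frequency_hz = NA_real_,
                      stride_time_cv = NA_real_, stride_length_m = NA_real_,
                      velocity_m_s = NA_real_, n_steps_dropped = 0L,
                      velocity_consistent = NA, skipped_reason = reason)
    class(out) <- c("gait_features", "data.frame")
    out
  }
  steps <- detect_steps(recording, start_s, end_s, sensor = sensor)
  if (inherits(steps, "skipped")) return(empty(steps$reason))
  fs <- recording$fs
  i0 <- max(1L, as.integer(floor((start_s - recording$t0_s) * fs)) + 1L)
  i1 <- min(recording$n, as.integer(ceiling((end_s - recording$t0_s) * fs)))
  se <- sample_entropy(recording$sensors[[sensor]][i0:i1, "x"],
                       m = sampen_m, r = sampen_r)
  f <- step_frequency(steps)
  cv <- stride_time_cv(steps)
  sl <- stride_length(recording, steps, leg_length_m, sensor = sensor)
  v <- gait_velocity(f, sl$mean_length_m)
  out <- data.frame(start_s = start_s, end_s = end_s,
                    n_steps = length(steps),
                    sample_entropy = as.numeric(se),
                    step_frequency_hz = as.numeric(f),
                    stride_time_cv = as.numeric(cv),
                    stride_length_m = sl$mean_length_m,
                    velocity_m_s = v,
                    n_steps_dropped = sl$n_dropped,
                    velocity_consistent =
                      is.finite(v) && abs(v - f * sl$mean_length_m) <= 1e-9,
                    skipped_reason = NA_character_)
  class(out) <- c("gait_features", "data.frame")
  out
}
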