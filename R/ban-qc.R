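## Transmission quality control: gaps are detected from the unique packet
## timestamps (the sensors have no retransmission protocol), summarised as
## burst-error statistics, and the unstable start-up period is trimmed
## before any gait feature is computed.

#' Detect transmission gaps in a packet stream
#'
#' For consecutive timestamps `t_i`, `t_{i+1}` a burst is emitted iff
#' `t_{i+1} - t_i > 16` ms, with `missing_samples = (t_{i+1} - t_i)/16 - 1`.
#' A missing leading portion (before the first packet) and trailing portion
#' (after the last packet, up to the expected span) are reported as bursts
#' too, so that `expected = received + sum(missing)` always holds. Packets
#' are sorted before detection, so the result is order-invariant.
#'
#' @param stream A [packet_stream()].
#' @return Data frame with columns `start_ms` (first missing sample),
#'   `end_ms` (`start_ms + duration_ms`), `missing_samples`, `duration_ms`.
#' @export
detect_gaps <- function(stream) {
  validate_packet_stream(stream)
  iv <- stream$nominal_interval_ms
  ts <- sort(stream$timestamp_ms)
  ## virtual packets one interval outside the session bracket the span
  ts_ext <- c(-iv, ts, stream$expected_span_ms + iv)
  d <- diff(ts_ext)
  gap <- which(d > iv)
  missing <- as.integer(d[gap] / iv - 1L)
  start_ms <- ts_ext[gap] + iv
  data.frame(start_ms = start_ms,
             end_ms = start_ms + missing * iv,
             missing_samples = missing,
             duration_ms = missing * iv)
}

#' Per-window data-loss percentage
#'
#' Loss is `100 * missing / expected` per fixed-length analysis window; the
#' report gives the mean and (population) standard deviation across windows,
#' mirroring the "data loss (%) mean +/- sd" convention of deployment
#' reports. A stream shorter than one window yields a single-window report
#' with `sd_undefined = TRUE`.
#'
#' @param stream A [packet_stream()].
#' @param window_s Analysis window length in seconds (default 60).
#' @return List with `mean_percent`, `sd_percent`, `per_window` (data
#'   frame), `n_windows`, `sd_undefined`, `missing_total`, `expected_total`.
#' @export
loss_percentage <- function(stream, window_s = 60) {
  assert_scalar(window_s, "window_s", lower = 0, strict_lower = TRUE)
  validate_packet_stream(stream)
  iv <- stream$nominal_interval_ms
  n_exp <- expected_samples(stream)
  present <- rep(FALSE, n_exp)
  idx <- as.integer(stream$timestamp_ms / iv) + 1L
  present[idx[idx <= n_exp]] <- TRUE
  win_len <- as.integer(round(window_s * 1000 / iv))
  win_id <- (seq_len(n_exp) - 1L) %/% win_len
  expected <- as.vector(table(win_id))
  missing <- as.vector(tapply(!present, win_id, sum))
  loss <- 100 * missing / expected
  per_window <- data.frame(window = seq_along(loss) - 1L,
                           start_s = (seq_along(loss) - 1L) * window_s,
                           expected = expected, missing = missing,
                           loss_percent = loss)
  single <- length(loss) < 2L
  list(mean_percent = mean(loss),
       sd_percent = if (single) NA_real_ else pop_sd(loss),
       per_window = per_window,
       n_windows = length(loss),
       sd_undefined = single,
       missing_total = sum(missing),
       expected_total = n_exp)
}

#' Burst-length statistics
#'
#' Arithmetic mean, population sd and mode of the burst durations (ms). The
#' 16 ms grid makes durations discrete, so the mode needs no binning; ties
#' are broken towards the smallest duration. An empty burst list returns an
#' empty-report sentinel rather than an error.
#'
#' @param bursts Data frame from [detect_gaps()] (or a vector of durations
#'   in ms).
#' @return List with `n`, `mean_ms`, `sd_ms`, `modal_ms`, `empty`.
#' @export
burst_statistics <- function(bursts) {
  dur <- if (is.data.frame(bursts)) bursts$duration_ms else as.numeric(bursts)
  if (length(dur) == 0L)
    return(list(n = 0L, mean_ms = NA_real_, sd_ms = NA_real_,
                modal_ms = NA_real_, empty = TRUE))
  list(n = length(dur), mean_ms = mean(dur), sd_ms = pop_sd(dur),
       modal_ms = modal_value(dur), empty = FALSE)
}

#' Trim the unstable start-up period
#'
#' The longest burst errors cluster at the beginning of a session, while the
#' sensors connect. Everything before the first gap-free window of
#' `stable_s` seconds is discarded and the trimmed duration reported;
#' timestamps are re-based so the trimmed stream starts at 0. If no stable
#' window exists the stream fails QC.
#'
#' @param stream A [packet_stream()].
#' @param stable_s Required gap-free run length in seconds (default 10).
#' @return List with `stream` (trimmed, or `NULL` on failure),
#'   `startup_trimmed_ms`, `qc_pass`, `reason`.
#' @export
trim_startup <- function(stream, stable_s = 10) {
  assert_scalar(stable_s, "stable_s", lower = 0, strict_lower = TRUE)
  gaps <- detect_gaps(stream)
  iv <- stream$nominal_interval_ms
  stable_ms <- stable_s * 1000
  span <- stream$expected_span_ms
  candidates <- sort(unique(c(0, gaps$end_ms)))
  candidates <- candidates[candidates + stable_ms <= span + iv]
  t0 <- NA_real_
  for (cand in candidates) {
    nxt <- gaps$start_ms[gaps$start_ms >= cand]
    if (!length(nxt) || min(nxt) >= cand + stable_ms) { t0 <- cand; break }
  }
  if (is.na(t0))
    return(list(stream = NULL, startup_trimmed_ms = NA_real_,
                qc_pass = FALSE,
                reason = sprintf("no gap-free window of %g s found", stable_s)))
  keep <- stream$timestamp_ms >= t0
  trimmed <- packet_stream(stream$sensor_id,
                           stream$timestamp_ms[keep] - t0,
                           stream$acc_g[keep, , drop = FALSE],
                           expected_span_ms = span - t0,
                           nominal_interval_ms = iv)
  list(stream = trimmed, startup_trimmed_ms = t0, qc_pass = TRUE,
       reason = NULL)
}

#' Quality-control report for a set of packet streams
#'
#' Per sensor (and pooled): data-loss percentage mean +/- sd across analysis
#' windows, average and most frequent burst-error length, and the trimmed
#' start-up duration. Mirrors the three-column loss table of deployment
#' reports.
#'
#' @param streams Named list of [packet_stream()] objects.
#' @param window_s Analysis window for [loss_percentage()].
#' @param stable_s Start-up policy for [trim_startup()]; `NULL` skips
#'   trimming.
#' @return Object of class `qc_report`: list with `per_sensor` data frame,
#'   `pooled` row, `trimmed` streams and `window_s`.
#' @export
qc_report <- function(streams, window_s = 60, stable_s = 10) {
  if (inherits(streams, "packet_stream")) streams <- list(streams)
  if (is.null(names(streams)))
    names(streams) <- vapply(streams, `[[`, "", "sensor_id")
  rows <- list()
  trimmed <- list()
  all_dur <- numeric(0)
  pooled_missing <- 0
  pooled_expected <- 0
  for (id in names(streams)) {
    s <- streams[[id]]
    tr <- if (is.null(stable_s)) list(stream = s, startup_trimmed_ms = 0,
                                      qc_pass = TRUE)
          else trim_startup(s, stable_s)
    if (!tr$qc_pass) {
      rows[[id]] <- data.frame(sensor = id, qc_pass = FALSE,
                               loss_mean_percent = NA_real_,
                               loss_sd_percent = NA_real_,
                               burst_mean_ms = NA_real_,
                               burst_sd_ms = NA_real_,
                               burst_modal_ms = NA_real_,
                               startup_trimmed_ms = NA_real_,
                               n_bursts = NA_integer_)
      next
    }
    st <- tr$stream
    trimmed[[id]] <- st
    gaps <- detect_gaps(st)
    lp <- loss_percentage(st, window_s)
    bs <- burst_statistics(gaps)
    all_dur <- c(all_dur, gaps$duration_ms)
    pooled_missing <- pooled_missing + lp$missing_total
    pooled_expected <- pooled_expected + lp$expected_total
    rows[[id]] <- data.frame(sensor = id, qc_pass = TRUE,
                             loss_mean_percent = lp$mean_percent,
                             loss_sd_percent = lp$sd_percent,
                             burst_mean_ms = bs$mean_ms,
                             burst_sd_ms = bs$sd_ms,
                             burst_modal_ms = bs$modal_ms,
                             startup_trimmed_ms = tr$startup_trimmed_ms,
                             n_bursts = bs$n)
  }
  per_sensor <- do.call(rbind, rows)
  rownames(per_sensor) <- NULL
  pb <- burst_statistics(all_dur)
  pooled <- data.frame(
    loss_percent = if (pooled_expected > 0)
      100 * pooled_missing / pooled_expected else NA_real_,
    transmission_percent = if (pooled_expected > 0)
      100 * (1 - pooled_missing / pooled_expected) else NA_real_,
    burst_mean_ms = pb$mean_ms, burst_sd_ms = pb$sd_ms,
    burst_modal_ms = pb$modal_ms, n_bursts = pb$n)
  structure(list(per_sensor = per_sensor, pooled = pooled,
                 trimmed = trimmed, window_s = window_s),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Transmission quality report (window", x$window_s, "s)\n")
  df <- x$per_sensor
  cat(sprintf("%-12s %-18s %-24s %-10s\n", "Sensor", "Data loss (%)",
              "Avg burst length (ms)", "Modal (ms)"))
  for (i in seq_len(nrow(df))) {
    if (!df$qc_pass[i]) {
      cat(sprintf("%-12s QC FAIL\n", df$sensor[i])); next
    }
    cat(sprintf("%-12s %6.2f +/- %-6s %10.2f +/- %-8.2f %6d\n",
                df$sensor[i], df$loss_mean_percent[i],
                ifelse(is.na(df$loss_sd_percent[i]), "NA",
                       sprintf("%.2f", df$loss_sd_percent[i])),
                df$burst_mean_ms[i],
                ifelse(is.na(df$burst_sd_ms[i]), NA_real_, df$burst_sd_ms[i]),
                as.integer(df$burst_modal_ms[i])))
  }
  cat(sprintf("Pooled: %.2f%% loss (%.2f%% transmitted), modal burst %s ms\n",
              x$pooled$loss_percent, x$pooled$transmission_percent,
              format(x$pooled$burst_modal_ms)))
  invisible(x)
}
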