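## Preprocessing: unit-interval normalization (for plotting/export parity
## with the display convention of the sensor platform), the 3-axis module,
## gridding of packet streams onto the uniform 62.5 Hz grid, and gap
## filling/splitting. Features always operate on raw g values; the
## normalized path exists for display and export.

#' Normalize acceleration to the unit interval
#'
#' `(a + 6) / 12`: the -6 g full-scale minimum maps to 0, +6 g to 1.
#' Values outside the full scale are clipped and counted in the `clipped`
#' attribute.
#'
#' @param a_g Acceleration value(s) in g; must be finite.
#' @return Values in `[0, 1]` with attribute `clipped` (count).
#' @export
normalize_g <- function(a_g) {
  if (any(!is.finite(a_g))) stopf("normalize_g: non-finite input")
  v <- (a_g + BAN_FULL_SCALE_G) / (2 * BAN_FULL_SCALE_G)
  clipped <- sum(v < 0 | v > 1)
  v <- pmin(pmax(v, 0), 1)
  attr(v, "clipped") <- clipped
  v
}

#' Module (Euclidean norm) of the 3-axis acceleration
#'
#' Computed on raw, un-normalized values in g; rotation invariant, which is
#' why sensor placement need not be precise.
#'
#' @param x Either an n x 3 matrix or the x component.
#' @param y,z Remaining components when `x` is a vector.
#' @return Magnitude in g.
#' @export
magnitude_g <- function(x, y = NULL, z = NULL) {
  if (is.matrix(x)) return(sqrt(rowSums(x^2)))
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stopf("magnitude_g: non-finite input")
  sqrt(x^2 + y^2 + z^2)
}

#' Grid packet streams onto the uniform sampling grid
#'
#' Places each sensor's packets at their grid position over
#' `[0, expected_span_ms]`; positions with no packet are `NA` and flagged in
#' the per-sensor `observed` mask. No interpolation happens here; see
#' [fill_gaps()].
#'
#' @param streams A [packet_stream()] or named list of them (a common
#'   expected span is enforced by taking the maximum).
#' @return Object of class `recording`: `fs`, `t0_s`, `n`, `t`, `sensors`
#'   (n x 3 matrices), `observed` / `filled` masks, `normalized` flag.
#' @export
as_recording <- function(streams) {
  if (inherits(streams, "packet_stream")) {
    streams <- stats::setNames(list(streams), streams$sensor_id)
  }
  iv <- streams[[1L]]$nominal_interval_ms
  span <- max(vapply(streams, `[[`, 0, "expected_span_ms"))
  n <- as.integer(span / iv) + 1L
  fs <- 1000 / iv
  sensors <- list(); observed <- list(); filled <- list()
  for (id in names(streams)) {
    s <- streams[[id]]
    validate_packet_stream(s)
    m <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
    idx <- as.integer(s$timestamp_ms / iv) + 1L
    ok <- idx <= n
    m[idx[ok], ] <- s$acc_g[ok, , drop = FALSE]
    sensors[[id]] <- m
    observed[[id]] <- !is.na(m[, 1L])
    filled[[id]] <- rep(FALSE, n)
  }
  structure(list(fs = fs, t0_s = 0, n = n, t = (seq_len(n) - 1L) / fs,
                 sensors = sensors, observed = observed, filled = filled,
                 normalized = FALSE),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d sensors, %d samples @ %.1f Hz (%.1f s), t0 = %.2f s\n",
              length(x$sensors), x$n, x$fs, x$n / x$fs, x$t0_s))
  invisible(x)
}

## Fill interior NA runs of length <= max_fill by linear interpolation;
## returns the matrix plus the filled mask.
fill_channel <- function(v, max_fill) {
  isna <- is.na(v)
  filled <- rep(FALSE, length(v))
  if (!any(isna)) return(list(v = v, filled = filled))
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    if (r$lengths[j] > max_fill) next
    a <- starts[j] - 1L; b <- ends[j] + 1L
    if (a < 1L || b > length(v)) next         # leading/trailing: never filled
    idx <- starts[j]:ends[j]
    v[idx] <- v[a] + (v[b] - v[a]) * (idx - a) / (b - a)
    filled[idx] <- TRUE
  }
  list(v = v, filled = filled)
}

#' Fill short gaps and split at long ones
#'
#' Gaps of at most `max_fill_samples` (default 4, i.e. one minimal 64 ms
#' reconnect burst) are linearly interpolated and masked as filled; longer
#' gaps are never fabricated: the recording is split into independent
#' gap-free segments at them. Observed samples are never altered.
#'
#' @param recording A [as_recording()] result.
#' @param max_fill_samples Longest gap (samples) that may be interpolated.
#' @param min_samples Shortest split segment worth keeping (default 64,
#'   about one second).
#' @return A single `recording` when no unfillable gap remains, otherwise a
#'   list of contiguous `recording` segments (possibly empty).
#' @export
fill_gaps <- function(recording, max_fill_samples = 4L, min_samples = 64L) {
  stopifnot(inherits(recording, "recording"))
  rec <- recording
  for (id in names(rec$sensors)) {
    for (c in 1:3) {
      fc <- fill_channel(rec$sensors[[id]][, c], max_fill_samples)
      rec$sensors[[id]][, c] <- fc$v
      if (c == 1L) rec$filled[[id]] <- fc$filled
    }
  }
  complete <- Reduce(`&`, lapply(rec$sensors, function(m) !is.na(m[, 1L])))
  if (all(complete)) return(rec)
  r <- rle(complete)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (j in which(r$values)) {
    if (r$lengths[j] < min_samples) next
    idx <- starts[j]:ends[j]
    seg <- rec
    seg$n <- length(idx)
    seg$t0_s <- rec$t0_s + (starts[j] - 1L) / rec$fs
    seg$t <- rec$t[idx]
    seg$sensors <- lapply(rec$sensors, function(m) m[idx, , drop = FALSE])
    seg$observed <- lapply(rec$observed, `[`, idx)
    seg$filled <- lapply(rec$filled, `[`, idx)
    segs[[length(segs) + 1L]] <- seg
  }
  segs
}

#' Convert a simulation directly to a recording (no loss, no gaps)
#'
#' @param sim A `gait_simulation` or `ban_session`.
#' @return A gap-free `recording`.
#' @export
as_recording_from_simulation <- function(sim) {
  n <- length(sim$t)
  structure(list(fs = sim$fs, t0_s = 0, n = n, t = sim$t,
                 sensors = sim$sensors,
                 observed = stats::setNames(
                   rep(list(rep(TRUE, n)), length(sim$sensors)),
                   names(sim$sensors)),
                 filled = stats::setNames(
                   rep(list(rep(FALSE, n)), length(sim$sensors)),
                   names(sim$sensors)),
                 normalized = FALSE),
            class = "recording")
}

#' Normalized copy of a recording (display/export convention)
#'
#' @param recording A `recording` with raw g channels.
#' @return The recording with channels mapped by [normalize_g()] and
#'   `normalized = TRUE`.
#' @export
normalize_recording <- function(recording) {
  stopifnot(inherits(recording, "recording"))
  if (recording$normalized) return(recording)
  recording$sensors <- lapply(recording$sensors, function(m) {
    ok <- is.finite(m)
    m[ok] <- (m[ok] + BAN_FULL_SCALE_G) / (2 * BAN_FULL_SCALE_G)
    m[ok] <- pmin(pmax(m[ok], 0), 1)
    m
  })
  recording$normalized <- TRUE
  recording
}

#' Three-panel plot of one sensor's normalized axes
#'
#' Reproduces the conventional display: x, y, z stacked, normalized to
#' `[0, 1]`, sample index on the horizontal axis.
#'
#' @param recording A `recording`.
#' @param sensor Sensor name (default belt).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_recording <- function(recording, sensor = "belt", ...) {
  rec <- normalize_recording(recording)
  m <- rec$sensors[[sensor]]
  old <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (c in 1:3)
    graphics::plot(m[, c], type = "l", ylim = c(0, 1), xlab = "sample",
                   ylab = paste0(colnames(m)[c], "-axis"), ...)
  invisible(recording)
}
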