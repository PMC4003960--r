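## Packet-stream I/O: the body-area-network data model and its CSV dialect.
## One row per packet: sensor_id, timestamp_ms, ax_g, ay_g, az_g. Timestamps
## are integer milliseconds on the 16 ms grid and unique per sensor.

#' Construct and validate a packet stream
#'
#' A packet stream is the raw unit of I/O: the time-ordered packets of one
#' sensor. Timestamps must be unique non-negative integer multiples of the
#' nominal 16 ms interval, and accelerations within the +/-6 g full scale.
#'
#' @param sensor_id One of belt, left_wrist, right_wrist, left_leg,
#'   right_leg.
#' @param timestamp_ms Integer milliseconds since session start.
#' @param acc_g n x 3 matrix (or data frame) of accelerations in g.
#' @param expected_span_ms Expected session span in ms (for loss accounting);
#'   defaults to the last timestamp.
#' @param nominal_interval_ms Grid step, 16 ms at 62.5 Hz.
#' @return An object of class `packet_stream`.
#' @export
packet_stream <- function(sensor_id, timestamp_ms, acc_g,
                          expected_span_ms = NULL,
                          nominal_interval_ms = BAN_INTERVAL_MS) {
  acc_g <- as.matrix(acc_g)
  if (ncol(acc_g) != 3L) stopf("acc_g must have three columns (x, y, z)")
  colnames(acc_g) <- c("x", "y", "z")
  ts <- as.numeric(timestamp_ms)
  if (length(ts) != nrow(acc_g))
    stopf("timestamp_ms and acc_g disagree in length")
  o <- order(ts)
  ts <- ts[o]
  acc_g <- acc_g[o, , drop = FALSE]
  if (is.null(expected_span_ms))
    expected_span_ms <- if (length(ts)) ts[length(ts)] else 0
  stream <- structure(list(sensor_id = as.character(sensor_id),
                           nominal_interval_ms = as.integer(nominal_interval_ms),
                           timestamp_ms = ts,
                           acc_g = acc_g,
                           expected_span_ms = as.numeric(expected_span_ms)),
                      class = "packet_stream")
  validate_packet_stream(stream)
  stream
}

validate_packet_stream <- function(stream) {
  ts <- stream$timestamp_ms
  iv <- stream$nominal_interval_ms
  if (any(!is.finite(ts)) || any(ts < 0))
    stopf("stream '%s': timestamps must be finite and >= 0", stream$sensor_id)
  if (any(ts %% iv != 0))
    stopf("stream '%s': timestamps must be integer multiples of %d ms",
          stream$sensor_id, iv)
  if (anyDuplicated(ts))
    stopf("stream '%s': duplicate timestamps: %s", stream$sensor_id,
          paste(head(unique(ts[duplicated(ts)]), 5L), collapse = ", "))
  if (any(abs(stream$acc_g) > BAN_FULL_SCALE_G + 1e-9, na.rm = TRUE))
    stopf("stream '%s': acceleration outside the +/-%g g full scale",
          stream$sensor_id, BAN_FULL_SCALE_G)
  invisible(stream)
}

#' @export
print.packet_stream <- function(x, ...) {
  cat(sprintf("<packet_stream> sensor %s: %d packets, span %.1f s (%d ms grid)\n",
              x$sensor_id, length(x$timestamp_ms),
              x$expected_span_ms / 1000, x$nominal_interval_ms))
  invisible(x)
}

expected_samples <- function(stream) {
  as.integer(stream$expected_span_ms / stream$nominal_interval_ms) + 1L
}

#' Write packet streams to the CSV interchange format
#'
#' One row per packet, columns `sensor_id,timestamp_ms,ax_g,ay_g,az_g`,
#' UTF-8, comma separated, dot decimal. Accelerations are written with 17
#' significant digits so a write/read round trip is bit-exact. A `.gz`
#' extension compresses transparently.
#'
#' @param streams A `packet_stream` or named list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_packet_csv <- function(streams, path) {
  if (inherits(streams, "packet_stream")) streams <- list(streams)
  rows <- lapply(streams, function(s) {
    validate_packet_stream(s)
    data.table::data.table(
      sensor_id = s$sensor_id,
      timestamp_ms = as.integer(s$timestamp_ms),
      ax_g = sprintf("%.17g", s$acc_g[, 1L]),
      ay_g = sprintf("%.17g", s$acc_g[, 2L]),
      az_g = sprintf("%.17g", s$acc_g[, 3L]))
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read packet streams from the CSV interchange format
#'
#' Splits rows by sensor, sorts by timestamp and validates the data model.
#' Rows with out-of-range accelerations, negative or off-grid timestamps are
#' dropped with a row-numbered warning; duplicated (sensor, timestamp) pairs
#' are an integrity error.
#'
#' @param path CSV file (optionally gzipped).
#' @param expected_span_ms Session span for loss accounting; defaults to the
#'   maximum timestamp observed across all sensors.
#' @return Named list of [packet_stream()] objects (possibly empty).
#' @export
read_packet_csv <- function(path, expected_span_ms = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- if (grepl("\\.gz$", path)) {
    ## base connections decompress transparently; fread would need R.utils
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    data.table::as.data.table(utils::read.csv(con,
                                              colClasses = c(sensor_id = "character")))
  } else {
    data.table::fread(path, colClasses = list(character = "sensor_id"))
  }
  required <- c("sensor_id", "timestamp_ms", "ax_g", "ay_g", "az_g")
  if (!all(required %in% names(dt)))
    stopf("format error: missing columns: %s",
          paste(setdiff(required, names(dt)), collapse = ", "))
  if (nrow(dt) == 0L) return(structure(list(), names = character(0)))
  dt$row <- seq_len(nrow(dt)) + 1L            # 1-based data rows after header
  bad <- !is.finite(dt$timestamp_ms) | dt$timestamp_ms < 0 |
    (dt$timestamp_ms %% BAN_INTERVAL_MS != 0) |
    !is.finite(dt$ax_g) | !is.finite(dt$ay_g) | !is.finite(dt$az_g) |
    pmax(abs(dt$ax_g), abs(dt$ay_g), abs(dt$az_g)) > BAN_FULL_SCALE_G + 1e-9
  if (any(bad)) {
    warnf("dropping %d invalid row(s): %s", sum(bad),
          paste(head(dt$row[bad], 10L), collapse = ", "))
    dt <- dt[!bad, ]
  }
  if (nrow(dt) == 0L) return(structure(list(), names = character(0)))
  dup <- duplicated(dt[, c("sensor_id", "timestamp_ms")])
  if (any(dup)) {
    d <- dt[dup, ]
    stopf("integrity error: duplicate (sensor, timestamp) at rows %s",
          paste(head(d$row, 10L), collapse = ", "))
  }
  if (is.null(expected_span_ms)) expected_span_ms <- max(dt$timestamp_ms)
  ids <- unique(dt$sensor_id)
  ids <- ids[order(match(ids, BAN_SENSORS, nomatch = NA), ids)]
  streams <- lapply(ids, function(id) {
    sub <- dt[dt$sensor_id == id, ]
    packet_stream(id, sub$timestamp_ms,
                  cbind(sub$ax_g, sub$ay_g, sub$az_g),
                  expected_span_ms = expected_span_ms)
  })
  names(streams) <- ids
  streams
}
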