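## Pipeline orchestration: simulate -> read -> QC -> trim -> preprocess ->
## segment -> features, driven by a JSON-serialisable run configuration so
## any reported number is reproducible from the config and seed alone.

#' Published per-patient data-loss statistics for the five-sensor network
#'
#' Field-deployment summary of the wireless accelerometer network in 11
#' patients' homes: mean +/- sd data loss per patient, mean +/- sd burst
#' length and the most frequent burst length (64 ms, the logger reconnect
#' minimum, in every patient). Used to parameterise realistic synthetic
#' loss models.
#'
#' @return Data frame with columns `id`, `loss_mean_percent`,
#'   `loss_sd_percent`, `burst_mean_ms`, `burst_sd_ms`, `burst_modal_ms`.
#' @export
deployment_loss_stats <- function() {
  utils::read.csv(system.file("extdata", "deployment_loss_stats.csv",
                              package = "pdgait"))
}

#' Run configuration
#'
#' A fully serialisable description of one pipeline run. Either `input`
#' (packet CSV path) or `simulate` (list: `profile`, `schedule` as a data
#' frame or list, `loss`) must be given.
#'
#' @param input Packet CSV path, or `NULL` to simulate.
#' @param simulate List with `profile`, `schedule`, `loss` specs.
#' @param seed Integer master seed.
#' @param leg_length_m Subject pendulum length (required for stride length).
#' @param qc List: `window_s`, `stable_s`.
#' @param segmentation List: `window_s`, `overlap`, `min_duration_s`,
#'   `max_gap_windows`, `sensors`.
#' @param features List: `sampen_m`, `sampen_r`, `sensor`.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL, seed = 1L,
                       leg_length_m = 0.95,
                       qc = list(window_s = 60, stable_s = 10),
                       segmentation = list(window_s = 2.56, overlap = 0.5,
                                           min_duration_s = 10,
                                           max_gap_windows = 1,
                                           sensors = c("left_leg",
                                                       "right_leg")),
                       features = list(sampen_m = 2, sampen_r = 0.2,
                                       sensor = "belt"),
                       out_dir = NULL) {
  if (is.null(input) && is.null(simulate))
    stopf("run_config: either 'input' or 'simulate' must be given")
  structure(list(input = input, simulate = simulate, seed = as.integer(seed),
                 leg_length_m = leg_length_m, qc = qc,
                 segmentation = segmentation, features = features,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with the [run_config()] fields.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- run_config(simulate = list())
  for (nm in c("qc", "segmentation", "features"))
    cfg[[nm]] <- utils::modifyList(defaults[[nm]],
                                   as.list(cfg[[nm]] %||% list()))
  do.call(run_config, cfg[intersect(names(cfg), names(defaults))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_from_config <- function(cfg) {
  spec <- cfg$simulate
  profile <- if (is.null(spec$profile)) healthy_profile()
             else do.call(gait_profile, as.list(spec$profile))
  schedule <- if (is.null(spec$schedule))
    activity_schedule(0, 600, "walking")
  else if (inherits(spec$schedule, "activity_schedule")) spec$schedule
  else do.call(activity_schedule, as.list(spec$schedule))
  sess <- simulate_session(schedule, profile, seed = cfg$seed)
  loss <- if (is.null(spec$loss)) loss_model(seed = cfg$seed + 1L)
          else do.call(loss_model, utils::modifyList(as.list(spec$loss),
                                                     list(seed = cfg$seed + 1L)))
  lost <- apply_loss_model(sess, loss)
  list(session = sess, streams = lost$streams, dropped = lost$dropped)
}

#' Run the full analysis pipeline
#'
#' Simulates or reads packet streams, computes the per-sensor transmission
#' QC report (with start-up trimming), grids and gap-fills the signals,
#' segments walking bouts from the leg sensors and computes the gait
#' feature set per bout. When `out_dir` is set, writes `qc.json`,
#' `qc.csv`, `segments.csv`, `features.csv` and `manifest.json`.
#'
#' @param config A [run_config()] (or path to a JSON config).
#' @return List of class `pipeline_result`: `qc`, `segments`, `features`,
#'   `manifest`, `qc_pass`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  streams <- if (!is.null(config$input)) read_packet_csv(config$input)
             else simulate_from_config(config)$streams
  qc <- qc_report(streams, window_s = config$qc$window_s,
                  stable_s = config$qc$stable_s)
  usable <- qc$trimmed
  ## only the sensors the analysis consumes should force splits at gaps
  needed <- unique(c(config$segmentation$sensors, config$features$sensor))
  usable <- usable[intersect(names(usable), needed)]
  segments <- list(); features <- list()
  if (length(usable)) {
    rec <- as_recording(usable)
    pieces <- fill_gaps(rec)
    if (inherits(pieces, "recording")) pieces <- list(pieces)
    for (piece in pieces) {
      segs <- segment_walking(
        piece, window_s = config$segmentation$window_s,
        overlap = config$segmentation$overlap,
        sensors = config$segmentation$sensors,
        min_duration_s = config$segmentation$min_duration_s,
        max_gap_windows = config$segmentation$max_gap_windows)
      if (nrow(segs) == 0L) next
      segments[[length(segments) + 1L]] <- segs
      for (i in seq_len(nrow(segs)))
        features[[length(features) + 1L]] <-
          gait_features(piece, segs[i, ], config$leg_length_m,
                        sampen_m = config$features$sampen_m,
                        sampen_r = config$features$sampen_r,
                        sensor = config$features$sensor)
    }
  }
  segments <- if (length(segments)) do.call(rbind, segments)
              else merge_windows(data.frame(), logical(0))
  features <- if (length(features)) do.call(rbind, features)
              else gait_features_empty()
  if (nrow(features) == 0L)
    warnf("run produced no walking segments / gait features")
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("pdgait")),
                   r_version = R.version.string,
                   config = unclass(config))
  result <- structure(list(qc = qc, segments = segments, features = features,
                           manifest = manifest,
                           qc_pass = any(qc$per_sensor$qc_pass)),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

gait_features_empty <- function() {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    n_steps = integer(0), sample_entropy = numeric(0),
                    step_frequency_hz = numeric(0),
                    stride_time_cv = numeric(0),
                    stride_length_m = numeric(0), velocity_m_s = numeric(0),
                    n_steps_dropped = integer(0),
                    velocity_consistent = logical(0),
                    skipped_reason = character(0))
  class(out) <- c("gait_features", "data.frame")
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  jsonlite::write_json(list(per_sensor = result$qc$per_sensor,
                            pooled = result$qc$pooled),
                       p("qc.json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  utils::write.csv(result$qc$per_sensor, p("qc.csv"), row.names = FALSE)
  utils::write.csv(result$segments, p("segments.csv"), row.names = FALSE)
  utils::write.csv(result$features, p("features.csv"), row.names = FALSE)
  cfg_json <- jsonlite::toJSON(result$manifest$config, auto_unbox = TRUE,
                               digits = NA, null = "null")
  cfg_path <- p("config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- result$manifest
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' Compare gait-feature distributions between two cohorts
#'
#' Descriptive per-feature mean/sd/median per cohort; no hypothesis test is
#' performed or implied.
#'
#' @param a,b `gait_features` tables (e.g. from [run_pipeline()]).
#' @param names Cohort names.
#' @return Data frame with one row per (cohort, feature); cohorts with no
#'   usable segments are flagged via the `empty` attribute, single-segment
#'   cohorts report `NA` sd.
#' @export
compare_cohorts <- function(a, b, names = c("A", "B")) {
  feats <- c("sample_entropy", "step_frequency_hz", "stride_time_cv",
             "stride_length_m", "velocity_m_s")
  one <- function(tab, nm) {
    if ("skipped_reason" %in% names(tab))
      tab <- tab[is.na(tab$skipped_reason), , drop = FALSE]
    do.call(rbind, lapply(feats, function(f) {
      v <- tab[[f]][is.finite(tab[[f]])]
      data.frame(cohort = nm, feature = f, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                 median = if (length(v)) stats::median(v) else NA_real_)
    }))
  }
  out <- rbind(one(a, names[1L]), one(b, names[2L]))
  attr(out, "empty") <- names[c(nrow(a) == 0L, nrow(b) == 0L)]
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic session's packet CSV and
#' ground truth), `qc` (QC report for a packet CSV), `analyze` (full
#' pipeline), `compare` (two feature CSVs). Flags: `--config <json>`,
#' `--seed <int>`, `--out <dir>`, `--in <csv>`, `--leg-length <m>`.
#' Config-file values win over flags, with a notice.
#'
#' @param args Character vector (default: the command line).
#' @return Exit status, invisibly.
#' @export
pdgait_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: pdgait <simulate|qc|analyze|compare> [--config cfg.json]",
            " [--seed N] [--out dir] [--in packets.csv] [--leg-length m]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- if (i + 1L <= length(args)) args[i + 1L] else NA
    i <- i + 2L
  }
  seed <- as.integer(opt$seed %||% 1L)
  out_dir <- opt$out %||% "."
  cfg <- NULL
  if (!is.null(opt$config)) {
    cfg <- read_run_config(opt$config)
    if (!is.null(opt$seed) && cfg$seed != seed)
      message("note: config file seed overrides --seed")
    seed <- cfg$seed
  }
  status <- 0L
  switch(cmd,
    simulate = {
      if (is.null(cfg)) cfg <- run_config(simulate = list(), seed = seed)
      sim <- simulate_from_config(cfg)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_packet_csv(sim$streams, file.path(out_dir, "packets.csv"))
      truth <- list(
        step_times = lapply(sim$session$truth$walking, `[[`, "step_times"),
        step_lengths_m = lapply(sim$session$truth$walking,
                                `[[`, "step_lengths_m"),
        dropped = sim$dropped,
        labels = rle(sim$session$labels)[c("lengths", "values")])
      jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      message("wrote ", file.path(out_dir, "packets.csv"))
    },
    qc = {
      streams <- read_packet_csv(opt[["in"]])
      rep <- qc_report(streams)
      print(rep)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(list(per_sensor = rep$per_sensor,
                                pooled = rep$pooled),
                           file.path(out_dir, "qc.json"), auto_unbox = TRUE,
                           digits = NA, na = "null")
      if (!any(rep$per_sensor$qc_pass)) status <- 1L
    },
    analyze = {
      if (is.null(cfg)) {
        if (is.null(opt[["in"]])) stopf("analyze needs --in or --config")
        cfg <- run_config(input = opt[["in"]], seed = seed,
                          leg_length_m = as.numeric(opt[["leg-length"]] %||%
                                                      0.95))
      }
      cfg$out_dir <- out_dir
      res <- run_pipeline(cfg)
      if (!res$qc_pass) status <- 1L
      message("wrote pipeline outputs to ", out_dir)
    },
    compare = {
      a <- utils::read.csv(opt$a)
      b <- utils::read.csv(opt$b)
      print(compare_cohorts(a, b))
    },
    stopf("unknown subcommand '%s'", cmd))
  invisible(status)
}
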