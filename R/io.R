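#' Read a recording from disk
#'
#' CSV layout: header `time_s,current_pA`, one row per sample. Sampling
#' uniformity is validated (maximum deviation of the time step from its
#' median below 1%). The `.h5` extension is recognised but not supported
#' by this build; convert to CSV.
#'
#' @param path File path; format inferred from the extension.
#' @return An [mea_ts] current trace (pA).
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5"))
    stop("HDF5 input is not supported by this build; ",
         "supply a CSV with columns time_s,current_pA", call. = FALSE)
  if (ext != "csv")
    stop("unrecognised recording format '.", ext, "'", call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(df)))
    stop("CSV must contain columns time_s and current_pA", call. = FALSE)
  if (nrow(df) < 2L) stop("recording has fewer than 2 samples",
                          call. = FALSE)
  dts <- diff(df$time_s)
  if (any(dts <= 0))
    stop("time column must be strictly increasing", call. = FALSE)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 0.01 * dt)
    stop("non-uniform sampling: time-step jitter exceeds 1%", call. = FALSE)
  mea_ts(df$current_pA, dt = dt, t0 = df$time_s[1], unit = "current")
}

#' Write a recording to CSV
#'
#' Values are written with 17 significant digits so a write-read
#' round-trip reproduces the samples exactly.
#'
#' @param rec An [mea_ts] current trace.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  .assert_ts(rec, unit = "current")
  lines <- c("time_s,current_pA",
             paste(sprintf("%.17g", ts_time(rec)),
                   sprintf("%.17g", rec$values), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a detected-event table to CSV
#'
#' @param events Events data frame (see [detect_spikes()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read a detected-event table from CSV
#'
#' @param path CSV path written by [write_events()].
#' @return An `mea_events` data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peak_time_s", "amplitude_pA", "width_s", "polarity")
  if (!all(need %in% names(df)))
    stop("events CSV must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(df$kind)) df$kind <- NA_character_
  if (is.null(df$pair_id)) df$pair_id <- NA_integer_
  class(df) <- c("mea_events", "data.frame")
  df
}

#' Read phase annotations from CSV
#'
#' Columns: `label`, `start_s`, `end_s`.
#'
#' @param path CSV path.
#' @return A validated phase data frame.
#' @export
read_phases <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert_phases(df)
  df
}

#' Assemble and validate a pipeline configuration
#'
#' Accepts a nested list or the path of a YAML file with blocks
#' `recording`, `schedule`, `async`, `sync`, `wave`, `detection`,
#' `segmentation`, `inhibition`, `circuit` and a top-level `seed`.
#' Unknown block or field names are rejected; every field maps onto the
#' argument of the corresponding constructor and carries its units.
#'
#' @param x A list or a YAML file path.
#' @return A list of class `mea_config` with constructed parameter
#'   objects (`recording`, `async`, `sync`, `detection`, ...) plus
#'   `schedule` and `seed`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("config must be a list or YAML path", call. = FALSE)
  known <- c("recording", "schedule", "async", "sync", "wave",
             "detection", "segmentation", "inhibition", "circuit",
             "seed", "input")
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  build <- function(block, ctor, rename = NULL) {
    args <- x[[block]]
    if (is.null(args)) args <- list()
    if (!is.null(rename)) {
      hit <- names(args) %in% names(rename)
      names(args)[hit] <- rename[names(args)[hit]]
    }
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop(sprintf("unknown key(s) in `%s`: %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    do.call(ctor, args)
  }
  rec_args <- x$recording
  if (is.null(rec_args)) rec_args <- list()
  if (is.null(rec_args$duration)) {
    if (!is.null(x$schedule)) {
      rec_args$duration <- sum(vapply(x$schedule,
                                      function(s) s$duration, numeric(1)))
    } else if (!is.null(x$inhibition)) {
      ip <- build("inhibition", inhibition_protocol)
      rec_args$duration <- ip$pre_duration + ip$block_duration +
        ip$post_duration
    } else stop("recording duration missing", call. = FALSE)
  }
  if (is.null(rec_args$seed) && !is.null(x$seed))
    rec_args$seed <- x$seed
  x$recording <- rec_args
  schedule <- NULL
  if (!is.null(x$schedule)) {
    schedule <- do.call(rbind, lapply(x$schedule, function(s) {
      data.frame(regime = s$regime, duration = s$duration,
                 stringsAsFactors = FALSE)
    }))
  }
  seg_defaults <- list(window = 30, rate_cutoff = 0.2, cv_cutoff = 0.6)
  seg <- x$segmentation
  if (is.null(seg)) seg <- list()
  bad <- setdiff(names(seg), names(seg_defaults))
  if (length(bad))
    stop("unknown key(s) in `segmentation`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  seg <- utils::modifyList(seg_defaults, seg)
  cfg <- list(
    recording = build("recording", recording_config),
    schedule = schedule,
    async = build("async", async_params),
    sync = build("sync", sync_params),
    wave = if (is.null(x$wave)) NULL else build("wave", wave_params),
    detection = build("detection", detection_config,
                      rename = c(threshold_pA = "threshold",
                                 refractory_s = "refractory",
                                 pairing_window_s = "pairing_window")),
    segmentation = seg,
    inhibition = if (is.null(x$inhibition)) NULL
                 else build("inhibition", inhibition_protocol),
    circuit = build("circuit", circuit_params),
    seed = x$seed,
    input = x$input)
  class(cfg) <- "mea_config"
  cfg
}

# Tiny polynomial content hash used to stamp outputs with their provenance.
.config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
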