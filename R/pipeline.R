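#' Run the full analysis pipeline
#'
#' Simulates (or loads) a recording, detects and pairs spikes, segments
#' regimes, computes per-regime statistics, and — when the configuration
#' carries an inhibition protocol — quantifies block and recovery.
#' Optionally writes the event table (CSV), statistics and report (JSON)
#' and publication-style figures (PDF) into `out_dir`; every output file
#' carries the seed and a configuration hash. The run is deterministic
#' given a fixed configuration and seed.
#'
#' @param config A [pipeline_config()] object, a list, or a YAML path.
#' @param out_dir Optional output directory (created if missing).
#' @param plots Write figures (trace, zoomed spike, amplitude/width/ISI
#'   histograms, phase-count bars) into `out_dir`? Ignored without
#'   `out_dir`.
#' @param verbose Log per-stage event counts?
#' @return A list of class `mea_report`: `recording`, `truth`, `events`,
#'   `segments`, `stats`, `wave_speed`, optionally `phases` and
#'   `inhibition`, plus `seed` and `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, plots = FALSE,
                         verbose = FALSE) {
  if (!inherits(config, "mea_config")) config <- pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL; phases <- NULL
  if (!is.null(config$input)) {
    rec <- stage("load", read_recording(config$input))
    say("loaded %d samples from %s", length(rec$values), config$input)
  } else if (!is.null(config$inhibition)) {
    sim <- stage("simulate",
                 simulate_inhibition_experiment(config$recording,
                                                config$inhibition,
                                                sync = config$sync))
    rec <- sim$recording; truth <- sim$truth; phases <- sim$phases
    say("simulated inhibition experiment: %d ground-truth lobes",
        nrow(truth))
  } else {
    schedule <- config$schedule
    if (is.null(schedule))
      schedule <- data.frame(regime = "synchronous",
                             duration = config$recording$duration)
    sim <- stage("simulate",
                 simulate_recording(config$recording, schedule,
                                    async = config$async,
                                    sync = config$sync,
                                    wave = config$wave))
    rec <- sim$recording; truth <- sim$truth
    say("simulated recording: %d ground-truth lobes", nrow(truth))
  }

  events <- stage("detect", {
    ev <- detect_spikes(rec, config$detection)
    pair_biphasic(ev, config$detection)
  })
  say("detected %d events (%d biphasic lobes)", nrow(events),
      sum(events$kind == "biphasic", na.rm = TRUE))

  span <- c(rec$t0, rec$t0 + length(rec$values) * rec$dt)
  seg <- config$segmentation
  segments <- stage("characterize",
                    segment_regimes(events, span, window = seg$window,
                                    rate_cutoff = seg$rate_cutoff,
                                    cv_cutoff = seg$cv_cutoff))
  stats <- stage("characterize", spike_statistics(events, segments))
  wave <- if (any(!is.na(events$pair_id))) {
    diam <- if (!is.null(config$wave)) config$wave$electrode_diameter
            else wave_params()$electrode_diameter
    estimate_wave_speed(events, diam)
  } else NULL

  inhibition <- NULL
  if (!is.null(phases)) {
    inhibition <- stage("inhibition", {
      counts <- phase_spike_counts(events, phases)
      mags <- vapply(seq_len(nrow(phases)), function(k) {
        fluctuation_magnitude(rec, phases[k, ])
      }, numeric(1))
      names(mags) <- phases$label
      assess_block(counts, mags)
    })
    say("inhibition: block %s, recovery %s", inhibition$block_called,
        inhibition$recovery_called)
  }

  report <- structure(
    list(recording = rec, truth = truth, events = events,
         segments = segments, stats = stats, wave_speed = wave,
         phases = phases, inhibition = inhibition,
         seed = config$recording$seed, config_hash = .config_hash(config)),
    class = "mea_report")

  if (!is.null(out_dir)) .write_report_bundle(report, config, out_dir,
                                              plots = plots)
  report
}

.write_report_bundle <- function(report, config, out_dir, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  written <- character(0)
  on.exit(if (!ok) unlink(written), add = TRUE)
  meta <- list(seed = report$seed, config_hash = report$config_hash)

  ev_path <- file.path(out_dir, "events.csv")
  write_events(report$events, ev_path)
  written <- c(written, ev_path)

  stats_path <- file.path(out_dir, "stats.json")
  jsonlite::write_json(c(meta, list(stats = report$stats)), stats_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  written <- c(written, stats_path)

  rep_path <- file.path(out_dir, "report.json")
  summary <- list(
    n_events = nrow(report$events),
    n_biphasic_pairs = sum(!is.na(report$events$pair_id)) %/% 2L,
    segments = as.data.frame(report$segments),
    median_wave_speed_um_s = if (is.null(report$wave_speed)) NULL
                             else report$wave_speed$median_um_s)
  if (!is.null(report$inhibition)) {
    summary$inhibition <- list(
      counts = as.list(report$inhibition$counts),
      magnitudes_pA = as.list(report$inhibition$magnitudes),
      block_called = report$inhibition$block_called,
      recovery_called = report$inhibition$recovery_called)
  }
  jsonlite::write_json(c(meta, summary), rep_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  written <- c(written, rep_path)

  if (plots) {
    fig_path <- file.path(out_dir, "figures.pdf")
    grDevices::pdf(fig_path, width = 7, height = 5)
    tryCatch(.report_figures(report), finally = grDevices::dev.off())
    written <- c(written, fig_path)
  }
  ok <- TRUE
  invisible(written)
}

.report_figures <- function(report) {
  plot(report$recording, main = "Recorded current")
  if (nrow(report$events)) {
    ev <- report$events
    k <- which.max(abs(ev$amplitude_pA))
    t0 <- ev$peak_time_s[k]
    zoom <- ts_window(report$recording, max(report$recording$t0, t0 - 2),
                      t0 + 2)
    plot(zoom, main = "Zoomed spike")
    graphics::hist(abs(ev$amplitude_pA), breaks = c(0, seq(50, 350, 50),
                                                    max(400, max(abs(ev$amplitude_pA)))),
                   xlab = "|amplitude| (pA)", main = "Spike amplitudes")
    graphics::hist(ev$width_s, breaks = 20, xlab = "width (s)",
                   main = "Spike widths")
    on <- event_onsets(ev)
    if (length(on) > 2)
      graphics::hist(diff(on), breaks = seq(0, ceiling(max(diff(on))), 1),
                     xlab = "inter-spike interval (s)", main = "ISIs")
  }
  if (!is.null(report$inhibition)) {
    graphics::barplot(report$inhibition$counts,
                      ylab = "spike count",
                      main = "Spikes before / during / after inhibitor")
  }
  invisible(NULL)
}

#' @export
print.mea_report <- function(x, ...) {
  cat("<mea_report>\n")
  cat(sprintf("  seed %s, config %s\n",
              if (is.null(x$seed)) "unset" else x$seed, x$config_hash))
  print(x$recording)
  cat(sprintf("  %d detected events; %d segments\n", nrow(x$events),
              nrow(x$segments)))
  if (!is.null(x$wave_speed) && x$wave_speed$n_pairs > 0)
    cat(sprintf("  median wave speed %.4g um/s (%d pairs)\n",
                x$wave_speed$median_um_s, x$wave_speed$n_pairs))
  if (!is.null(x$inhibition)) print(x$inhibition)
  invisible(x)
}
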