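#' Recording configuration for the synthetic generator
#'
#' @param duration Recording length in seconds.
#' @param sampling_rate Sampling rate in Hz. The default 1 kHz oversamples
#'   the 0.1-10 Hz activity band and the shortest (30 ms) spike widths by a
#'   wide margin.
#' @param seed Integer seed; every simulator call that receives a config
#'   with a non-`NULL` seed is fully reproducible.
#' @param baseline_noise_pp Peak-to-peak span of the medium-only baseline
#'   noise in pA. Medium-only recordings on this class of system stay below
#'   1 pA, so the default span is 0.8 pA; the generator hard-bounds noise
#'   samples at half the span on either side of zero so the configured
#'   peak-to-peak is never exceeded.
#'
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(duration, sampling_rate = 1000, seed = NULL,
                             baseline_noise_pp = 0.8) {
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be positive (seconds)", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be positive (Hz)", call. = FALSE)
  if (baseline_noise_pp < 0)
    stop("`baseline_noise_pp` must be >= 0", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 seed = seed, baseline_noise_pp = baseline_noise_pp),
            class = "recording_config")
}

#' Asynchronous-sporadic regime parameters
#'
#' Basal uncorrelated single-cell activity: sporadic unipolar spikes of
#' roughly 100 pA, mostly negative, with widths mostly between 30 and
#' 200 ms. Widths are drawn log-uniformly; the default bounds put about
#' 80% of draws inside 30-200 ms.
#'
#' @param event_rate Poisson event rate (events/s).
#' @param amplitude_mean,amplitude_sd Normal parameters of the absolute
#'   spike amplitude (pA).
#' @param width_low,width_high Log-uniform width bounds (s).
#' @param negative_polarity_prob Probability that a spike is negative.
#' @return An object of class `async_params`.
#' @export
async_params <- function(event_rate = 0.1, amplitude_mean = 100,
                         amplitude_sd = 30, width_low = 0.02,
                         width_high = 0.22, negative_polarity_prob = 0.7) {
  if (event_rate < 0) stop("`event_rate` must be >= 0", call. = FALSE)
  if (width_low <= 0 || width_low >= width_high)
    stop("need 0 < width_low < width_high", call. = FALSE)
  if (negative_polarity_prob < 0 || negative_polarity_prob > 1)
    stop("`negative_polarity_prob` must lie in [0, 1]", call. = FALSE)
  structure(list(event_rate = event_rate, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, width_low = width_low,
                 width_high = width_high,
                 negative_polarity_prob = negative_polarity_prob),
            class = "async_params")
}

#' Quasi-periodic biphasic regime parameters
#'
#' Collaborative population activity: biphasic spikes of about +/-150 pA,
#' widths 50-300 ms, a positive-to-negative lobe separation of about
#' 0.3 s, and inter-spike intervals around 2 s (spike rate near 0.5 Hz).
#' ISIs are drawn from a Normal truncated to `isi_clip` (default 1-10 s,
#' the observed spread of intervals between biphasic spikes).
#'
#' @param mean_isi Mean inter-spike interval between biphasic events (s).
#' @param isi_jitter_sd ISI standard deviation before truncation (s).
#' @param amplitude Lobe amplitude (pA); lobes are +amplitude then
#'   -amplitude.
#' @param width_low,width_high Log-uniform lobe width bounds (s).
#' @param biphasic_separation Positive-to-negative lobe peak separation (s),
#'   used when no wave parameters are supplied.
#' @param isi_clip Length-2 truncation bounds for the ISI draw (s).
#' @return An object of class `sync_params`.
#' @export
sync_params <- function(mean_isi = 2, isi_jitter_sd = 1, amplitude = 150,
                        width_low = 0.05, width_high = 0.3,
                        biphasic_separation = 0.3, isi_clip = c(1, 10)) {
  if (amplitude <= 0) stop("`amplitude` must be positive", call. = FALSE)
  if (mean_isi <= biphasic_separation)
    stop("`mean_isi` must exceed `biphasic_separation`", call. = FALSE)
  if (width_low <= 0 || width_low >= width_high)
    stop("need 0 < width_low < width_high", call. = FALSE)
  if (length(isi_clip) != 2L || isi_clip[1] <= 0 || isi_clip[1] >= isi_clip[2])
    stop("`isi_clip` must be increasing positive bounds", call. = FALSE)
  structure(list(mean_isi = mean_isi, isi_jitter_sd = isi_jitter_sd,
                 amplitude = amplitude, width_low = width_low,
                 width_high = width_high,
                 biphasic_separation = biphasic_separation,
                 isi_clip = isi_clip),
            class = "sync_params")
}

#' Traveling-wave geometry parameters
#'
#' A slow extracellular wave crossing the electrode produces the biphasic
#' spike: an upward lobe as it enters and a downward lobe as it leaves, so
#' the lobe separation is the electrode diameter divided by the wave speed.
#' The diameter is derived from the (circular) electrode area.
#'
#' @param wave_speed Wave propagation speed (um/s).
#' @param electrode_area Electrode area (mm^2); default 1 mm^2.
#' @return An object of class `wave_params` with the derived
#'   `electrode_diameter` (mm).
#' @examples
#' wave_params(500)$electrode_diameter   # 1.128 mm for a 1 mm^2 disc
#' @export
wave_params <- function(wave_speed = 500, electrode_area = 1) {
  if (wave_speed <= 0) stop("`wave_speed` must be positive", call. = FALSE)
  if (electrode_area <= 0)
    stop("`electrode_area` must be positive", call. = FALSE)
  diameter <- 2 * sqrt(electrode_area / pi)
  structure(list(wave_speed = wave_speed, electrode_area = electrode_area,
                 electrode_diameter = diameter),
            class = "wave_params")
}

#' Three-phase calcium-channel inhibition protocol
#'
#' Normal activity, an inhibitor-block phase in which spiking collapses to
#' small residual fluctuations, and a recovered phase after wash-out with
#' fresh medium. In the reference experiment the inhibitor was present for
#' about 20 minutes and block-phase fluctuations stayed under 5 pA; the
#' default residual span of 4 pA keeps simulated block phases strictly
#' inside that bound.
#'
#' @param pre_duration,block_duration,post_duration Phase lengths (s).
#' @param residual_amplitude Peak magnitude bound of residual block-phase
#'   fluctuations (pA); must stay below any detection threshold in use.
#' @return An object of class `inhibition_protocol`.
#' @export
inhibition_protocol <- function(pre_duration = 600, block_duration = 1200,
                                post_duration = 600,
                                residual_amplitude = 4) {
  durs <- c(pre_duration, block_duration, post_duration)
  if (any(durs <= 0)) stop("all phase durations must be positive",
                           call. = FALSE)
  if (residual_amplitude < 0)
    stop("`residual_amplitude` must be >= 0", call. = FALSE)
  structure(list(pre_duration = pre_duration,
                 block_duration = block_duration,
                 post_duration = post_duration,
                 residual_amplitude = residual_amplitude),
            class = "inhibition_protocol")
}

# ---- internal building blocks -------------------------------------------

# Quantile-calibrated bounded Gaussian noise: sd chosen so the theoretical
# 0.01-99.99 percentile span equals `pp`, then hard-bounded at +/- pp/2 so
# the realised peak-to-peak never exceeds the configured span (the bound
# touches ~0.02% of samples).
.baseline_noise <- function(n, pp) {
  if (pp <= 0) return(numeric(n))
  sd <- pp / (2 * stats::qnorm(0.9999))
  pmin(pmax(stats::rnorm(n, 0, sd), -pp / 2), pp / 2)
}

# Gaussian lobe width convention: the drawn width is the full width at the
# 50 pA analysis threshold when the lobe clears it comfortably, and the
# FWHM otherwise, so detector-measured widths match ground truth.
.lobe_sigma <- function(width, amp_pA, ref_pA = 50) {
  a <- abs(amp_pA)
  if (a > 1.1 * ref_pA)
    width / (2 * sqrt(2 * log(a / ref_pA)))
  else
    width / (2 * sqrt(2 * log(2)))
}

# Add one Gaussian lobe (evaluated to +/- 5 sigma) into `vals` in place.
.add_lobe <- function(vals, fs, center, amp, sigma) {
  n <- length(vals)
  i1 <- max(1L, floor((center - 5 * sigma) * fs) + 1L)
  i2 <- min(n, ceiling((center + 5 * sigma) * fs) + 1L)
  if (i2 < i1) return(vals)
  tt <- (seq.int(i1, i2) - 1L) / fs
  vals[i1:i2] <- vals[i1:i2] + amp * exp(-(tt - center)^2 / (2 * sigma^2))
  vals
}

# Truncated-normal ISI by rejection; degenerate sd returns the clipped mean.
.draw_isi <- function(sync) {
  if (sync$isi_jitter_sd <= 0)
    return(min(max(sync$mean_isi, sync$isi_clip[1]), sync$isi_clip[2]))
  repeat {
    x <- stats::rnorm(1, sync$mean_isi, sync$isi_jitter_sd)
    if (x >= sync$isi_clip[1] && x <= sync$isi_clip[2]) return(x)
  }
}

.truth_row <- function(time, amp, width, kind, regime, event_id) {
  data.frame(time_s = time, amplitude_pA = amp, width_s = width,
             polarity = ifelse(amp < 0, "-", "+"), kind = kind,
             regime = regime, event_id = event_id,
             stringsAsFactors = FALSE)
}

.empty_truth <- function() {
  data.frame(time_s = numeric(0), amplitude_pA = numeric(0),
             width_s = numeric(0), polarity = character(0),
             kind = character(0), regime = character(0),
             event_id = integer(0), stringsAsFactors = FALSE)
}

# Poisson unipolar events inside [t_start, t_end); margin keeps lobe
# support inside the segment.
.gen_async_events <- function(t_start, t_end, pars, regime = "asynchronous") {
  dur <- t_end - t_start
  n_ev <- stats::rpois(1, pars$event_rate * dur)
  if (n_ev == 0) return(.empty_truth())
  margin <- pars$width_high
  times <- sort(stats::runif(n_ev, t_start + margin,
                             max(t_start + margin, t_end - margin)))
  mag <- abs(stats::rnorm(n_ev, pars$amplitude_mean, pars$amplitude_sd))
  sgn <- ifelse(stats::runif(n_ev) < pars$negative_polarity_prob, -1, 1)
  width <- exp(stats::runif(n_ev, log(pars$width_low), log(pars$width_high)))
  .truth_row(times, sgn * mag, width, "unipolar", regime, NA_integer_)
}

# Quasi-periodic biphasic trains: +lobe then -lobe `sep` apart, onsets
# advancing by truncated-normal ISIs.
.gen_sync_events <- function(t_start, t_end, sync, sep,
                             regime = "synchronous") {
  margin <- 4 * .lobe_sigma(sync$width_high, sync$amplitude)
  t <- t_start + margin + stats::runif(1, 0, sync$mean_isi)
  rows <- list()
  while (t + sep + margin < t_end) {
    w1 <- exp(stats::runif(1, log(sync$width_low), log(sync$width_high)))
    w2 <- exp(stats::runif(1, log(sync$width_low), log(sync$width_high)))
    rows[[length(rows) + 1L]] <- .truth_row(
      c(t, t + sep), c(sync$amplitude, -sync$amplitude), c(w1, w2),
      "biphasic", regime, NA_integer_)
    t <- t + .draw_isi(sync)
  }
  if (!length(rows)) return(.empty_truth())
  do.call(rbind, rows)
}

.insert_events <- function(vals, fs, truth) {
  if (nrow(truth)) {
    for (k in seq_len(nrow(truth))) {
      sigma <- .lobe_sigma(truth$width_s[k], truth$amplitude_pA[k])
      vals <- .add_lobe(vals, fs, truth$time_s[k], truth$amplitude_pA[k],
                        sigma)
    }
  }
  vals
}

# Count lobes (across distinct events) whose +/-4 sigma supports overlap.
.count_overlaps <- function(truth) {
  if (nrow(truth) < 2L) return(0L)
  sig <- mapply(.lobe_sigma, truth$width_s, truth$amplitude_pA)
  lo <- truth$time_s - 4 * sig
  hi <- truth$time_s + 4 * sig
  o <- order(truth$time_s)
  lo <- lo[o]; hi <- hi[o]; id <- truth$event_id[o]
  sum(lo[-1L] < hi[-length(hi)] & id[-1L] != id[-length(id)])
}

# ---- public generators ---------------------------------------------------

#' Simulate a medium-only baseline recording
#'
#' Zero-mean bounded Gaussian noise emulating a recording with culture
#' medium but no cells: the realised peak-to-peak amplitude never exceeds
#' `config$baseline_noise_pp` (default 0.8 pA, under the sub-1 pA level of
#' medium-only recordings).
#'
#' @param config A [recording_config]. The seed, if set, makes the trace
#'   reproducible.
#' @return An [mea_ts] current trace (pA).
#' @examples
#' ts <- simulate_baseline(recording_config(10, seed = 1))
#' max(abs(ts$values))
#' @export
simulate_baseline <- function(config) {
  stopifnot(inherits(config, "recording_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- round(config$duration * config$sampling_rate)
  mea_ts(.baseline_noise(n, config$baseline_noise_pp),
         dt = 1 / config$sampling_rate, t0 = 0, unit = "current")
}

#' Biphasic spike template
#'
#' Charge-balanced waveform of one positive and one negative Gaussian lobe
#' of equal amplitude. The lobe-peak separation is the electrode diameter
#' divided by the wave speed when `wave` is supplied (the traveling-wave
#' picture), otherwise `sync$biphasic_separation`.
#'
#' @param wave Optional [wave_params]; takes precedence for the separation.
#' @param sync A [sync_params] supplying amplitude and width bounds.
#' @param sampling_rate Sampling rate (Hz).
#' @param width Lobe width (s); defaults to the geometric mean of the sync
#'   width bounds.
#' @return A list of class `mea_template` with elements `values`, `dt`,
#'   `separation`, `amplitude` and `width`. `values` starts 5 lobe-sigmas
#'   before the positive peak.
#' @examples
#' tpl <- biphasic_template(wave_params(500), sampling_rate = 1000)
#' tpl$separation   # 1.128 mm / 500 um/s = 2.26 s
#' @export
biphasic_template <- function(wave = NULL, sync = sync_params(),
                              sampling_rate = 1000, width = NULL) {
  stopifnot(inherits(sync, "sync_params"))
  sep <- if (!is.null(wave)) {
    stopifnot(inherits(wave, "wave_params"))
    wave$electrode_diameter * 1000 / wave$wave_speed
  } else {
    sync$biphasic_separation
  }
  if (sep < 2 / sampling_rate)
    stop("lobe separation shorter than 2 samples at this sampling rate",
         call. = FALSE)
  if (is.null(width))
    width <- exp(mean(log(c(sync$width_low, sync$width_high))))
  sigma <- .lobe_sigma(width, sync$amplitude)
  dt <- 1 / sampling_rate
  tt <- seq(-5 * sigma, sep + 5 * sigma, by = dt)
  vals <- sync$amplitude * (exp(-tt^2 / (2 * sigma^2)) -
                            exp(-(tt - sep)^2 / (2 * sigma^2)))
  structure(list(values = vals, dt = dt, separation = sep,
                 amplitude = sync$amplitude, width = width, sigma = sigma),
            class = "mea_template")
}

#' Simulate a multi-regime extracellular recording with ground truth
#'
#' Generates baseline noise plus, per scheduled segment, either Poisson
#' asynchronous unipolar spikes or quasi-periodic biphasic spikes.
#' Overlapping events superpose linearly (the recorded signal is the sum
#' of all cell contributions); overlaps are counted, never dropped.
#'
#' @param config A [recording_config].
#' @param schedule Data frame with columns `regime`
#'   (`"asynchronous"`/`"synchronous"`) and `duration` (s); durations must
#'   sum to `config$duration`.
#' @param async An [async_params].
#' @param sync A [sync_params].
#' @param wave Optional [wave_params]; when supplied it sets the biphasic
#'   lobe separation from electrode diameter and wave speed.
#' @return A list of class `mea_sim` with elements `recording` ([mea_ts],
#'   pA), `truth` (data frame: `time_s`, `amplitude_pA`, `width_s`,
#'   `polarity`, `kind`, `regime`, `event_id`; one row per lobe, biphasic
#'   lobes share an `event_id`) and `overlaps` (count of overlapping
#'   insertions across distinct events).
#' @examples
#' sim <- simulate_recording(recording_config(60, seed = 1),
#'                           data.frame(regime = "synchronous", duration = 60))
#' nrow(sim$truth)
#' @export
simulate_recording <- function(config, schedule, async = async_params(),
                               sync = sync_params(), wave = NULL) {
  stopifnot(inherits(config, "recording_config"),
            inherits(async, "async_params"),
            inherits(sync, "sync_params"))
  if (!is.data.frame(schedule) ||
      !all(c("regime", "duration") %in% names(schedule)) ||
      nrow(schedule) == 0L)
    stop("`schedule` must be a non-empty data frame with columns ",
         "`regime` and `duration`", call. = FALSE)
  if (any(schedule$duration <= 0))
    stop("schedule durations must be positive", call. = FALSE)
  if (abs(sum(schedule$duration) - config$duration) > 1e-9)
    stop("schedule durations must sum to the configured recording duration",
         call. = FALSE)
  bad <- setdiff(schedule$regime, c("asynchronous", "synchronous"))
  if (length(bad))
    stop("unknown regime label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  min_width <- min(async$width_low, sync$width_low)
  if (config$sampling_rate < 10 / min_width)
    stop("sampling_rate must be at least 10x the reciprocal of the ",
         "shortest spike width", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  vals <- .baseline_noise(n, config$baseline_noise_pp)
  sep <- if (!is.null(wave)) {
    stopifnot(inherits(wave, "wave_params"))
    wave$electrode_diameter * 1000 / wave$wave_speed
  } else {
    sync$biphasic_separation
  }
  if (sep >= sync$mean_isi)
    stop("biphasic lobe separation must stay below the mean ISI",
         call. = FALSE)
  truth <- .empty_truth()
  t_cur <- 0
  for (k in seq_len(nrow(schedule))) {
    t_next <- t_cur + schedule$duration[k]
    seg <- if (schedule$regime[k] == "asynchronous")
      .gen_async_events(t_cur, t_next, async)
    else
      .gen_sync_events(t_cur, t_next, sync, sep)
    truth <- rbind(truth, seg)
    t_cur <- t_next
  }
  truth <- truth[order(truth$time_s), , drop = FALSE]
  rownames(truth) <- NULL
  # one event_id per unipolar lobe; biphasic lobes share the id of their +
  # lobe (generated consecutively in time before sorting is preserved by
  # construction: the - lobe follows its + lobe by `sep` < mean ISI)
  truth$event_id <- .assign_event_ids(truth)
  vals <- .insert_events(vals, fs, truth)
  rec <- mea_ts(vals, dt = 1 / fs, t0 = 0, unit = "current")
  structure(list(recording = rec, truth = truth,
                 overlaps = .count_overlaps(truth)),
            class = "mea_sim")
}

.assign_event_ids <- function(truth) {
  id <- integer(nrow(truth))
  nxt <- 1L
  open_pos <- NULL   # index of an unmatched + biphasic lobe
  for (k in seq_len(nrow(truth))) {
    if (truth$kind[k] == "unipolar") {
      id[k] <- nxt; nxt <- nxt + 1L
    } else if (truth$amplitude_pA[k] > 0) {
      id[k] <- nxt; open_pos <- nxt; nxt <- nxt + 1L
    } else {
      id[k] <- if (is.null(open_pos)) nxt else open_pos
      if (is.null(open_pos)) nxt <- nxt + 1L
      open_pos <- NULL
    }
  }
  id
}

#' Simulate a three-phase inhibition experiment
#'
#' Before-phase activity (quasi-periodic by default), an inhibitor-block
#' phase in which spiking collapses to sub-threshold residual fluctuations,
#' and an after-phase drawn from the same distributions as the before
#' phase, emulating wash-out and recovery.
#'
#' @param config A [recording_config] whose duration equals the summed
#'   protocol phase durations.
#' @param protocol An [inhibition_protocol].
#' @param async Optional [async_params]; if supplied (and `sync` is
#'   `NULL`), pre/post phases are asynchronous.
#' @param sync A [sync_params] for pre/post activity (default), or `NULL`
#'   to use `async`.
#' @return A list of class `mea_sim` with elements `recording`, `truth`,
#'   `overlaps` and `phases` (data frame `label` = before/during/after,
#'   `start_s`, `end_s`; half-open intervals).
#' @export
simulate_inhibition_experiment <- function(config,
                                           protocol = inhibition_protocol(),
                                           async = NULL,
                                           sync = sync_params()) {
  stopifnot(inherits(config, "recording_config"),
            inherits(protocol, "inhibition_protocol"))
  total <- protocol$pre_duration + protocol$block_duration +
    protocol$post_duration
  if (abs(total - config$duration) > 1e-9)
    stop("protocol phase durations must sum to the configured recording ",
         "duration", call. = FALSE)
  use_sync <- !is.null(sync)
  if (!use_sync && is.null(async))
    stop("supply `sync` or `async` for the pre/post activity", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate
  vals <- .baseline_noise(round(config$duration * fs),
                          config$baseline_noise_pp)
  b1 <- protocol$pre_duration
  b2 <- b1 + protocol$block_duration
  gen_active <- function(t0, t1, regime) {
    if (use_sync) .gen_sync_events(t0, t1, sync, sync$biphasic_separation,
                                   regime)
    else .gen_async_events(t0, t1, async, regime)
  }
  pre <- gen_active(0, b1, if (use_sync) "synchronous" else "asynchronous")
  during <- .gen_residual_events(b1, b2, protocol$residual_amplitude,
                                 config$baseline_noise_pp)
  post <- gen_active(b2, config$duration,
                     if (use_sync) "synchronous" else "asynchronous")
  truth <- rbind(pre, during, post)
  truth <- truth[order(truth$time_s), , drop = FALSE]
  rownames(truth) <- NULL
  truth$event_id <- .assign_event_ids(truth)
  vals <- .insert_events(vals, fs, truth)
  phases <- data.frame(label = c("before", "during", "after"),
                       start_s = c(0, b1, b2),
                       end_s = c(b1, b2, config$duration),
                       stringsAsFactors = FALSE)
  structure(list(recording = mea_ts(vals, dt = 1 / fs, t0 = 0,
                                    unit = "current"),
                 truth = truth, overlaps = .count_overlaps(truth),
                 phases = phases),
            class = "mea_sim")
}

# Sparse sub-threshold residual fluctuations during the block phase. Event
# magnitudes are bounded so that spike + baseline noise never exceeds
# `residual`; events closer than 1 s are thinned so bounds cannot stack.
.gen_residual_events <- function(t_start, t_end, residual, noise_pp,
                                 rate = 0.2) {
  amp_max <- residual - noise_pp / 2
  if (amp_max <= 0) return(.empty_truth())
  ev <- .gen_async_events(t_start, t_end,
                          async_params(event_rate = rate,
                                       amplitude_mean = 0.6 * amp_max,
                                       amplitude_sd = 0.15 * amp_max,
                                       width_low = 0.03, width_high = 0.2,
                                       negative_polarity_prob = 0.5),
                          regime = "blocked")
  if (nrow(ev) > 1L)
    ev <- ev[c(TRUE, diff(ev$time_s) >= 1), , drop = FALSE]
  ev$amplitude_pA <- sign(ev$amplitude_pA) *
    pmin(abs(ev$amplitude_pA), amp_max)
  ev
}

#' @export
print.mea_sim <- function(x, ...) {
  cat(sprintf("<mea_sim> %.6g s at %.6g Hz; %d ground-truth lobes (%d events), %d overlap(s)\n",
              ts_duration(x$recording) + x$recording$dt,
              1 / x$recording$dt, nrow(x$truth),
              length(unique(x$truth$event_id)), x$overlaps))
  if (!is.null(x$phases)) {
    cat("  phases: ",
        paste(sprintf("%s [%g, %g)", x$phases$label, x$phases$start_s,
                      x$phases$end_s), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
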