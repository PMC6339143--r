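#' Event onset times (biphasic pairs counted once)
#'
#' Collapses a detected-event table to event onsets: unipolar events keep
#' their peak time, a biphasic pair contributes the time of its first
#' lobe. Used by regime segmentation and ISI statistics, which treat a
#' biphasic spike as one event.
#'
#' @param events Events data frame; `pair_id` may be absent or all-`NA`,
#'   in which case every event counts.
#' @return Sorted numeric vector of onset times (s).
#' @export
event_onsets <- function(events) {
  if (nrow(events) == 0L) return(numeric(0))
  if (is.null(events$pair_id) || all(is.na(events$pair_id)))
    return(sort(events$peak_time_s))
  unpaired <- events$peak_time_s[is.na(events$pair_id)]
  paired <- events[!is.na(events$pair_id), , drop = FALSE]
  firsts <- tapply(paired$peak_time_s, paired$pair_id, min)
  sort(c(unpaired, as.numeric(firsts)))
}

#' Segment a recording into asynchronous and synchronous regimes
#'
#' Slides a fixed window over the recording span, computes the event-onset
#' rate and the coefficient of variation (CV) of inter-onset intervals in
#' each window, and labels a window synchronous when the rate reaches
#' `rate_cutoff` and the CV stays at or below `cv_cutoff` (quasi-periodic
#' activity is both frequent and regular). Adjacent same-label windows are
#' merged. The defaults separate sporadic sub-0.2 Hz activity from
#' ~0.5 Hz quasi-periodic trains with wide margin.
#'
#' @param events Events data frame (ideally after [pair_biphasic()], so a
#'   biphasic pair counts once).
#' @param rec_span Length-2 numeric: recording start and end (s).
#' @param window Window length (s).
#' @param rate_cutoff Minimum onset rate (events/s) for a synchronous call.
#' @param cv_cutoff Maximum inter-onset-interval CV for a synchronous call.
#' @return Data frame of class `mea_segments`: `start_s`, `end_s`, `label`,
#'   `spike_count` (detected lobes in the segment), `spike_rate`
#'   (lobes/s). An empty event list yields one asynchronous segment
#'   spanning the recording.
#' @export
segment_regimes <- function(events, rec_span, window = 30,
                            rate_cutoff = 0.2, cv_cutoff = 0.6) {
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  if (length(rec_span) != 2L || rec_span[2] <= rec_span[1])
    stop("`rec_span` must be increasing start/end times", call. = FALSE)
  span0 <- rec_span[1]; span1 <- rec_span[2]
  make_seg <- function(start, end, label) {
    cnt <- if (nrow(events)) {
      sum(events$peak_time_s >= start & events$peak_time_s < end)
    } else 0L
    data.frame(start_s = start, end_s = end, label = label,
               spike_count = cnt, spike_rate = cnt / (end - start),
               stringsAsFactors = FALSE)
  }
  if (nrow(events) == 0L) {
    out <- make_seg(span0, span1, "asynchronous")
    class(out) <- c("mea_segments", "data.frame")
    return(out)
  }
  if (is.unsorted(events$peak_time_s))
    stop("`events` must be sorted by peak time", call. = FALSE)
  onsets <- event_onsets(events)
  breaks <- seq(span0, span1, by = window)
  if (breaks[length(breaks)] < span1) breaks <- c(breaks, span1)
  labels <- character(length(breaks) - 1L)
  for (k in seq_along(labels)) {
    w <- onsets[onsets >= breaks[k] & onsets < breaks[k + 1L]]
    rate <- length(w) / (breaks[k + 1L] - breaks[k])
    cv <- if (length(w) >= 3L) {
      isi <- diff(w)
      stats::sd(isi) / mean(isi)
    } else Inf
    labels[k] <- if (rate >= rate_cutoff && is.finite(cv) &&
                     cv <= cv_cutoff) "synchronous" else "asynchronous"
  }
  runs <- rle(labels)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  out <- do.call(rbind, lapply(seq_along(runs$values), function(k) {
    make_seg(breaks[starts[k]], breaks[stops[k] + 1L], runs$values[k])
  }))
  rownames(out) <- NULL
  class(out) <- c("mea_segments", "data.frame")
  out
}

#' Per-regime spike statistics
#'
#' For each regime label present in `segments`, computes the amplitude,
#' width and inter-spike-interval histograms together with the unipolar
#' fraction, biphasic lobe separations and mean event rate. Amplitude
#' bins run in 50 pA steps from 50 to 350 pA (plus a sub-threshold and an
#' overflow bin) on the absolute amplitude; widths are binned at 50 ms up
#' to 0.5 s plus overflow; ISIs between consecutive event onsets within a
#' segment are binned at 1 s resolution.
#'
#' @param events Events data frame with `kind` set (see [pair_biphasic()]).
#' @param segments A segmentation from [segment_regimes()] (any data frame
#'   with `start_s`, `end_s`, `label`).
#' @return A list of class `mea_spike_stats`, one entry per label, each
#'   with `amplitude_histogram`, `width_histogram`, `isi_histogram` (data
#'   frames `lo`, `hi`, `count`), `unipolar_fraction`,
#'   `biphasic_separations`, `n_events`, `n_onsets`, `mean_rate` (onsets/s;
#'   a biphasic pair counts once) and `lobe_rate` (lobes/s).
#' @export
spike_statistics <- function(events, segments) {
  stopifnot(is.data.frame(segments),
            all(c("start_s", "end_s", "label") %in% names(segments)))
  amp_breaks <- c(0, seq(50, 350, by = 50), Inf)
  wid_breaks <- c(seq(0, 0.5, by = 0.05), Inf)
  out <- list()
  for (lab in unique(segments$label)) {
    seg <- segments[segments$label == lab, , drop = FALSE]
    dur <- sum(seg$end_s - seg$start_s)
    in_lab <- rep(FALSE, nrow(events))
    seg_of <- rep(NA_integer_, nrow(events))
    if (nrow(events)) {
      for (j in seq_len(nrow(seg))) {
        hit <- events$peak_time_s >= seg$start_s[j] &
          events$peak_time_s < seg$end_s[j]
        in_lab <- in_lab | hit
        seg_of[hit] <- j
      }
    }
    ev <- events[in_lab, , drop = FALSE]
    # ISIs between consecutive onsets, never across segment boundaries
    isis <- numeric(0)
    seps <- numeric(0)
    if (nrow(ev)) {
      for (j in seq_len(nrow(seg))) {
        evj <- ev[seg_of[in_lab] == j, , drop = FALSE]
        on <- event_onsets(evj)
        if (length(on) >= 2L) isis <- c(isis, diff(on))
        if (!is.null(evj$pair_id)) {
          pid <- evj$pair_id[!is.na(evj$pair_id)]
          full <- names(which(table(pid) == 2L))
          for (p in full) {
            tp <- evj$peak_time_s[!is.na(evj$pair_id) & evj$pair_id == p]
            seps <- c(seps, diff(sort(tp)))
          }
        }
      }
    }
    isi_breaks <- seq(0, max(1, ceiling(max(isis, 1))), by = 1)
    kind_known <- nrow(ev) > 0 && !all(is.na(ev$kind))
    out[[lab]] <- list(
      amplitude_histogram = .hist_table(abs(ev$amplitude_pA), amp_breaks),
      width_histogram = .hist_table(ev$width_s, wid_breaks),
      isi_histogram = .hist_table(isis, isi_breaks),
      unipolar_fraction = if (kind_known)
        mean(ev$kind == "unipolar", na.rm = TRUE) else NA_real_,
      biphasic_separations = seps,
      n_events = nrow(ev),
      n_onsets = length(event_onsets(ev)),
      mean_rate = length(event_onsets(ev)) / dur,
      lobe_rate = nrow(ev) / dur,
      duration_s = dur)
  }
  structure(out, class = "mea_spike_stats")
}

.hist_table <- function(x, breaks) {
  if (length(x) == 0L) {
    return(data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                      count = 0L))
  }
  cnt <- as.integer(table(cut(x, breaks = breaks, right = FALSE,
                              include.lowest = TRUE)))
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1], count = cnt)
}

#' @export
print.mea_spike_stats <- function(x, ...) {
  for (lab in names(x)) {
    s <- x[[lab]]
    cat(sprintf("%s: %d lobes (%d onsets) over %.6g s; rate %.3g events/s; unipolar fraction %s\n",
                lab, s$n_events, s$n_onsets, s$duration_s, s$mean_rate,
                if (is.na(s$unipolar_fraction)) "NA"
                else sprintf("%.2f", s$unipolar_fraction)))
  }
  invisible(x)
}

#' Estimate traveling-wave speed from biphasic lobe separations
#'
#' Under the traveling-wave picture the two lobes of a biphasic spike mark
#' the wave entering and leaving the electrode, so each pair yields a
#' speed estimate: electrode diameter divided by lobe separation.
#'
#' @param events Events data frame after [pair_biphasic()] containing at
#'   least one complete pair.
#' @param electrode_diameter Electrode diameter in mm; for a circular
#'   electrode of area A mm^2 this is `2 * sqrt(A / pi)` (1.128 mm for
#'   1 mm^2), see [wave_params()].
#' @return A list of class `mea_wave_speed`: `speeds_um_s` (per-pair),
#'   `median_um_s`, `separations_s`, `n_pairs`. With no pairs all fields
#'   are empty/`NA` and a warning is emitted.
#' @examples
#' # separation 2 s on a 1 mm-diameter electrode -> 500 um/s
#' @export
estimate_wave_speed <- function(events, electrode_diameter) {
  if (electrode_diameter <= 0)
    stop("`electrode_diameter` must be positive (mm)", call. = FALSE)
  seps <- numeric(0)
  if (nrow(events) && !is.null(events$pair_id) &&
      any(!is.na(events$pair_id))) {
    pid <- events$pair_id[!is.na(events$pair_id)]
    full <- names(which(table(pid) == 2L))
    seps <- vapply(full, function(p) {
      diff(sort(events$peak_time_s[!is.na(events$pair_id) &
                                   events$pair_id == p]))
    }, numeric(1))
  }
  if (length(seps) == 0L) {
    warning("no complete biphasic pairs; wave speed not estimable",
            call. = FALSE)
    return(structure(list(speeds_um_s = numeric(0), median_um_s = NA_real_,
                          separations_s = numeric(0), n_pairs = 0L),
                     class = "mea_wave_speed"))
  }
  speeds <- electrode_diameter * 1000 / seps
  structure(list(speeds_um_s = unname(speeds),
                 median_um_s = stats::median(speeds),
                 separations_s = unname(seps),
                 n_pairs = length(seps)),
            class = "mea_wave_speed")
}

#' @export
print.mea_wave_speed <- function(x, ...) {
  if (x$n_pairs == 0L) cat("<mea_wave_speed> no pairs\n")
  else cat(sprintf("<mea_wave_speed> %d pairs; median %.4g um/s (separations %.3g-%.3g s)\n",
                   x$n_pairs, x$median_um_s, min(x$separations_s),
                   max(x$separations_s)))
  invisible(x)
}
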