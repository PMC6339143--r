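#' Spike detection configuration
#'
#' @param threshold Detection threshold in pA, applied symmetrically as
#'   +/- threshold. The reference analyses count only spikes over
#'   +/-50 pA, hence the default.
#' @param refractory Minimum gap (s) between same-polarity peaks; closer
#'   peaks are merged keeping the larger one.
#' @param pairing_window Maximum positive-to-negative peak separation (s)
#'   for a biphasic call; the default 2 s covers the observed 0.3-2 s lobe
#'   separations.
#' @param baseline_window If positive, a sliding-median baseline over this
#'   window (s) is subtracted before thresholding; 0 (default) disables
#'   the correction.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold = 50, refractory = 0.05,
                             pairing_window = 2, baseline_window = 0) {
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  if (refractory < 0) stop("`refractory` must be >= 0", call. = FALSE)
  if (pairing_window <= 0)
    stop("`pairing_window` must be positive", call. = FALSE)
  structure(list(threshold = threshold, refractory = refractory,
                 pairing_window = pairing_window,
                 baseline_window = baseline_window),
            class = "detection_config")
}

.empty_events <- function() {
  structure(
    data.frame(peak_time_s = numeric(0), amplitude_pA = numeric(0),
               width_s = numeric(0), polarity = character(0),
               kind = character(0), pair_id = integer(0),
               stringsAsFactors = FALSE),
    class = c("mea_events", "data.frame"))
}

#' Detect threshold-crossing spikes in a current trace
#'
#' One event is emitted per contiguous excursion beyond `+threshold` or
#' below `-threshold`. The peak time is the extremum sample inside the
#' excursion (earliest sample wins on ties), the amplitude is the signed
#' extremum value, and the width is the time between the excursion's two
#' threshold crossings, located by linear interpolation between samples
#' (the trace boundary stands in for a missing crossing). Same-polarity
#' peaks closer than the refractory gap are merged, keeping the larger.
#'
#' @param rec An [mea_ts] current trace (pA), at least 3 samples, all
#'   finite.
#' @param cfg A [detection_config].
#' @return An `mea_events` data frame sorted by `peak_time_s` with columns
#'   `peak_time_s`, `amplitude_pA`, `width_s`, `polarity` (`"+"`/`"-"`)
#'   and, until [pair_biphasic()] is applied, `kind = NA` and
#'   `pair_id = NA`.
#' @examples
#' x <- numeric(1000); x[400:500] <- 100
#' ev <- detect_spikes(mea_ts(x, dt = 1e-3), detection_config())
#' ev$width_s   # ~0.1 s
#' @export
detect_spikes <- function(rec, cfg = detection_config()) {
  .assert_ts(rec, unit = "current")
  if (length(rec$values) < 3L)
    stop("trace must have at least 3 samples", call. = FALSE)
  if (!all(is.finite(rec$values)))
    stop("trace contains non-finite samples", call. = FALSE)
  if (!inherits(cfg, "detection_config"))
    stop("`cfg` must be created by detection_config()", call. = FALSE)
  x <- rec$values
  if (cfg$baseline_window > 0)
    x <- x - .sliding_median(x, round(cfg$baseline_window / rec$dt))
  pos <- .excursions(x, rec$dt, rec$t0, cfg$threshold, positive = TRUE)
  neg <- .excursions(-x, rec$dt, rec$t0, cfg$threshold, positive = FALSE)
  pos <- .merge_refractory(pos, cfg$refractory)
  neg <- .merge_refractory(neg, cfg$refractory)
  ev <- rbind(pos, neg)
  if (nrow(ev) == 0L) return(.empty_events())
  ev <- ev[order(ev$peak_time_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev$kind <- NA_character_
  ev$pair_id <- NA_integer_
  class(ev) <- c("mea_events", "data.frame")
  ev
}

# Runs of samples strictly above `thr` in `x` (already sign-flipped for the
# negative side). Crossing times by linear interpolation.
.excursions <- function(x, dt, t0, thr, positive) {
  above <- x > thr
  if (!any(above)) {
    return(data.frame(peak_time_s = numeric(0), amplitude_pA = numeric(0),
                      width_s = numeric(0), polarity = character(0),
                      stringsAsFactors = FALSE))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  n <- length(x)
  tt <- function(i) t0 + (i - 1) * dt
  out <- lapply(seq_along(starts), function(k) {
    i1 <- starts[k]; i2 <- ends[k]
    seg <- x[i1:i2]
    pk <- i1 - 1L + which.max(seg)      # earliest max on ties
    tc1 <- if (i1 > 1L)
      tt(i1 - 1L) + dt * (thr - x[i1 - 1L]) / (x[i1] - x[i1 - 1L])
    else tt(i1)
    tc2 <- if (i2 < n)
      tt(i2) + dt * (thr - x[i2]) / (x[i2 + 1L] - x[i2])
    else tt(i2)
    c(tt(pk), x[pk], tc2 - tc1)
  })
  m <- do.call(rbind, out)
  data.frame(peak_time_s = m[, 1],
             amplitude_pA = if (positive) m[, 2] else -m[, 2],
             width_s = m[, 3],
             polarity = if (positive) "+" else "-",
             stringsAsFactors = FALSE)
}

# Merge same-polarity peaks closer than `refractory`, keeping the larger
# |amplitude| (earlier wins on ties). Chained comparisons use the last
# kept peak.
.merge_refractory <- function(ev, refractory) {
  if (nrow(ev) < 2L || refractory <= 0) return(ev)
  keep <- logical(nrow(ev))
  keep[1L] <- TRUE
  last <- 1L
  for (k in 2:nrow(ev)) {
    if (ev$peak_time_s[k] - ev$peak_time_s[last] < refractory) {
      if (abs(ev$amplitude_pA[k]) > abs(ev$amplitude_pA[last])) {
        keep[last] <- FALSE
        keep[k] <- TRUE
        last <- k
      }
    } else {
      keep[k] <- TRUE
      last <- k
    }
  }
  ev[keep, , drop = FALSE]
}

.sliding_median <- function(x, w) {
  if (w < 3L) return(rep(stats::median(x), length(x)))
  n <- length(x)
  half <- w %/% 2L
  out <- numeric(n)
  # median over a window centred on each sample, evaluated on a coarse
  # grid and interpolated: the baseline varies on 10-s scales, not per
  # sample
  grid <- unique(c(seq(1L, n, by = max(1L, half)), n))
  med <- vapply(grid, function(i) {
    stats::median(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  stats::approx(grid, med, xout = seq_len(n), rule = 2)$y
}

#' Classify detected spikes as unipolar or biphasic
#'
#' Greedy left-to-right pairing: scanning events in time order, two
#' adjacent events of opposite polarity whose peaks lie within
#' `cfg$pairing_window` seconds form a biphasic pair and receive a shared
#' `pair_id`; every other event is unipolar. Each event belongs to at most
#' one pair.
#'
#' @param events An `mea_events` data frame from [detect_spikes()], sorted
#'   by time.
#' @param cfg A [detection_config].
#' @return The events with `kind` set to `"unipolar"` or `"biphasic"` and
#'   `pair_id` filled for paired events.
#' @export
pair_biphasic <- function(events, cfg = detection_config()) {
  if (!is.data.frame(events))
    stop("`events` must be an events data frame", call. = FALSE)
  n <- nrow(events)
  if (n == 0L) return(events)
  if (is.unsorted(events$peak_time_s))
    stop("`events` must be sorted by peak time", call. = FALSE)
  kind <- rep("unipolar", n)
  pair_id <- rep(NA_integer_, n)
  pid <- 0L
  k <- 1L
  while (k < n) {
    sep <- events$peak_time_s[k + 1L] - events$peak_time_s[k]
    if (events$polarity[k] != events$polarity[k + 1L] &&
        sep <= cfg$pairing_window) {
      pid <- pid + 1L
      kind[c(k, k + 1L)] <- "biphasic"
      pair_id[c(k, k + 1L)] <- pid
      k <- k + 2L
    } else {
      k <- k + 1L
    }
  }
  events$kind <- kind
  events$pair_id <- pair_id
  events
}

#' @export
print.mea_events <- function(x, ...) {
  cat(sprintf("<mea_events> %d event(s)", nrow(x)))
  if (nrow(x) && !all(is.na(x$kind))) {
    nb <- sum(x$kind == "biphasic", na.rm = TRUE)
    cat(sprintf(": %d unipolar, %d biphasic lobes (%d pairs)",
                sum(x$kind == "unipolar", na.rm = TRUE), nb, nb %/% 2L))
  }
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more\n", nrow(x) - 10L))
  invisible(x)
}
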