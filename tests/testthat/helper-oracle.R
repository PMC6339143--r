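# Naive per-sample spike detector used as an independent oracle for
# detect_spikes(): a state machine walked sample by sample, with the same
# documented conventions (strict > threshold, earliest extremum on ties,
# linearly interpolated crossings, boundary stands in for a missing
# crossing, sequential refractory merge keeping the larger peak).
brute_detect <- function(x, dt, t0 = 0, threshold = 50, refractory = 0) {
  one_side <- function(sgn) {
    y <- sgn * x
    n <- length(y)
    rows <- list()
    in_exc <- FALSE
    i1 <- pk <- NA_integer_
    tt <- function(i) t0 + (i - 1) * dt
    for (i in seq_len(n)) {
      if (!in_exc && y[i] > threshold) {
        in_exc <- TRUE; i1 <- i; pk <- i
      } else if (in_exc && y[i] > y[pk]) {
        pk <- i
      }
      if (in_exc && (i == n || y[i + 1] <= threshold)) {
        i2 <- i
        tc1 <- if (i1 > 1)
          tt(i1 - 1) + dt * (threshold - y[i1 - 1]) / (y[i1] - y[i1 - 1])
        else tt(i1)
        tc2 <- if (i2 < n)
          tt(i2) + dt * (threshold - y[i2]) / (y[i2 + 1] - y[i2])
        else tt(i2)
        rows[[length(rows) + 1L]] <-
          data.frame(peak_time_s = tt(pk), amplitude_pA = sgn * y[pk],
                     width_s = tc2 - tc1,
                     polarity = if (sgn > 0) "+" else "-",
                     stringsAsFactors = FALSE)
        in_exc <- FALSE
      }
    }
    ev <- if (length(rows)) do.call(rbind, rows) else
      data.frame(peak_time_s = numeric(0), amplitude_pA = numeric(0),
                 width_s = numeric(0), polarity = character(0),
                 stringsAsFactors = FALSE)
    if (refractory > 0 && nrow(ev) > 1) {
      keep <- logical(nrow(ev)); keep[1] <- TRUE; last <- 1L
      for (k in 2:nrow(ev)) {
        if (ev$peak_time_s[k] - ev$peak_time_s[last] < refractory) {
          if (abs(ev$amplitude_pA[k]) > abs(ev$amplitude_pA[last])) {
            keep[last] <- FALSE; keep[k] <- TRUE; last <- k
          }
        } else {
          keep[k] <- TRUE; last <- k
        }
      }
      ev <- ev[keep, , drop = FALSE]
    }
    ev
  }
  ev <- rbind(one_side(1), one_side(-1))
  ev <- ev[order(ev$peak_time_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# A trace of zeros with rectangular pulses stamped in: pulses is a data
# frame with columns start_s, dur_s, amp_pA.
pulse_trace <- function(duration, dt, pulses) {
  n <- round(duration / dt)
  x <- numeric(n)
  for (k in seq_len(nrow(pulses))) {
    i1 <- round(pulses$start_s[k] / dt) + 1L
    i2 <- min(n, i1 + round(pulses$dur_s[k] / dt) - 1L)
    x[i1:i2] <- x[i1:i2] + pulses$amp_pA[k]
  }
  mea_ts(x, dt = dt, t0 = 0, unit = "current")
}

# Hand-built event tables for the characterization tests.
make_events <- function(times, amps, widths = 0.1,
                        kind = NA_character_, pair_id = NA_integer_) {
  o <- order(times)
  ev <- data.frame(peak_time_s = times, amplitude_pA = amps,
                   width_s = rep_len(widths, length(times)),
                   polarity = ifelse(amps < 0, "-", "+"),
                   kind = rep_len(kind, length(times)),
                   pair_id = rep_len(pair_id, length(times)),
                   stringsAsFactors = FALSE)[o, ]
  rownames(ev) <- NULL
  class(ev) <- c("mea_events", "data.frame")
  ev
}
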