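#' Assign detected spikes to experiment phases
#'
#' Each event is assigned to the unique phase whose half-open interval
#' `[start_s, end_s)` contains its peak time; events outside every phase
#' are ignored and their count attached as the `"ignored"` attribute.
#'
#' @param events Events data frame, sorted by peak time.
#' @param phases Data frame with columns `label`, `start_s`, `end_s`
#'   (non-overlapping; typically labels before/during/after).
#' @return Named integer vector of per-phase counts, in `phases` order,
#'   with attribute `ignored`.
#' @export
phase_spike_counts <- function(events, phases) {
  .assert_phases(phases)
  counts <- integer(nrow(phases))
  names(counts) <- phases$label
  if (nrow(events)) {
    if (is.unsorted(events$peak_time_s))
      stop("`events` must be sorted by peak time", call. = FALSE)
    for (k in seq_len(nrow(phases))) {
      counts[k] <- sum(events$peak_time_s >= phases$start_s[k] &
                       events$peak_time_s < phases$end_s[k])
    }
  }
  attr(counts, "ignored") <- nrow(events) - sum(counts)
  counts
}

.assert_phases <- function(phases) {
  if (!is.data.frame(phases) ||
      !all(c("label", "start_s", "end_s") %in% names(phases)))
    stop("`phases` needs columns label, start_s, end_s", call. = FALSE)
  if (any(phases$end_s <= phases$start_s))
    stop("each phase must have end_s > start_s", call. = FALSE)
  if (nrow(phases) > 1L) {
    o <- order(phases$start_s)
    if (any(phases$start_s[o][-1L] < phases$end_s[o][-nrow(phases)]))
      stop("phases must not overlap", call. = FALSE)
  }
  if (anyDuplicated(phases$label))
    stop("phase labels must be unique", call. = FALSE)
  invisible(phases)
}

#' Robust fluctuation magnitude within a phase
#'
#' Peak current fluctuation of a trace window, measured robustly as the
#' 99.5th percentile of the absolute median-subtracted current, so a
#' single stray noise sample cannot dominate the estimate. Invariant to
#' constant offsets.
#'
#' @param rec An [mea_ts] current trace (pA).
#' @param phase Either a length-2 numeric `c(start, end)` in seconds or a
#'   one-row phase data frame with `start_s`, `end_s`.
#' @return Fluctuation magnitude in pA.
#' @export
fluctuation_magnitude <- function(rec, phase) {
  .assert_ts(rec, unit = "current")
  if (is.data.frame(phase)) phase <- c(phase$start_s[1], phase$end_s[1])
  if (length(phase) != 2L || phase[2] <= phase[1])
    stop("`phase` must be increasing start/end times", call. = FALSE)
  tt <- ts_time(rec)
  x <- rec$values[tt >= phase[1] & tt < phase[2]]
  if (length(x) < 10L)
    stop("phase covers fewer than 10 samples", call. = FALSE)
  as.numeric(stats::quantile(abs(x - stats::median(x)), 0.995,
                             names = FALSE))
}

#' Call inhibitor block and recovery from a three-phase experiment
#'
#' Decision rule for a before/during/after inhibition experiment:
#' the block is called when the during-phase spike count falls to at most
#' 10% of the before-phase count ("almost zero") and the during-phase
#' fluctuation magnitude stays at or below `block_magnitude`; recovery is
#' called when the after-phase count lies within `count_tolerance`
#' (fractionally) of the before-phase count.
#'
#' @param counts Named per-phase counts (`before`, `during`, `after`),
#'   e.g. from [phase_spike_counts()].
#' @param magnitudes Named per-phase fluctuation magnitudes in pA, e.g.
#'   from [fluctuation_magnitude()].
#' @param count_tolerance Fractional tolerance for recovery (default 0.5:
#'   after-count within +/-50% of before-count).
#' @param block_magnitude Maximum during-phase fluctuation for a block
#'   call (pA); default 5, the level activity collapses below under
#'   effective calcium-channel inhibition.
#' @return A list of class `mea_inhibition_report` with `counts`,
#'   `magnitudes`, `block_called`, `recovery_called` and the thresholds
#'   used. A zero before-count makes both calls `NA` with a warning.
#' @examples
#' assess_block(c(before = 20, during = 0, after = 18),
#'              c(before = 100, during = 3, after = 95))
#' @export
assess_block <- function(counts, magnitudes, count_tolerance = 0.5,
                         block_magnitude = 5) {
  need <- c("before", "during", "after")
  if (!all(need %in% names(counts)) || !all(need %in% names(magnitudes)))
    stop("`counts` and `magnitudes` must be named before/during/after",
         call. = FALSE)
  counts <- counts[need]; magnitudes <- magnitudes[need]
  if (any(counts < 0) || any(magnitudes < 0))
    stop("counts and magnitudes must be non-negative", call. = FALSE)
  if (counts[["before"]] == 0) {
    warning("before-phase count is zero; block/recovery undecidable",
            call. = FALSE)
    block <- NA
    recovery <- NA
  } else {
    block <- counts[["during"]] <= 0.1 * counts[["before"]] &&
      magnitudes[["during"]] <= block_magnitude
    recovery <- abs(counts[["after"]] - counts[["before"]]) <=
      count_tolerance * counts[["before"]]
  }
  structure(list(counts = counts, magnitudes = magnitudes,
                 block_called = block, recovery_called = recovery,
                 count_tolerance = count_tolerance,
                 block_magnitude = block_magnitude),
            class = "mea_inhibition_report")
}

#' @export
print.mea_inhibition_report <- function(x, ...) {
  cat("<mea_inhibition_report>\n")
  cat(sprintf("  counts     before/during/after: %d / %d / %d\n",
              x$counts[["before"]], x$counts[["during"]],
              x$counts[["after"]]))
  cat(sprintf("  magnitudes before/during/after: %.3g / %.3g / %.3g pA\n",
              x$magnitudes[["before"]], x$magnitudes[["during"]],
              x$magnitudes[["after"]]))
  cat(sprintf("  block called: %s; recovery called: %s\n",
              x$block_called, x$recovery_called))
  invisible(x)
}

#' Onset time of an inhibitor block (diagnostic)
#'
#' Start of the first 60-s window, stepped at 10 s through the during
#' phase, whose fluctuation magnitude drops below `block_magnitude`.
#' Diagnostic companion to [assess_block()] for "how fast did the
#' inhibitor act" questions.
#'
#' @param rec An [mea_ts] current trace (pA).
#' @param phase The during-phase interval (see [fluctuation_magnitude()]).
#' @param block_magnitude Fluctuation level defining "blocked" (pA).
#' @param window,step Window length and step (s).
#' @return Onset time in seconds, or `NA` if no window qualifies.
#' @export
block_onset_time <- function(rec, phase, block_magnitude = 5,
                             window = 60, step = 10) {
  if (is.data.frame(phase)) phase <- c(phase$start_s[1], phase$end_s[1])
  starts <- seq(phase[1], phase[2] - window, by = step)
  for (s in starts) {
    if (fluctuation_magnitude(rec, c(s, s + window)) < block_magnitude)
      return(s)
  }
  NA_real_
}
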