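#' Growth summary of electrode cell counts
#'
#' Per-day average and standard error of the mean over electrodes, plus
#' the same two rows normalised by the final-day average (so the final
#' normalised average is exactly 1). The S.E.M uses the sample (n-1)
#' standard deviation divided by sqrt(n).
#'
#' @param counts Numeric matrix of cell counts, rows = electrodes (at
#'   least 2), columns = days; column names are taken as day labels.
#' @param days Optional numeric day labels (strictly increasing),
#'   overriding column names.
#' @return A data frame of class `mea_growth_summary` with columns `day`,
#'   `average`, `sem`, `normalized_average`, `normalized_sem`.
#' @examples
#' m <- matrix(rep(c(40, 90, 160, 280, 1190), each = 8), nrow = 8)
#' growth_summary(m, days = c(1, 2, 3, 4, 8))
#' @export
growth_summary <- function(counts, days = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0))
    stop("`counts` must be a non-negative numeric matrix", call. = FALSE)
  if (nrow(counts) < 2L)
    stop("at least 2 electrodes are required (S.E.M undefined for one)",
         call. = FALSE)
  if (is.null(days)) {
    days <- suppressWarnings(as.numeric(colnames(counts)))
    if (anyNA(days)) days <- seq_len(ncol(counts))
  }
  if (length(days) != ncol(counts) || is.unsorted(days, strictly = TRUE))
    stop("day labels must be strictly increasing, one per column",
         call. = FALSE)
  n <- nrow(counts)
  avg <- colMeans(counts)
  sem <- apply(counts, 2, stats::sd) / sqrt(n)
  final <- avg[length(avg)]
  if (final <= 0) stop("final-day average must be positive", call. = FALSE)
  out <- data.frame(day = days, average = avg, sem = sem,
                    normalized_average = avg / final,
                    normalized_sem = sem / final)
  rownames(out) <- NULL
  class(out) <- c("mea_growth_summary", "data.frame")
  out
}

#' @export
print.mea_growth_summary <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$average <- round(y$average, digits)
  y$sem <- round(y$sem, digits)
  y$normalized_average <- round(y$normalized_average, digits)
  y$normalized_sem <- signif(y$normalized_sem, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Percent viability from an MTT plate
#'
#' Mean absorbance of each condition expressed as a percentage of the
#' negative-control mean, with the S.E.M propagated from the condition
#' replicates (the control mean is treated as fixed). Conditions falling
#' below `cytotoxic_below` percent are flagged cytotoxic.
#'
#' @param plate Data frame with columns `condition` and `absorbance`, one
#'   row per replicate; at least 3 replicates per condition.
#' @param negative_control Name of the negative-control condition.
#' @param cytotoxic_below Flag threshold in percent (default 90, the level
#'   above which a compound is considered non-cytotoxic here).
#' @return A data frame of class `mea_viability` with columns `condition`,
#'   `n`, `percent`, `sem_percent`, `cytotoxic`.
#' @examples
#' plate <- data.frame(
#'   condition = rep(c("negative", "gd_250uM"), each = 3),
#'   absorbance = c(1.00, 1.02, 0.98, 0.95, 0.92, 0.93))
#' percent_viability(plate)
#' @export
percent_viability <- function(plate, negative_control = "negative",
                              cytotoxic_below = 90) {
  if (!is.data.frame(plate) ||
      !all(c("condition", "absorbance") %in% names(plate)))
    stop("`plate` needs columns condition and absorbance", call. = FALSE)
  reps <- table(plate$condition)
  if (any(reps < 3L))
    stop("every condition needs at least 3 replicates", call. = FALSE)
  if (!negative_control %in% plate$condition)
    stop("negative control condition '", negative_control,
         "' not present", call. = FALSE)
  ctrl <- mean(plate$absorbance[plate$condition == negative_control])
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("negative-control mean absorbance must be positive", call. = FALSE)
  conds <- unique(plate$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    a <- plate$absorbance[plate$condition == cc]
    data.frame(condition = cc, n = length(a),
               percent = 100 * mean(a) / ctrl,
               sem_percent = 100 * stats::sd(a) / sqrt(length(a)) / ctrl,
               stringsAsFactors = FALSE)
  }))
  out$cytotoxic <- out$percent < cytotoxic_below
  rownames(out) <- NULL
  class(out) <- c("mea_viability", "data.frame")
  out
}

#' Final concentration after diluting a stock into medium
#'
#' `final = stock * added / (added + medium)`, converted from mM to uM.
#' The reference inhibition experiment added 3 uL of 1 mM gadolinium to
#' 280 uL of medium, giving about 10.6 uM.
#'
#' @param added_volume_ul Volume of stock added (uL).
#' @param stock_concentration_mM Stock concentration (mM).
#' @param medium_volume_ul Medium volume before addition (uL).
#' @return Final concentration in uM.
#' @examples
#' dilution_concentration(3, 1, 280)   # 10.6 uM
#' @export
dilution_concentration <- function(added_volume_ul, stock_concentration_mM,
                                   medium_volume_ul) {
  if (added_volume_ul < 0 || medium_volume_ul <= 0 ||
      stock_concentration_mM < 0)
    stop("volumes must be positive and concentrations non-negative",
         call. = FALSE)
  1000 * stock_concentration_mM * added_volume_ul /
    (added_volume_ul + medium_volume_ul)
}
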