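#' Electrode-electrolyte equivalent-circuit parameters
#'
#' The recording chain is modelled as a charge-transfer resistance `R_D` in
#' parallel with the Helmholtz-Gouy-Chapman double-layer capacitance `C_D`,
#' in series with the spreading resistance `R_c`; the cell-generated
#' current is read out by a transimpedance amplifier with feedback
#' resistance `R_F`. The seal impedance `Z_seal` between sensing and
#' counter electrode is assumed very large; it enters no equation but is
#' validated here because the measurement model presumes it dominates the
#' interface resistances.
#'
#' Defaults describe a mm^2-scale gold electrode recording pA-scale
#' currents: `R_D` = 10 MOhm, `C_D` = 1 uF, `R_c` = 10 kOhm, `R_F` = 1 GOhm.
#'
#' @param rd_ohm Charge-transfer resistance (Ohm).
#' @param cd_farad Double-layer capacitance (F).
#' @param rc_ohm Spreading resistance (Ohm).
#' @param rf_ohm Amplifier feedback resistance (Ohm).
#' @param zseal_ohm Seal impedance magnitude (Ohm). A warning is emitted if
#'   it is not at least 10x the larger of `rd_ohm` and `rc_ohm`.
#'
#' @return An object of class `circuit_params`.
#' @examples
#' p <- circuit_params()
#' time_constant(p)
#' @export
circuit_params <- function(rd_ohm = 1e7, cd_farad = 1e-6, rc_ohm = 1e4,
                           rf_ohm = 1e9, zseal_ohm = 1e12) {
  vals <- c(rd_ohm = rd_ohm, cd_farad = cd_farad, rc_ohm = rc_ohm,
            rf_ohm = rf_ohm, zseal_ohm = zseal_ohm)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all circuit parameters must be strictly positive and finite",
         call. = FALSE)
  if (zseal_ohm < 10 * max(rd_ohm, rc_ohm))
    warning("Z_seal is not large relative to R_D and R_c; ",
            "the lumped measurement model assumes a very high seal impedance",
            call. = FALSE)
  structure(as.list(vals), class = "circuit_params")
}

.assert_circuit <- function(p) {
  if (!inherits(p, "circuit_params"))
    stop("`params` must be created by circuit_params()", call. = FALSE)
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf(paste0("<circuit_params> R_D = %.3g Ohm, C_D = %.3g F, ",
                     "R_c = %.3g Ohm, R_F = %.3g Ohm, Z_seal = %.3g Ohm ",
                     "(tau = %.3g s)\n"),
              x$rd_ohm, x$cd_farad, x$rc_ohm, x$rf_ohm, x$zseal_ohm,
              time_constant(x)))
  invisible(x)
}

#' Interface charging time constant
#'
#' Time constant of the electrode interface: the double-layer capacitance
#' charging through the parallel combination of charge-transfer and
#' spreading resistances,
#' `tau = C_D * (R_c * R_D) / (R_c + R_D)`.
#'
#' @param params A [circuit_params] object.
#' @return Time constant in seconds.
#' @export
time_constant <- function(params) {
  .assert_circuit(params)
  params$cd_farad * (params$rc_ohm * params$rd_ohm) /
    (params$rc_ohm + params$rd_ohm)
}

#' Interface current driven by a cell-generated voltage
#'
#' Displacement current coupled through the double-layer capacitance in
#' response to the extracellular voltage `v_s(t)` generated by the cell
#' population:
#' `i_s(t) = dv_s/dt * C_D * (1 - exp(-(t - t0)/tau))`,
#' with `tau` from [time_constant()]. The exponential factor describes the
#' charging of the interface network from the start of the trace. The
#' derivative is taken by central differences in the interior and one-sided
#' differences at the trace ends.
#'
#' @param vs An [mea_ts] voltage trace (V), at least 3 samples.
#' @param params A [circuit_params] object.
#' @return An [mea_ts] current trace in pA with the same sampling.
#' @examples
#' p <- circuit_params()
#' ramp <- mea_ts(1e-3 * seq(0, 1, by = 1e-3), dt = 1e-3, unit = "voltage")
#' i <- interface_current(ramp, p)   # tends to C_D * 1 mV/s = 1000 pA
#' @export
interface_current <- function(vs, params) {
  .assert_ts(vs, unit = "voltage")
  .assert_circuit(params)
  n <- length(vs$values)
  if (n < 3L)
    stop("voltage trace must have at least 3 samples for the derivative",
         call. = FALSE)
  dv <- .diff_central(vs$values, vs$dt)
  tau <- time_constant(params)
  t_rel <- (seq_len(n) - 1L) * vs$dt
  i_amp <- dv * params$cd_farad * (1 - exp(-t_rel / tau))
  mea_ts(i_amp * 1e12, dt = vs$dt, t0 = vs$t0, unit = "current")
}

#' Transimpedance amplifier output
#'
#' Output voltage of the current-to-voltage read-out stage,
#' `v_o(t) = -R_F * i_s(t)`: the measured current is inverted and scaled by
#' the feedback resistance.
#'
#' @param current An [mea_ts] current trace (pA).
#' @param params A [circuit_params] object.
#' @return An [mea_ts] voltage trace in V with the same sampling.
#' @examples
#' p <- circuit_params(rf_ohm = 1e9)
#' i <- mea_ts(rep(100, 10), dt = 1e-3, unit = "current")
#' transimpedance_output(i, p)$values[1]   # -0.1 V
#' @export
transimpedance_output <- function(current, params) {
  .assert_ts(current, unit = "current")
  .assert_circuit(params)
  mea_ts(-params$rf_ohm * current$values * 1e-12,
         dt = current$dt, t0 = current$t0, unit = "voltage")
}

# Central differences interior, one-sided at the ends: second-order
# accurate, no phase lag on band-limited signals.
.diff_central <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  if (n > 2L)
    d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d
}
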