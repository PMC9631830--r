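#' Sensor and reference-assay specification
#'
#' Describes the interstitial-fluid (ISF) biosensor and the serum reference
#' assay used for its one-point calibration. Serum assays carry a 5%
#' coefficient of variation (FDA-acceptable chromatographic assay error) and a
#' 1-h laboratory turnaround, so a calibration performed at time `i` uses the
#' serum and ISF measurements taken at `i - delay_h`. The ISF sensor error
#' magnitude is not established for minimally invasive beta-lactam sensors;
#' the default is a 10% multiplicative CV and is a configuration knob, not a
#' constant. Readings below the assay's lower limit of quantification
#' (1 mg/L) report the floor and are flagged.
#'
#' @param isf_cv ISF sensor coefficient of variation (fraction, >= 0).
#' @param serum_cv serum assay CV (fraction); default 0.05.
#' @param delay_h serum turnaround delay (h); default 1.
#' @param recal_interval_h interval between one-point recalibrations (h);
#'   default 6, a TDM-like cadence.
#' @param sampling_period_h ISF sensor sampling period (h); default 0.5.
#' @param detection_floor lower limit of quantification (mg/L); default 1.
#' @param reset_threshold relative calibration-factor discrepancy above which
#'   the controller's integral term is reset; default 0.30.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(isf_cv = 0.10, serum_cv = 0.05, delay_h = 1,
                        recal_interval_h = 6, sampling_period_h = 0.5,
                        detection_floor = 1, reset_threshold = 0.30) {
  stopifnot(isf_cv >= 0, serum_cv >= 0, delay_h >= 0,
            recal_interval_h > 0, sampling_period_h > 0)
  structure(list(isf_cv = isf_cv, serum_cv = serum_cv, delay_h = delay_h,
                 recal_interval_h = recal_interval_h,
                 sampling_period_h = sampling_period_h,
                 detection_floor = detection_floor,
                 reset_threshold = reset_threshold),
            class = "sensor_spec")
}

## Multiplicative Gaussian measurement: max(0, C * (1 + eps)), eps ~ N(0, cv).
noisy_measurement <- function(true_conc, cv) {
  stopifnot(all(true_conc >= 0))
  if (cv == 0) return(true_conc)
  pmax(0, true_conc * (1 + stats::rnorm(length(true_conc), 0, cv)))
}

#' Simulated ISF sensor and serum assay measurements
#'
#' Both apply multiplicative Gaussian noise floored at zero:
#' `M = max(0, C * (1 + eps))` with `eps ~ Normal(0, CV)`. `measure_isf` uses
#' the ISF sensor CV, `measure_serum` the serum assay CV. Noise draws come
#' from the current R RNG stream, so measurements are reproducible under a
#' fixed seed and independent of integrator step size.
#'
#' @param true_conc true concentration(s), mg/L, >= 0.
#' @param spec a [sensor_spec()].
#' @return Measured concentration(s), mg/L.
#' @export
measure_isf <- function(true_conc, spec = sensor_spec()) {
  noisy_measurement(true_conc, spec$isf_cv)
}

#' @rdname measure_isf
#' @export
measure_serum <- function(true_conc, spec = sensor_spec()) {
  noisy_measurement(true_conc, spec$serum_cv)
}

#' Initial (identity) calibration state
#'
#' Before the first one-point calibration the factor is the identity 1.0.
#'
#' @return An object of class `calibration_state` with fields `m` (factor),
#'   `time_h` (timestamp of last calibration, `NA` before the first),
#'   `discrepancy` (last relative change in the factor), `calibrated`
#'   (logical) and `skipped` (count of calibrations skipped at the detection
#'   floor).
#' @export
calibration_state <- function() {
  structure(list(m = 1.0, time_h = NA_real_, discrepancy = 0,
                 calibrated = FALSE, skipped = 0L),
            class = "calibration_state")
}

#' One-point calibration of the ISF sensor against a delayed serum assay
#'
#' Updates the calibration factor to the ratio of the two measurements taken
#' at time `i - delay`: `m_i = M_serum(i - t) / M_isf(i - t)`. The relative
#' discrepancy `|m_new - m_old| / m_old` is recorded; when it exceeds the
#' reset threshold (default 30%) the caller should reset the PID integral
#' term. If the ISF measurement is at or below the detection floor the
#' calibration is skipped and the previous factor retained.
#'
#' @param cal a [calibration_state()].
#' @param M_serum_delayed serum measurement taken at `i - delay` (mg/L).
#' @param M_isf_delayed ISF measurement taken at `i - delay` (mg/L).
#' @param i_h calibration time (h).
#' @param spec a [sensor_spec()].
#' @return Updated `calibration_state`; field `reset_triggered` (logical)
#'   indicates whether the discrepancy exceeded the threshold.
#' @examples
#' cal <- calibrate_sensor(calibration_state(), 50, 25, i_h = 2.5)
#' cal$m # 2
#' @export
calibrate_sensor <- function(cal, M_serum_delayed, M_isf_delayed, i_h,
                             spec = sensor_spec()) {
  cal$reset_triggered <- FALSE
  if (!is.finite(M_isf_delayed) || M_isf_delayed <= spec$detection_floor) {
    cal$skipped <- cal$skipped + 1L
    return(cal)
  }
  m_new <- M_serum_delayed / M_isf_delayed
  cal$discrepancy <- if (cal$calibrated) abs(m_new - cal$m) / cal$m else 0
  cal$reset_triggered <- cal$calibrated && cal$discrepancy > spec$reset_threshold
  cal$m <- m_new
  cal$time_h <- i_h
  cal$calibrated <- TRUE
  cal
}

#' Convert an ISF reading into the controller's serum-scale measurement
#'
#' Applies the current one-point calibration factor:
#' `C_V(k) = m_i * M_isf(k)`. Before the first calibration the identity
#' factor is used (with a warning, once per state).
#'
#' @param M_isf ISF sensor reading (mg/L).
#' @param cal a [calibration_state()].
#' @return The calibrated serum-scale measurement `C_V` (mg/L).
#' @export
controller_measurement <- function(M_isf, cal) {
  if (!cal$calibrated)
    warning("controller measurement requested before first calibration; ",
            "using identity factor")
  cal$m * M_isf
}
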