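#' PID controller configuration
#'
#' Discrete PID law evaluated every `dt` hours:
#' `u(k) = B(k) + s * [Kp e(k) + Ki * sum(e) * dt + Kd * (e(k) - e(k-1)) / dt]`
#' where the integral sum runs over a trailing sliding window of `window_h`
#' hours (anti-windup) and `e(k) = C_V(k) - SP`. The gain coefficients follow
#' `Kd = Kp / Td` and `Ki = Kp * Ti`; set `textbook_gains = TRUE` for the
#' conventional reciprocal arrangement `Ki = Kp / Ti`, `Kd = Kp * Td`.
#'
#' The sign factor `s` is controlled by `error_sign`:
#' * `"negative_feedback"` (default): `s = -1`, i.e. the corrective terms are
#'   subtracted, so concentrations above target reduce the rate. This is the
#'   stabilizing convention and the one consistent with the closed-loop
#'   behaviour the controller is meant to produce.
#' * `"as_printed"`: `s = +1`, the error `C_V - SP` enters with positive
#'   gains. Provided for auditability of the discrete law's arithmetic; on a
#'   physical plant this is positive feedback.
#'
#' Safety constraints, applied in order after the raw law:
#' 1. if `C_V` exceeds the upper bound of the control range, delivery halts
#'    (`u = 0`) for this sample (no latching; re-evaluated next sample);
#' 2. `u <= max_rate_multiple * B(k)` (default 5x basal);
#' 3. `u >= min_rate_frac * u_prev` (default 50% of the last nonzero
#'    commanded rate); a halt is allowed to violate this floor;
#' 4. `u >= 0`.
#'
#' @param Kp proportional gain ((mg/h)/(mg/L)).
#' @param Td,Ti derivative and integral time constants (h).
#' @param dt sampling period (h); default 0.5.
#' @param window_h integral sliding-window length (h); default 6; must be a
#'   multiple of `dt`.
#' @param setpoint target serum concentration (mg/L); default the midpoint of
#'   the control range, 60 mg/L.
#' @param control_range broader range used for control (mg/L); default
#'   (20, 100).
#' @param basal predefined basal infusion profile: a single rate (mg/h) or a
#'   function of time; default 300 mg/h, the initial infusion rate.
#' @param max_rate_multiple saturation cap as a multiple of basal; default 5.
#' @param min_rate_frac floor as a fraction of the previous commanded rate;
#'   default 0.5.
#' @param error_sign `"negative_feedback"` or `"as_printed"` (see Details).
#' @param textbook_gains use the reciprocal gain convention.
#' @return An object of class `pid_config` with derived fields `Ki`, `Kd`
#'   and `n_window` (window length in samples).
#' @export
pid_config <- function(Kp = 5, Td = 1, Ti = 0.5, dt = 0.5, window_h = 6,
                       setpoint = 60, control_range = c(20, 100),
                       basal = 300, max_rate_multiple = 5,
                       min_rate_frac = 0.5,
                       error_sign = c("negative_feedback", "as_printed"),
                       textbook_gains = FALSE) {
  error_sign <- match.arg(error_sign)
  stopifnot(Kp > 0, Td > 0, Ti > 0, dt > 0, window_h > 0,
            setpoint > control_range[1], setpoint < control_range[2])
  n_window <- window_h / dt
  if (abs(n_window - round(n_window)) > 1e-9)
    stop("window_h must be a multiple of dt")
  cfg <- list(Kp = Kp, Td = Td, Ti = Ti,
              Ki = if (textbook_gains) Kp / Ti else Kp * Ti,
              Kd = if (textbook_gains) Kp * Td else Kp / Td,
              dt = dt, window_h = window_h, n_window = as.integer(round(n_window)),
              setpoint = setpoint, control_range = control_range,
              basal = basal, max_rate_multiple = max_rate_multiple,
              min_rate_frac = min_rate_frac, error_sign = error_sign,
              textbook_gains = textbook_gains)
  class(cfg) <- "pid_config"
  cfg
}

basal_at <- function(cfg, t_h) {
  if (is.function(cfg$basal)) cfg$basal(t_h) else cfg$basal
}

#' Initial controller state
#'
#' @param cfg a [pid_config()].
#' @param u_prev the rate in force before the controller starts (mg/h); the
#'   50%-of-previous floor references it at the first controlled sample.
#' @return An object of class `pid_state`: empty error window, previous rate
#'   memory, previous error `NA` (the first step uses a zero derivative),
#'   halted flag, and counters.
#' @export
pid_state <- function(cfg, u_prev = basal_at(cfg, 0)) {
  structure(list(errors = numeric(0), u_prev = u_prev, e_prev = NA_real_,
                 halted = FALSE, n_resets = 0L, n_steps = 0L),
            class = "pid_state")
}

#' One controller step
#'
#' Appends the new error to the sliding window (zeroing it first if
#' `reset_integral`), evaluates the discrete PID law with backward-difference
#' derivative and rectangle-rule integral, and applies the safety constraints.
#' The controller always returns a rate.
#'
#' @param C_V calibrated serum-scale measurement (mg/L), >= 0.
#' @param t_h current time (h), used to evaluate the basal profile.
#' @param cfg a [pid_config()].
#' @param state a [pid_state()].
#' @param reset_integral zero the error window before this step (triggered by
#'   a >30% calibration discrepancy).
#' @return A list with `u` (commanded rate, mg/h), the updated `state`, and
#'   `log`, a one-row data frame with the P/I/D terms, the raw and applied
#'   rate and which constraint bound (`none`, `halt`, `cap`, `floor`).
#' @export
pid_step <- function(C_V, t_h, cfg, state, reset_integral = FALSE) {
  stopifnot(C_V >= 0)
  if (reset_integral) {
    state$errors <- numeric(0)
    state$e_prev <- NA_real_
    state$n_resets <- state$n_resets + 1L
  }
  e <- C_V - cfg$setpoint
  e_prev <- if (is.na(state$e_prev)) e else state$e_prev
  state$errors <- c(state$errors, e)
  if (length(state$errors) > cfg$n_window)
    state$errors <- state$errors[(length(state$errors) - cfg$n_window + 1L):
                                   length(state$errors)]
  s <- if (cfg$error_sign == "negative_feedback") -1 else 1
  B <- basal_at(cfg, t_h)
  P <- cfg$Kp * e
  I <- cfg$Ki * sum(state$errors) * cfg$dt
  D <- cfg$Kd * (e - e_prev) / cfg$dt
  u_raw <- B + s * (P + I + D)
  con <- apply_constraints(u_raw, C_V, cfg, state, t_h = t_h)
  state$e_prev <- e
  state$halted <- con$constraint == "halt"
  if (con$u > 0) state$u_prev <- con$u
  state$n_steps <- state$n_steps + 1L
  list(u = con$u, state = state,
       log = data.frame(time_h = t_h, C_V = C_V, e = e, P_term = s * P,
                        I_term = s * I, D_term = s * D, u_raw = u_raw,
                        u_applied = con$u, constraint_applied = con$constraint,
                        integral_reset = reset_integral))
}

#' Apply the safety constraints to a raw commanded rate
#'
#' Ordered rules: halt (highest precedence, may violate the floor), cap at
#' `max_rate_multiple * basal`, floor at `min_rate_frac` of the last nonzero
#' commanded rate, and non-negativity.
#'
#' @param u_raw raw PID output (mg/h), finite.
#' @param C_V current calibrated measurement (mg/L).
#' @param cfg a [pid_config()].
#' @param state a [pid_state()] (supplies the previous-rate memory).
#' @param t_h time (h) at which to evaluate the basal profile.
#' @return A list with `u` (constrained rate) and `constraint` (one of
#'   `"none"`, `"halt"`, `"cap"`, `"floor"`).
#' @export
apply_constraints <- function(u_raw, C_V, cfg, state, t_h = 0) {
  stopifnot(is.finite(u_raw))
  if (C_V > cfg$control_range[2])
    return(list(u = 0, constraint = "halt"))
  u <- u_raw
  constraint <- "none"
  cap <- cfg$max_rate_multiple * basal_at(cfg, t_h)
  if (u > cap) {
    u <- cap
    constraint <- "cap"
  }
  floor_u <- cfg$min_rate_frac * state$u_prev
  if (u < floor_u) {
    u <- floor_u
    constraint <- "floor"
  }
  if (u < 0) u <- 0
  list(u = u, constraint = constraint)
}

#' Adaptive-tuning hook
#'
#' Interface point for on-line re-tuning of the controller. The adaptation
#' mechanism itself is out of scope (it is not exercised under the target
#' ranges used here), so this hook returns the configuration unchanged and
#' counts its invocations.
#'
#' @param cfg a [pid_config()].
#' @param state a [pid_state()].
#' @param trigger_conditions ignored.
#' @return `cfg`, unchanged, with attribute `adapt_calls` incremented.
#' @export
adapt_tuning <- function(cfg, state = NULL, trigger_conditions = NULL) {
  n <- attr(cfg, "adapt_calls")
  attr(cfg, "adapt_calls") <- if (is.null(n)) 1L else n + 1L
  cfg
}
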