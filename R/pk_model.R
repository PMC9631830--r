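#' Pharmacokinetic parameters of the three-compartment piperacillin model
#'
#' The model has an unbound central compartment (volume `V`, serum
#' concentration `X1/V`), an interstitial-fluid (ISF) compartment (volume
#' `Visf`, ISF concentration `X2/Visf`) and a peripheral compartment.
#' Elimination (`Ke`) acts on the central compartment only; `KCP`/`KPC` are
#' the central-peripheral transfer rate constants and `Kisf`/`Kub` the
#' central-to-ISF and ISF-to-central transfer rate constants. Clearance is
#' `CL = Ke_base * V`.
#'
#' Exactly one of `CL` and `Ke_base` must be given; the other is derived.
#'
#' @param V central volume of distribution (L).
#' @param Visf ISF volume (L).
#' @param CL clearance (L/h).
#' @param Ke_base baseline elimination rate constant (1/h).
#' @param KCP,KPC central to/from peripheral transfer rate constants (1/h).
#' @param Kisf,Kub central-to-ISF / ISF-to-central transfer rate constants (1/h).
#' @return An object of class `pk_parameters` (a named list).
#' @examples
#' pk_parameters(V = 17, Visf = 12.4, CL = 14,
#'               KCP = 2, KPC = 1.5, Kisf = 1, Kub = 1.5)
#' @export
pk_parameters <- function(V, Visf, CL = NULL, Ke_base = NULL,
                          KCP, KPC, Kisf, Kub) {
  if (is.null(Ke_base) && is.null(CL))
    stop("one of CL or Ke_base must be supplied")
  if (is.null(Ke_base)) Ke_base <- CL / V
  if (is.null(CL)) CL <- Ke_base * V
  p <- list(V = V, Visf = Visf, Ke_base = Ke_base, CL = CL,
            KCP = KCP, KPC = KPC, Kisf = Kisf, Kub = Kub)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PK parameters must be finite and strictly positive")
  if (abs(p$CL - p$Ke_base * p$V) > 1e-8 * p$CL)
    stop("inconsistent CL, Ke_base and V")
  class(p) <- "pk_parameters"
  p
}

#' Instantaneous derivatives of the compartment amounts
#'
#' Mass balance of the three-compartment model:
#' \deqn{dX_1/dt = rate + K_{PC} X_3 + K_{ub} X_2 - (k_e(t) + K_{CP} + K_{isf}) X_1}
#' \deqn{dX_2/dt = K_{isf} X_1 - K_{ub} X_2}
#' \deqn{dX_3/dt = K_{CP} X_1 - K_{PC} X_3}
#'
#' @param state numeric length-3 vector of amounts `(X1, X2, X3)` in mg.
#' @param rate infusion rate into the central compartment (mg/h).
#' @param params a [pk_parameters()] object.
#' @param ke_t instantaneous elimination rate constant (1/h); defaults to
#'   `params$Ke_base`.
#' @return Numeric length-3 vector of amount derivatives (mg/h).
#' @export
pk_derivatives <- function(state, rate, params, ke_t = params$Ke_base) {
  if (length(state) != 3L || any(!is.finite(state)))
    stop("state must be three finite amounts")
  stopifnot(ke_t > 0)
  c(rate + params$KPC * state[3] + params$Kub * state[2] -
      (ke_t + params$KCP + params$Kisf) * state[1],
    params$Kisf * state[1] - params$Kub * state[2],
    params$KCP * state[1] - params$KPC * state[3])
}

#' Serum concentration at steady state under a constant infusion
#'
#' For the linear model with elimination from the central compartment only,
#' the steady-state serum concentration under a constant rate `R` is
#' `R / (Ke_base * V) = R / CL`, independent of the transfer constants.
#'
#' @param params a [pk_parameters()] object.
#' @param rate constant infusion rate (mg/h), non-negative.
#' @return Steady-state serum concentration (mg/L).
#' @examples
#' p <- pk_parameters(V = 17, Visf = 12.4, CL = 14,
#'                    KCP = 2, KPC = 1.5, Kisf = 1, Kub = 1.5)
#' steady_state_serum(p, 840) # 60 mg/L
#' @export
steady_state_serum <- function(params, rate) {
  stopifnot(rate >= 0)
  rate / (params$Ke_base * params$V)
}

## Resolve a ke modulator into the (A, P, phi) sinusoid parameters used by the
## compiled right-hand side, or NULL when a general R function must be used.
ke_sinusoid_params <- function(ke_modulator) {
  if (is.null(ke_modulator)) return(c(A = 0, P = 24, phi = 0))
  if (inherits(ke_modulator, "ke_sinusoid")) {
    return(c(A = attr(ke_modulator, "A"), P = attr(ke_modulator, "P"),
             phi = attr(ke_modulator, "phi")))
  }
  NULL
}

## Advance the state over [t0, t1] at a constant rate, returning states at
## `times` (which must start at t0 and end at t1). One deSolve call; the
## caller is responsible for splitting at schedule breakpoints.
pk_advance <- function(state, t0, t1, rate, params, ke_modulator = NULL,
                       times = c(t0, t1), rtol = 1e-6, atol = 1e-6) {
  sinus <- ke_sinusoid_params(ke_modulator)
  if (!is.null(sinus)) {
    parms <- c(params$Ke_base, params$KCP, params$KPC, params$Kisf,
               params$Kub, rate, sinus[["A"]], sinus[["P"]], sinus[["phi"]])
    out <- deSolve::ode(y = state, times = times, func = "pk_derivs",
                        parms = parms, dllname = "piperloop",
                        initfunc = "pk_initmod", method = "ode45",
                        rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, y, p) {
      ke <- params$Ke_base * ke_modulator(t)
      list(pk_derivatives(y, rate, params, ke))
    }
    out <- deSolve::ode(y = state, times = times, func = rhs, parms = NULL,
                        method = "ode45", rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("ODE integration failed on segment [%g, %g] h", t0, t1))
  unname(out[, 2:4, drop = FALSE])
}

#' Simulate the three-compartment model under an infusion schedule
#'
#' Integrates the model with an adaptive Dormand-Prince (RK45) method,
#' restarting the integrator at every schedule breakpoint so that rate
#' discontinuities are never smoothed across. Time-varying elimination is
#' supported through `ke_modulator`, a function mapping time (h) to a
#' dimensionless multiplier of `Ke_base` (see [ke_modulator()]).
#'
#' @param params a [pk_parameters()] object.
#' @param schedule an [infusion_schedule()]; times outside every segment have
#'   rate 0.
#' @param horizon simulation end time (h), > 0.
#' @param output_step spacing of the output grid (h).
#' @param initial numeric length-3 initial amounts (mg); default all zero.
#' @param ke_modulator `NULL` (constant elimination), a [ke_modulator()]
#'   sinusoid, or any function of time returning a positive multiplier.
#' @param rtol,atol integrator tolerances.
#' @return A `simulation_trace`: a data frame with columns `time_h`,
#'   `rate_mg_per_h`, `X1_mg`, `X2_mg`, `X3_mg`, `serum_mg_per_L`,
#'   `isf_mg_per_L`, `cum_dose_mg`. Amounts are clipped to zero on output;
#'   an excursion below -1e-6 mg raises an error.
#' @examples
#' p <- pk_parameters(V = 17, Visf = 12.4, CL = 14,
#'                    KCP = 2, KPC = 1.5, Kisf = 1, Kub = 1.5)
#' tr <- pk_simulate(p, infusion_schedule(0, 30, 840), horizon = 30)
#' tail(tr$serum_mg_per_L, 1) # approaches 840/14 = 60 mg/L
#' @export
pk_simulate <- function(params, schedule, horizon, output_step = 0.1,
                        initial = c(0, 0, 0), ke_modulator = NULL,
                        rtol = 1e-6, atol = 1e-6) {
  stopifnot(horizon > 0, output_step > 0)
  validate_schedule(schedule)
  segs <- effective_segments(schedule, horizon)
  grid <- round(seq(0, horizon, by = output_step), 10)

  all_t <- numeric(0)
  all_x <- matrix(numeric(0), ncol = 3)
  state <- as.numeric(initial)
  for (i in seq_len(nrow(segs))) {
    t0 <- segs$start[i]; t1 <- segs$end[i]
    tt <- sort(unique(c(t0, grid[grid > t0 + 1e-12 & grid < t1 - 1e-12], t1)))
    x <- pk_advance(state, t0, t1, segs$rate[i], params, ke_modulator,
                    times = tt, rtol = rtol, atol = atol)
    state <- x[nrow(x), ]
    keep <- if (i == 1L) seq_along(tt) else seq_along(tt)[-1L]
    all_t <- c(all_t, tt[keep])
    all_x <- rbind(all_x, x[keep, , drop = FALSE])
  }

  if (min(all_x) < -1e-6)
    stop(sprintf("negative compartment amount (%.3g mg): integration problem",
                 min(all_x)))
  all_x[all_x < 0] <- 0

  tr <- data.frame(
    time_h = all_t,
    rate_mg_per_h = schedule_rate_at(schedule, all_t),
    X1_mg = all_x[, 1], X2_mg = all_x[, 2], X3_mg = all_x[, 3],
    serum_mg_per_L = all_x[, 1] / params$V,
    isf_mg_per_L = all_x[, 2] / params$Visf,
    cum_dose_mg = vapply(all_t, function(t) schedule_total_dose(schedule, t),
                         numeric(1))
  )
  class(tr) <- c("simulation_trace", "data.frame")
  tr
}

## Partition [0, horizon] into contiguous constant-rate segments (gaps in the
## schedule become rate-0 segments).
effective_segments <- function(schedule, horizon) {
  bp <- sort(unique(c(0, horizon,
                      schedule$start_h[schedule$start_h < horizon],
                      schedule$end_h[schedule$end_h < horizon])))
  bp <- bp[bp >= 0 & bp <= horizon]
  data.frame(start = bp[-length(bp)], end = bp[-1L],
             rate = schedule_rate_at(schedule, bp[-length(bp)]))
}

#' Read and write simulation traces as CSV
#'
#' Columns: `time_h, rate_mg_per_h, X1_mg, X2_mg, X3_mg, serum_mg_per_L,
#' isf_mg_per_L, cum_dose_mg`.
#'
#' @param trace a trace from [pk_simulate()].
#' @param path file path.
#' @return `read_trace_csv` returns the trace data frame; `write_trace_csv`
#'   returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(unclass(trace)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path)
  class(tr) <- c("simulation_trace", "data.frame")
  tr
}
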