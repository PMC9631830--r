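#' Comparator dosing-protocol configuration
#'
#' Parameters of the three standard clinical regimens and of the closed-loop
#' arm's scaffold: 4,000 mg piperacillin boluses infused over 20 min, a 6-h
#' dosing interval, a fixed continuous rate of 4,000 mg per 6 h
#' (666.67 mg/h), TDM titration steps of +/-500 mg per 6 h against the
#' midpoint of the (20, 100) mg/L control range using serum measurements with
#' a 1-h lab turnaround, a 30-h trial horizon, and for the closed-loop arm a
#' 300 mg/h initial basal rate with controller start at 2.5 h.
#'
#' @param bolus_mg bolus / loading dose (mg).
#' @param bolus_duration_h infusion duration of a bolus (h); default 1/3.
#' @param interval_h dosing / titration interval (h); default 6.
#' @param continuous_rate continuous rate (mg/h); default 4000/6.
#' @param titration_step_mg titration step per interval (mg); default 500.
#' @param titration_target titration reference concentration (mg/L);
#'   default 60, the midpoint of the control range.
#' @param serum_delay_h lab turnaround of titration measurements (h).
#' @param horizon_h trial horizon (h); default 30.
#' @param basal_rate closed-loop initial/basal rate (mg/h); default 300.
#' @param controller_start_h closed-loop controller start time (h);
#'   default 2.5.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(bolus_mg = 4000, bolus_duration_h = 1 / 3,
                            interval_h = 6, continuous_rate = 4000 / 6,
                            titration_step_mg = 500, titration_target = 60,
                            serum_delay_h = 1, horizon_h = 30,
                            basal_rate = 300, controller_start_h = 2.5) {
  cfg <- list(bolus_mg = bolus_mg, bolus_duration_h = bolus_duration_h,
              interval_h = interval_h, continuous_rate = continuous_rate,
              titration_step_mg = titration_step_mg,
              titration_target = titration_target,
              serum_delay_h = serum_delay_h, horizon_h = horizon_h,
              basal_rate = basal_rate,
              controller_start_h = controller_start_h)
  stopifnot(all(unlist(cfg) > 0))
  class(cfg) <- "protocol_config"
  cfg
}

#' Protocol 1: intermittent bolus dosing
#'
#' 4,000 mg boluses infused over 20 min at 6-h intervals starting at t = 0.
#' Within a 30-h horizon the doses fall at 0, 6, 12, 18 and 24 h (a dose at
#' 30 h would deliver outside the window), for 20,000 mg in total.
#'
#' @param cfg a [protocol_config()].
#' @return An [infusion_schedule()].
#' @export
protocol1_bolus <- function(cfg = protocol_config()) {
  starts <- seq(0, cfg$horizon_h - 1e-9, by = cfg$interval_h)
  rate <- cfg$bolus_mg / cfg$bolus_duration_h
  infusion_schedule(starts, starts + cfg$bolus_duration_h,
                    rep(rate, length(starts)))
}

#' Protocol 2: loading dose then fixed continuous infusion
#'
#' A 4,000 mg loading dose over 20 min, then a constant 4,000 mg/6 h
#' (666.67 mg/h) from the end of the loading infusion to the horizon.
#'
#' @param cfg a [protocol_config()].
#' @return An [infusion_schedule()].
#' @export
protocol2_continuous <- function(cfg = protocol_config()) {
  load_end <- min(cfg$bolus_duration_h, cfg$horizon_h)
  s <- infusion_schedule(0, load_end, cfg$bolus_mg / cfg$bolus_duration_h)
  if (cfg$horizon_h > load_end)
    s <- schedule_append(s, load_end, cfg$horizon_h, cfg$continuous_rate)
  s
}

#' One TDM titration decision
#'
#' The 6-h dose is decreased by the titration step if the delayed serum
#' measurement is above the target midpoint, increased if below, and left
#' unchanged if exactly equal. The resulting rate is floored at 0.
#'
#' @param current_rate current continuous rate (mg/h).
#' @param measurement the 1-h-delayed serum measurement (mg/L), or `NA`
#'   (missing measurement: no change).
#' @param cfg a [protocol_config()].
#' @return The new continuous rate (mg/h).
#' @export
titration_update <- function(current_rate, measurement,
                             cfg = protocol_config()) {
  if (is.na(measurement)) return(current_rate)
  step <- cfg$titration_step_mg / cfg$interval_h
  new_rate <- if (measurement > cfg$titration_target) current_rate - step
              else if (measurement < cfg$titration_target) current_rate + step
              else current_rate
  max(0, new_rate)
}

#' Protocol 3: TDM-titrated continuous infusion
#'
#' Starts as protocol 2; at each titration instant (6, 12, 18, 24 h for a
#' 30-h horizon) the continuous rate is adjusted by +/-500 mg per 6 h
#' according to a serum measurement drawn 1 h earlier (lab turnaround). The
#' measurement is supplied by `serum_sampler`, a function called with the
#' *sampling* time (titration time minus the delay) that must return the
#' measured serum concentration (mg/L) under the schedule built so far; in a
#' live trial this closes over the running simulation (see [run_arm()]).
#'
#' @param cfg a [protocol_config()].
#' @param serum_sampler `function(t_sample_h, schedule_so_far) -> mg/L`.
#' @return An [infusion_schedule()] with one segment per titration block,
#'   with attribute `titration_log` (data frame of decisions).
#' @export
protocol3_titrated <- function(cfg = protocol_config(), serum_sampler) {
  load_end <- cfg$bolus_duration_h
  sched <- infusion_schedule(0, load_end, cfg$bolus_mg / cfg$bolus_duration_h)
  titration_times <- seq(cfg$interval_h, cfg$horizon_h - 1e-9,
                         by = cfg$interval_h)
  rate <- cfg$continuous_rate
  seg_start <- load_end
  log <- NULL
  for (tt in c(titration_times, cfg$horizon_h)) {
    if (tt >= cfg$horizon_h) {
      sched <- schedule_append(sched, seg_start, cfg$horizon_h, rate)
      break
    }
    sched <- schedule_append(sched, seg_start, tt, rate)
    meas <- serum_sampler(tt - cfg$serum_delay_h, sched)
    new_rate <- titration_update(rate, meas, cfg)
    log <- rbind(log, data.frame(titration_h = tt,
                                 sample_h = tt - cfg$serum_delay_h,
                                 measurement = meas, rate_before = rate,
                                 rate_after = new_rate))
    rate <- new_rate
    seg_start <- tt
  }
  attr(sched, "titration_log") <- log
  sched
}

#' Scaffold of the closed-loop arm
#'
#' The open-loop part of the closed-loop protocol: a 4,000 mg loading dose
#' over 20 min at t = 0, the 300 mg/h basal rate running open-loop from the
#' end of the loading infusion until the controller starts at 2.5 h.
#'
#' @param cfg a [protocol_config()].
#' @return A list with `loading` (an [infusion_schedule()] covering
#'   `[0, controller_start_h)`), `controller_start_h` and `basal_rate`.
#' @export
closed_loop_scaffold <- function(cfg = protocol_config()) {
  s <- infusion_schedule(0, cfg$bolus_duration_h,
                         cfg$bolus_mg / cfg$bolus_duration_h)
  if (cfg$controller_start_h > cfg$bolus_duration_h)
    s <- schedule_append(s, cfg$bolus_duration_h, cfg$controller_start_h,
                         cfg$basal_rate)
  list(loading = s, controller_start_h = cfg$controller_start_h,
       basal_rate = cfg$basal_rate)
}
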