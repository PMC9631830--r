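#' Trial configuration
#'
#' @param n_patients cohort size; default 20.
#' @param horizon_h trial horizon (h); default 30.
#' @param eval_range tight evaluation range (mg/L); default (32, 64),
#'   2-4x the Pseudomonas aeruginosa breakpoint.
#' @param control_range broad control range (mg/L); default (20, 100).
#' @param output_step metric grid resolution (h); default 0.1.
#' @param dose_metric `"mean_rate"` (total delivered mass / horizon, default)
#'   or `"median_hourly_bins"` (median of the 30 hourly delivered masses).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_patients = 20, horizon_h = 30,
                         eval_range = c(32, 64), control_range = c(20, 100),
                         output_step = 0.1,
                         dose_metric = c("mean_rate", "median_hourly_bins")) {
  dose_metric <- match.arg(dose_metric)
  stopifnot(eval_range[1] >= control_range[1],
            eval_range[2] <= control_range[2],
            output_step > 0, horizon_h > 0)
  structure(list(n_patients = n_patients, horizon_h = horizon_h,
                 eval_range = eval_range, control_range = control_range,
                 output_step = output_step, dose_metric = dose_metric),
            class = "trial_config")
}

## Measure of {t in [t_0, t_end]: lo <= y(t) <= hi} for the piecewise-linear
## interpolant of (t, y). Constant segments sitting exactly on an excluded
## boundary are not counted (include_lo/include_hi).
band_measure <- function(t, y, lo, hi, include_lo = TRUE, include_hi = TRUE) {
  n <- length(t)
  dt <- t[-1] - t[-n]
  y0 <- y[-n]; y1 <- y[-1]
  ymin <- pmin(y0, y1); ymax <- pmax(y0, y1)
  const <- ymax - ymin == 0
  frac <- numeric(n - 1L)
  nc <- !const
  overlap <- pmax(0, pmin(ymax[nc], hi) - pmax(ymin[nc], lo))
  frac[nc] <- overlap / (ymax[nc] - ymin[nc])
  in_lo <- if (include_lo) ymin[const] >= lo else ymin[const] > lo
  in_hi <- if (include_hi) ymin[const] <= hi else ymin[const] < hi
  frac[const] <- as.numeric(in_lo & in_hi)
  sum(dt * frac)
}

#' Per-patient therapeutic target-attainment metrics
#'
#' Computes, on the serum concentration trace over the evaluation window:
#' `MEAN` (trapezoid time-average, mg/L), `TIR` (% time within the evaluation
#' range), `TBR` (% time below its lower bound), `TAR` (% time above its
#' upper bound), `TA_lo` (% time above the lower bound, = TIR + TAR) and
#' `DOSE` (average delivered dose per hour, mg/h). Time fractions are exact
#' for the piecewise-linear interpolant of the trace, so range crossings
#' between grid points are counted at their interpolated crossing times.
#'
#' @param trace a trace from [pk_simulate()] (or any data frame with
#'   `time_h`, `serum_mg_per_L`, `cum_dose_mg`).
#' @param eval_range length-2 evaluation range (mg/L).
#' @param window length-2 evaluation window (h); must be covered by the trace.
#' @param dose_metric see [trial_config()].
#' @return A one-row data frame with columns `MEAN`, `TIR`, `TBR`, `TAR`,
#'   `TA_lo`, `DOSE`.
#' @examples
#' tr <- data.frame(time_h = c(0, 30), serum_mg_per_L = c(48, 48),
#'                  cum_dose_mg = c(0, 12000))
#' compute_metrics(tr) # TIR 100, MEAN 48, DOSE 400
#' @export
compute_metrics <- function(trace, eval_range = c(32, 64), window = c(0, 30),
                            dose_metric = "mean_rate") {
  stopifnot(window[2] > window[1])
  if (min(trace$time_h) > window[1] + 1e-9 ||
      max(trace$time_h) < window[2] - 1e-9)
    stop("trace does not cover the evaluation window")
  sel <- trace$time_h >= window[1] - 1e-9 & trace$time_h <= window[2] + 1e-9
  t <- trace$time_h[sel]
  y <- trace$serum_mg_per_L[sel]
  width <- window[2] - window[1]
  lo <- eval_range[1]; hi <- eval_range[2]

  tir <- band_measure(t, y, lo, hi)
  tbr <- band_measure(t, y, -Inf, lo, include_hi = FALSE)
  tar <- band_measure(t, y, hi, Inf, include_lo = FALSE)
  ta_lo <- band_measure(t, y, lo, Inf)
  mean_conc <- sum(diff(t) * (y[-length(y)] + y[-1]) / 2) / width

  cum <- stats::approx(trace$time_h, trace$cum_dose_mg, xout = window)$y
  dose <- if (dose_metric == "mean_rate") {
    (cum[2] - cum[1]) / width
  } else {
    edges <- seq(window[1], window[2], by = 1)
    ce <- stats::approx(trace$time_h, trace$cum_dose_mg, xout = edges)$y
    stats::median(diff(ce))
  }
  data.frame(MEAN = mean_conc, TIR = 100 * tir / width,
             TBR = 100 * tbr / width, TAR = 100 * tar / width,
             TA_lo = 100 * ta_lo / width, DOSE = dose)
}

#' Closed-loop co-simulation of one patient
#'
#' Couples the PK plant, the ISF sensor, the delayed one-point calibration
#' and the constrained PID controller at the sensor sampling period. The
#' loading dose and open-loop basal run until the controller start; from then
#' on, at every sample the ISF reading is calibrated to serum scale, the
#' controller commands a rate, and the plant is advanced to the next sample.
#' Recalibration happens on the sensor spec's interval using the serum
#' measurement drawn one turnaround-delay earlier; a calibration-factor jump
#' beyond the reset threshold zeroes the PID integral window.
#'
#' @param patient a `virtual_patient` from [sample_population()].
#' @param pcfg a [protocol_config()].
#' @param pid_cfg a [pid_config()].
#' @param s_spec a [sensor_spec()].
#' @param output_step dense trace resolution (h).
#' @return A list with `trace` (a simulation trace), `controller_log`,
#'   `measurement_log`, the final `calibration` and `pid_state`.
#' @export
run_closed_loop_patient <- function(patient, pcfg = protocol_config(),
                                    pid_cfg = pid_config(),
                                    s_spec = sensor_spec(),
                                    output_step = 0.1) {
  mod <- ke_modulator(patient)
  scaf <- closed_loop_scaffold(pcfg)
  dt <- s_spec$sampling_period_h
  horizon <- pcfg$horizon_h
  start <- scaf$controller_start_h
  sample_times <- seq(0, horizon - dt / 2, by = dt)
  is_cal_time <- function(t) t >= start - 1e-9 &&
    abs((t - start) / s_spec$recal_interval_h -
          round((t - start) / s_spec$recal_interval_h)) < 1e-9

  state <- c(0, 0, 0)
  cal <- calibration_state()
  pstate <- pid_state(pid_cfg, u_prev = scaf$basal_rate)
  M_isf_log <- M_serum_log <- rep(NA_real_, length(sample_times))
  ctrl_log <- vector("list", length(sample_times))
  meas_log <- vector("list", length(sample_times))
  times_out <- list(); states_out <- list(); rates_out <- list()
  cum_dose <- 0; cum_out <- list()

  for (k in seq_along(sample_times)) {
    t <- sample_times[k]
    true_serum <- state[1] / patient$params$V
    true_isf <- state[2] / patient$params$Visf
    M_isf_log[k] <- measure_isf(true_isf, s_spec)
    if (is_cal_time(t + s_spec$delay_h))
      M_serum_log[k] <- measure_serum(true_serum, s_spec)

    if (t >= start - 1e-9) {
      reset <- FALSE
      if (is_cal_time(t)) {
        k_del <- k - round(s_spec$delay_h / dt)
        if (k_del >= 1L && !is.na(M_serum_log[k_del])) {
          cal <- calibrate_sensor(cal, M_serum_log[k_del], M_isf_log[k_del],
                                  t, s_spec)
          reset <- isTRUE(cal$reset_triggered)
          meas_log[[k]] <- data.frame(time_h = t, M_isf = M_isf_log[k_del],
                                      M_serum = M_serum_log[k_del],
                                      m = cal$m,
                                      discrepancy_frac = cal$discrepancy,
                                      reset_triggered = reset)
        }
      }
      C_V <- controller_measurement(M_isf_log[k], cal)
      res <- pid_step(C_V, t, pid_cfg, pstate, reset_integral = reset)
      u <- res$u
      pstate <- res$state
      ctrl_log[[k]] <- res$log
      pieces <- data.frame(t0 = t, t1 = t + dt, rate = u)
    } else {
      # open-loop scaffold; split the step at loading-schedule breakpoints
      bp <- sort(unique(c(t, t + dt,
                          scaf$loading$end_h[scaf$loading$end_h > t &
                                               scaf$loading$end_h < t + dt])))
      pieces <- data.frame(t0 = bp[-length(bp)], t1 = bp[-1],
                           rate = schedule_rate_at(scaf$loading,
                                                   bp[-length(bp)]))
    }

    for (j in seq_len(nrow(pieces))) {
      t0 <- pieces$t0[j]; t1 <- pieces$t1[j]; r <- pieces$rate[j]
      tt <- sort(unique(c(t0, seq(ceiling(t0 / output_step) * output_step,
                                  t1, by = output_step), t1)))
      tt <- tt[tt >= t0 - 1e-12 & tt <= t1 + 1e-12]
      x <- pk_advance(state, t0, t1, r, patient$params, mod, times = tt)
      state <- x[nrow(x), ]
      keep <- seq_along(tt)[-length(tt)]
      times_out[[length(times_out) + 1L]] <- tt[keep]
      states_out[[length(states_out) + 1L]] <- x[keep, , drop = FALSE]
      rates_out[[length(rates_out) + 1L]] <- rep(r, length(keep))
      cum_out[[length(cum_out) + 1L]] <- cum_dose + r * (tt[keep] - t0)
      cum_dose <- cum_dose + r * (t1 - t0)
    }
  }

  tm <- c(unlist(times_out), horizon)
  xs <- rbind(do.call(rbind, states_out), state)
  xs[xs < 0] <- 0
  tr <- data.frame(
    time_h = tm,
    rate_mg_per_h = c(unlist(rates_out), 0),
    X1_mg = xs[, 1], X2_mg = xs[, 2], X3_mg = xs[, 3],
    serum_mg_per_L = xs[, 1] / patient$params$V,
    isf_mg_per_L = xs[, 2] / patient$params$Visf,
    cum_dose_mg = c(unlist(cum_out), cum_dose)
  )
  class(tr) <- c("simulation_trace", "data.frame")
  list(trace = tr,
       controller_log = do.call(rbind, ctrl_log),
       measurement_log = do.call(rbind, meas_log),
       calibration = cal, pid_state = pstate)
}

## TDM-titrated arm for one patient: the serum sampler re-simulates the
## schedule built so far and applies the assay error (same 5% CV as the
## calibration assay).
run_titrated_patient <- function(patient, pcfg = protocol_config(),
                                 s_spec = sensor_spec(), output_step = 0.1) {
  mod <- ke_modulator(patient)
  sampler <- function(t_sample, sched) {
    tr <- pk_simulate(patient$params, sched, horizon = t_sample,
                      output_step = t_sample, ke_modulator = mod)
    measure_serum(tr$serum_mg_per_L[nrow(tr)], s_spec)
  }
  sched <- protocol3_titrated(pcfg, sampler)
  tr <- pk_simulate(patient$params, sched, horizon = pcfg$horizon_h,
                    output_step = output_step, ke_modulator = mod)
  attr(tr, "schedule") <- sched
  tr
}

#' Simulate one intervention arm over a cohort
#'
#' Runs every patient independently with a per-patient seeded noise stream
#' (derived from the patient's `noise_seed` and the arm, so arms are
#' statistically independent but reproducible). The closed-loop arm
#' co-simulates plant, sensor, calibration and controller at the sensor
#' sampling period; the titrated arm co-simulates the 6-hourly TDM loop.
#'
#' @param arm one of `"bolus"`, `"rate"`, `"rate-titrate"`, `"closed"`.
#' @param cohort a cohort from [sample_population()].
#' @param tcfg a [trial_config()].
#' @param pcfg a [protocol_config()].
#' @param pid_cfg a [pid_config()] (closed arm only).
#' @param s_spec a [sensor_spec()].
#' @param keep_traces retain per-patient traces in the result.
#' @return A list with `metrics` (one row per patient) and, if requested,
#'   `traces` (list of simulation traces).
#' @export
run_arm <- function(arm = c("bolus", "rate", "rate-titrate", "closed"),
                    cohort, tcfg = trial_config(), pcfg = protocol_config(),
                    pid_cfg = pid_config(), s_spec = sensor_spec(),
                    keep_traces = FALSE) {
  arm <- match.arg(arm)
  stopifnot(length(cohort) >= 1L)
  arm_offset <- c(bolus = 1L, rate = 2L, `rate-titrate` = 3L, closed = 4L)[arm]
  traces <- vector("list", length(cohort))
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    set.seed((p$noise_seed + 7919L * arm_offset) %% .Machine$integer.max)
    tr <- tryCatch(
      switch(arm,
        bolus = pk_simulate(p$params, protocol1_bolus(pcfg),
                            horizon = tcfg$horizon_h,
                            output_step = tcfg$output_step,
                            ke_modulator = ke_modulator(p)),
        rate = pk_simulate(p$params, protocol2_continuous(pcfg),
                           horizon = tcfg$horizon_h,
                           output_step = tcfg$output_step,
                           ke_modulator = ke_modulator(p)),
        `rate-titrate` = run_titrated_patient(p, pcfg, s_spec,
                                              tcfg$output_step),
        closed = run_closed_loop_patient(p, pcfg, pid_cfg, s_spec,
                                         tcfg$output_step)$trace),
      error = function(e) stop(sprintf("arm '%s', patient %d: %s",
                                       arm, p$id, conditionMessage(e))))
    m <- compute_metrics(tr, tcfg$eval_range, c(0, tcfg$horizon_h),
                         tcfg$dose_metric)
    rows[[i]] <- cbind(data.frame(arm = arm, patient = p$id), m)
    if (keep_traces) traces[[i]] <- tr
  }
  out <- list(metrics = do.call(rbind, rows))
  if (keep_traces) out$traces <- traces
  out
}

#' Pairwise Wilcoxon signed-rank comparisons with Holm correction
#'
#' For each metric, every pair of arms is compared with a two-sided paired
#' Wilcoxon signed-rank test (exact when the sample permits, normal
#' approximation otherwise, as in `stats::wilcox.test`; zero differences are
#' dropped per the standard signed-rank convention). Holm's step-down
#' adjustment is applied within each metric's family of pairwise tests
#' (optionally across all metrics at once).
#'
#' @param metrics a metrics data frame from [run_arm()] results bound
#'   together (columns `arm`, `patient`, then metric columns).
#' @param metric_cols which metric columns to test.
#' @param family `"per_metric"` (default) or `"global"`.
#' @param alpha family-wise error rate for the significance flag.
#' @return A data frame with one row per metric and arm pair: the signed-rank
#'   statistic `V`, raw and Holm-adjusted p-values, and a significance flag.
#' @export
pairwise_tests <- function(metrics,
                           metric_cols = c("MEAN", "TIR", "TBR", "TAR",
                                           "TA_lo", "DOSE"),
                           family = c("per_metric", "global"),
                           alpha = 0.05) {
  family <- match.arg(family)
  arms <- unique(metrics$arm)
  pairs <- utils::combn(arms, 2, simplify = FALSE)
  rows <- list()
  for (mc in metric_cols) {
    for (pr in pairs) {
      x <- metrics[metrics$arm == pr[1], ]
      y <- metrics[metrics$arm == pr[2], ]
      x <- x[order(x$patient), mc]
      y <- y[order(y$patient), mc]
      res <- tryCatch(
        suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)),
        error = function(e) list(statistic = c(V = NA_real_), p.value = 1))
      # all-zero differences leave the statistic undefined: report p = 1
      p <- if (is.na(res$p.value)) 1 else res$p.value
      rows[[length(rows) + 1L]] <-
        data.frame(metric = mc, arm1 = pr[1], arm2 = pr[2],
                   V = unname(res$statistic), p_raw = p)
    }
  }
  tab <- do.call(rbind, rows)
  if (family == "per_metric") {
    tab$p_holm <- stats::ave(tab$p_raw, tab$metric,
                             FUN = function(p) stats::p.adjust(p, "holm"))
  } else {
    tab$p_holm <- stats::p.adjust(tab$p_raw, "holm")
  }
  tab$significant <- tab$p_holm < alpha
  tab
}

#' Population summary of per-patient metrics
#'
#' Median, interquartile range and 5th/95th percentiles per arm and metric
#' (linear-interpolation quantiles, `stats::quantile` type 7).
#'
#' @param metrics a combined metrics data frame (see [pairwise_tests()]).
#' @param metric_cols metric columns to summarise.
#' @return A data frame with columns `arm`, `metric`, `median`, `q25`, `q75`,
#'   `p5`, `p95`.
#' @export
summarize_trial <- function(metrics,
                            metric_cols = c("MEAN", "TIR", "TBR", "TAR",
                                            "TA_lo", "DOSE")) {
  stopifnot(nrow(metrics) >= 1L)
  rows <- list()
  for (a in unique(metrics$arm)) {
    for (mc in metric_cols) {
      v <- metrics[metrics$arm == a, mc]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.05, 0.95), type = 7,
                           names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(arm = a, metric = mc, median = q[2], q25 = q[1],
                   q75 = q[3], p5 = q[4], p95 = q[5])
    }
  }
  do.call(rbind, rows)
}

#' Run the full in-silico trial
#'
#' Samples a seeded virtual cohort, runs the requested intervention arms,
#' computes per-patient metrics, population summaries and the pairwise
#' Wilcoxon / Holm comparison table.
#'
#' @param seed cohort and noise seed.
#' @param arms arms to run.
#' @param tcfg,pcfg,pid_cfg,s_spec,pop_spec,ivar component configurations.
#' @param keep_traces retain per-patient traces.
#' @return A list of class `trial_result` with `cohort`, `metrics`,
#'   `summary`, `stats` and optionally `traces`.
#' @examples
#' \donttest{
#' res <- run_trial(seed = 1, arms = c("bolus", "rate"))
#' res$summary
#' }
#' @export
run_trial <- function(seed = 1L,
                      arms = c("bolus", "rate", "rate-titrate", "closed"),
                      tcfg = trial_config(), pcfg = protocol_config(),
                      pid_cfg = pid_config(), s_spec = sensor_spec(),
                      pop_spec = NULL, ivar = intraday_spec(),
                      keep_traces = FALSE) {
  if (is.null(pop_spec)) pop_spec <- population_spec(n_patients = tcfg$n_patients)
  cohort <- sample_population(pop_spec, ivar, seed)
  arm_res <- lapply(arms, run_arm, cohort = cohort, tcfg = tcfg, pcfg = pcfg,
                    pid_cfg = pid_cfg, s_spec = s_spec,
                    keep_traces = keep_traces)
  metrics <- do.call(rbind, lapply(arm_res, `[[`, "metrics"))
  out <- list(cohort = cohort, metrics = metrics,
              summary = summarize_trial(metrics),
              stats = if (length(arms) >= 2) pairwise_tests(metrics) else NULL)
  if (keep_traces) out$traces <- lapply(arm_res, `[[`, "traces")
  class(out) <- "trial_result"
  out
}

#' Write trial outputs to a directory
#'
#' Emits `cohort.json`, `metrics.csv` (patient x metric), `summary.json`
#' (median/IQR/percentile table) and `stats.csv` (pairwise comparisons).
#'
#' @param result a `trial_result` from [run_trial()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_json(result$cohort, file.path(dir, "cohort.json"))
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       digits = NA, dataframe = "rows")
  if (!is.null(result$stats))
    utils::write.csv(result$stats, file.path(dir, "stats.csv"),
                     row.names = FALSE)
  invisible(dir)
}
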