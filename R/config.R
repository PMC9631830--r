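#' Default platform configuration
#'
#' A single nested list covering every tunable parameter of the platform:
#' population distribution moments, intra-day variability, sensor and assay
#' errors, controller gains and constraints, protocol doses and trial
#' settings. `load_config()` reads a YAML or JSON file and overrides any
#' subset of these defaults (unknown keys are an error).
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    population = list(n_patients = 20,
                      V = c(17.0, 8.0), CL = c(14.0, 8.4),
                      Visf = c(12.4, 12.8), KCP = c(2.0, 1.0),
                      KPC = c(1.5, 0.75), Kisf = c(1.0, 0.5),
                      Kub = c(1.5, 0.75), family = "lognormal"),
    intraday = list(amplitude_range = c(0, 0.3), period_h = 24),
    sensor = list(isf_cv = 0.10, serum_cv = 0.05, delay_h = 1,
                  recal_interval_h = 6, sampling_period_h = 0.5,
                  detection_floor = 1, reset_threshold = 0.30),
    pid = list(Kp = 5, Td = 1, Ti = 0.5, dt = 0.5, window_h = 6,
               setpoint = 60, control_range = c(20, 100), basal = 300,
               max_rate_multiple = 5, min_rate_frac = 0.5,
               error_sign = "negative_feedback", textbook_gains = FALSE),
    protocol = list(bolus_mg = 4000, bolus_duration_h = 1 / 3,
                    interval_h = 6, continuous_rate = 4000 / 6,
                    titration_step_mg = 500, titration_target = 60,
                    serum_delay_h = 1, horizon_h = 30, basal_rate = 300,
                    controller_start_h = 2.5),
    trial = list(n_patients = 20, horizon_h = 30, eval_range = c(32, 64),
                 control_range = c(20, 100), output_step = 0.1,
                 dose_metric = "mean_rate")
  )
}

#' @rdname default_config
#' @param path path to a YAML (`.yml`/`.yaml`, requires the `yaml` package)
#'   or JSON configuration file overriding any subset of the defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  over <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configuration")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (section in names(over)) {
    if (!section %in% names(cfg))
      stop("unknown configuration section: ", section)
    for (key in names(over[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop("unknown configuration key: ", section, ".", key)
      cfg[[section]][[key]] <- over[[section]][[key]]
    }
  }
  cfg
}

#' Instantiate component configurations from a nested configuration list
#'
#' @param cfg a list from [default_config()] / [load_config()].
#' @return A list with `pop_spec`, `ivar`, `s_spec`, `pid_cfg`, `pcfg`,
#'   `tcfg` ready to pass to [run_trial()].
#' @export
build_configs <- function(cfg = default_config()) {
  list(
    pop_spec = do.call(population_spec,
                       c(cfg$population["n_patients"],
                         cfg$population[c("V", "CL", "Visf", "KCP", "KPC",
                                          "Kisf", "Kub")],
                         cfg$population["family"])),
    ivar = do.call(intraday_spec, cfg$intraday),
    s_spec = do.call(sensor_spec, cfg$sensor),
    pid_cfg = do.call(pid_config, cfg$pid),
    pcfg = do.call(protocol_config, cfg$protocol),
    tcfg = do.call(trial_config, cfg$trial)
  )
}
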