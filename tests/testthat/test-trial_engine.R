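make_trace <- function(t, serum, dose_rate = 400) {
  data.frame(time_h = t, serum_mg_per_L = serum,
             cum_dose_mg = dose_rate * t)
}

test_that("metrics on simple traces match hand computation", {
  flat48 <- make_trace(c(0, 30), c(48, 48))
  m <- compute_metrics(flat48)
  expect_equal(m$TIR, 100)
  expect_equal(m$TBR, 0)
  expect_equal(m$TAR, 0)
  expect_equal(m$TA_lo, 100)
  expect_equal(m$MEAN, 48)
  expect_equal(m$DOSE, 400)

  ramp <- make_trace(c(0, 30), c(0, 96))
  m <- compute_metrics(ramp)
  expect_equal(m$TBR, 100 / 3, tolerance = 1e-9)
  expect_equal(m$TIR, 100 / 3, tolerance = 1e-9)
  expect_equal(m$TAR, 100 / 3, tolerance = 1e-9)
  expect_equal(m$MEAN, 48)

  flat70 <- make_trace(c(0, 30), c(70, 70))
  m <- compute_metrics(flat70)
  expect_equal(m$TAR, 100)
  expect_equal(m$TA_lo, 100)
  expect_equal(m$TIR, 0)
})

test_that("sub-sample range crossings are counted at interpolated times", {
  # serum linear from 60 to 68 over one 0.5-h step: crossing 64 at midpoint
  tr <- make_trace(c(0, 29.5, 30), c(60, 60, 68))
  m <- compute_metrics(tr)
  expect_equal(m$TAR, 100 * 0.25 / 30, tolerance = 1e-9)
})

test_that("metric closure and range monotonicity hold on random traces", {
  set.seed(5)
  for (rep in 1:10) {
    t <- seq(0, 30, by = 0.1)
    y <- pmax(0, 60 + cumsum(rnorm(length(t), 0, 3)))
    tr <- make_trace(t, y)
    m <- compute_metrics(tr)
    expect_equal(m$TIR + m$TBR + m$TAR, 100, tolerance = 1e-6)
    expect_equal(m$TA_lo, m$TIR + m$TAR, tolerance = 1e-6)
    m_wide <- compute_metrics(tr, eval_range = c(20, 100))
    expect_gte(m_wide$TIR + 1e-9, m$TIR)
  }
})

test_that("interpolating metrics agree with a brute-force fine-grid counter", {
  coh <- sample_population(population_spec(n_patients = 2), seed = 6)
  for (p in coh) {
    tr <- pk_simulate(p$params, protocol1_bolus(), horizon = 30,
                      output_step = 0.1, ke_modulator = ke_modulator(p))
    m <- compute_metrics(tr)
    b <- brute_metrics(tr)
    expect_lt(abs(m$TIR - b[["TIR"]]), 0.1)
    expect_lt(abs(m$TBR - b[["TBR"]]), 0.1)
    expect_lt(abs(m$TAR - b[["TAR"]]), 0.1)
  }
})

test_that("windows not covered by the trace are rejected", {
  tr <- make_trace(c(0, 10), c(50, 50))
  expect_error(compute_metrics(tr, window = c(0, 30)), "cover")
})

test_that("paired Wilcoxon p-values match full sign enumeration for small n", {
  # all-positive differences 1..6: two-sided exact p = 2/64
  x <- c(11, 12, 13, 14, 15, 16); y <- c(10, 10, 10, 10, 10, 10)
  expect_equal(wilcoxon_enum_p(x, y), 0.03125)
  expect_equal(suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value),
               0.03125)
  set.seed(9)
  for (n in c(6, 8, 10)) {
    a <- round(rnorm(n, 50, 10), 2)
    b <- round(a + rnorm(n, 1, 4), 2)
    expect_equal(suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value),
                 wilcoxon_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("pairwise comparison table applies Holm within each metric", {
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))

  metrics <- rbind(
    data.frame(arm = "a", patient = 1:8, TIR = c(10, 12, 11, 14, 9, 13, 10, 12)),
    data.frame(arm = "b", patient = 1:8, TIR = c(30, 28, 33, 31, 29, 35, 30, 28)),
    data.frame(arm = "c", patient = 1:8, TIR = c(30, 28, 33, 31, 29, 35, 30, 28)))
  tab <- pairwise_tests(metrics, metric_cols = "TIR")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_holm >= tab$p_raw))
  # identical paired vectors: p = 1, not significant
  bc <- tab[tab$arm1 == "b" & tab$arm2 == "c", ]
  expect_equal(bc$p_raw, 1)
  expect_false(bc$significant)
  ab <- tab[tab$arm1 == "a" & tab$arm2 == "b", ]
  expect_true(ab$significant)
})

test_that("population summaries use linear-interpolation quantiles", {
  metrics <- data.frame(arm = "x", patient = 1:20, TIR = as.numeric(1:20))
  s <- summarize_trial(metrics, metric_cols = "TIR")
  expect_equal(s$median, 10.5)
  expect_equal(s$q25, 5.75)   # type-7 quantile of 1..20
  expect_equal(s$q75, 15.25)
  expect_equal(s$p5, 1.95)
  expect_equal(s$p95, 19.05)

  one <- summarize_trial(data.frame(arm = "x", patient = 1, TIR = 42),
                         metric_cols = "TIR")
  expect_equal(one$median, 42)
  expect_equal(one$q25, 42)
  expect_error(summarize_trial(metrics[0, ]), "nrow")
})

test_that("the bolus arm shows five peak/trough cycles", {
  spec <- population_spec(n_patients = 1, V = c(17, 0), CL = c(14, 0),
                          Visf = c(12.4, 0), KCP = c(2, 0), KPC = c(1.5, 0),
                          Kisf = c(1, 0), Kub = c(1.5, 0))
  coh <- sample_population(spec, intraday_spec(c(0, 0)), seed = 1)
  res <- run_arm("bolus", coh, keep_traces = TRUE)
  s <- res$traces[[1]]$serum_mg_per_L
  t <- res$traces[[1]]$time_h
  # local maxima separated by the 6-h dosing interval
  peaks <- t[which(diff(sign(diff(s))) == -2) + 1]
  expect_equal(length(peaks), 5)
  expect_equal(round(diff(peaks)), rep(6, 4))
})

test_that("arm runs are bitwise reproducible under the same cohort seed", {
  coh <- sample_population(population_spec(n_patients = 2), seed = 12)
  a <- run_arm("closed", coh)
  b <- run_arm("closed", coh)
  expect_identical(a$metrics, b$metrics)
})

test_that("the closed loop settles near the set point with a noise-free sensor", {
  spec <- population_spec(n_patients = 1, V = c(17, 0), CL = c(14, 0),
                          Visf = c(12.4, 0), KCP = c(2, 0), KPC = c(1.5, 0),
                          Kisf = c(1, 0), Kub = c(1.5, 0))
  coh <- sample_population(spec, intraday_spec(c(0, 0)), seed = 2)
  res <- run_closed_loop_patient(coh[[1]],
                                 s_spec = sensor_spec(isf_cv = 0, serum_cv = 0))
  tr <- res$trace
  late <- tr$serum_mg_per_L[tr$time_h >= 15]
  # within the evaluation range and near the controller's achievable
  # equilibrium for this plant (finite-window integral leaves an offset)
  expect_true(all(late > 32 & late < 64))
  expect_lt(diff(range(late)), 10)
})

test_that("trial outputs round-trip to disk", {
  coh_dir <- tempfile()
  res <- run_trial(seed = 3, arms = c("bolus", "rate"),
                   tcfg = trial_config(n_patients = 4),
                   pop_spec = population_spec(n_patients = 4))
  write_trial_outputs(res, coh_dir)
  expect_true(file.exists(file.path(coh_dir, "metrics.csv")))
  expect_true(file.exists(file.path(coh_dir, "stats.csv")))
  back <- read.csv(file.path(coh_dir, "metrics.csv"))
  expect_equal(nrow(back), 8)
})

test_that("configuration files override defaults and reject unknown keys", {
  cfg <- default_config()
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(pid = list(Kp = 7)), f, auto_unbox = TRUE)
  over <- load_config(f)
  expect_equal(over$pid$Kp, 7)
  expect_equal(over$pid$Td, cfg$pid$Td)
  jsonlite::write_json(list(pid = list(nope = 1)), f, auto_unbox = TRUE)
  expect_error(load_config(f), "unknown configuration key")
  cc <- build_configs(over)
  expect_equal(cc$pid_cfg$Kp, 7)
  expect_s3_class(cc$pop_spec, "population_spec")
})
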