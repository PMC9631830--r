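test_that("derivatives follow the three-compartment mass balance", {
  p <- ref_params()
  expect_equal(pk_derivatives(c(0, 0, 0), 0, p), c(0, 0, 0))

  # single-exponential limit: only elimination acts
  p1 <- pk_parameters(V = 10, Visf = 1, Ke_base = 0.5,
                      KCP = 1e-12, KPC = 1e-12, Kisf = 1e-12, Kub = 1e-12)
  expect_equal(pk_derivatives(c(100, 0, 0), 0, p1), c(-50, 0, 0),
               tolerance = 1e-9)

  # hand arithmetic on the stated mass balance
  p2 <- pk_parameters(V = 17, Visf = 12.4, Ke_base = 0.8,
                      KCP = 0.3, KPC = 0.2, Kisf = 0.4, Kub = 0.6)
  expect_equal(pk_derivatives(c(10, 20, 30), 300, p2), c(303, -8, -3))

  expect_error(pk_derivatives(c(NaN, 0, 0), 0, p), "finite")
})

test_that("zero input gives an identically-zero trace", {
  tr <- pk_simulate(ref_params(), infusion_schedule(), horizon = 10,
                    output_step = 0.5)
  expect_true(all(tr$X1_mg == 0 & tr$X2_mg == 0 & tr$X3_mg == 0))
  expect_true(all(tr$cum_dose_mg == 0))
})

test_that("constant infusion converges to the analytic steady state", {
  p <- ref_params()
  expect_equal(steady_state_serum(p, 0), 0)
  expect_equal(steady_state_serum(p, 840), 60)
  expect_equal(steady_state_serum(p, 666.7), 47.62, tolerance = 1e-3)

  tr <- pk_simulate(p, infusion_schedule(0, 200, 840), horizon = 200,
                    output_step = 1)
  expect_equal(tail(tr$serum_mg_per_L, 1), 60, tolerance = 1e-3)
})

test_that("mass is conserved when elimination is switched off", {
  set.seed(11)
  for (rep in 1:5) {
    p <- pk_parameters(V = runif(1, 5, 30), Visf = runif(1, 2, 25),
                       Ke_base = 1e-10, KCP = runif(1, 0.5, 3),
                       KPC = runif(1, 0.5, 3), Kisf = runif(1, 0.2, 2),
                       Kub = runif(1, 0.2, 2))
    starts <- cumsum(runif(3, 0.5, 2))
    sched <- infusion_schedule(starts, starts + 0.3, runif(3, 100, 5000))
    tr <- pk_simulate(p, sched, horizon = 6, output_step = 0.25)
    total <- tr$X1_mg + tr$X2_mg + tr$X3_mg
    keep <- tr$cum_dose_mg > 0
    expect_lt(max(abs(total[keep] - tr$cum_dose_mg[keep]) /
                    tr$cum_dose_mg[keep]), 1e-6)
  }
})

test_that("adaptive integration matches a tiny-step explicit Euler oracle", {
  set.seed(7)
  for (rep in 1:3) {
    p <- pk_parameters(V = runif(1, 8, 25), Visf = runif(1, 4, 20),
                       CL = runif(1, 5, 25), KCP = runif(1, 0.5, 3),
                       KPC = runif(1, 0.5, 3), Kisf = runif(1, 0.3, 2),
                       Kub = runif(1, 0.3, 2))
    sched <- infusion_schedule(c(0, 2, 4), c(1, 3, 5.5),
                               runif(3, 200, 4000))
    mod <- ke_modulator(list(A = 0.25, P = 24, phi = 1))
    tr <- pk_simulate(p, sched, horizon = 6, output_step = 0.1,
                      ke_modulator = mod)
    orc <- euler_simulate(p, sched, horizon = 6, step = 1e-4, ke_mult = mod)
    ours <- approx(tr$time_h, tr$X1_mg, xout = orc$time)$y
    scale <- max(orc$X[, 1])
    expect_lt(max(abs(ours - orc$X[, 1]) / scale), 1e-3)
  }
})

test_that("the model is linear: doubling the schedule doubles the trace", {
  p <- ref_params()
  sched <- infusion_schedule(c(0, 3), c(1, 4), c(2000, 500))
  sched2 <- infusion_schedule(c(0, 3), c(1, 4), c(4000, 1000))
  tr1 <- pk_simulate(p, sched, horizon = 6, output_step = 0.25)
  tr2 <- pk_simulate(p, sched2, horizon = 6, output_step = 0.25)
  expect_equal(tr2$serum_mg_per_L, 2 * tr1$serum_mg_per_L, tolerance = 1e-6)
})

test_that("cumulative dose equals the time-integral of the applied rate", {
  sched <- infusion_schedule(c(0, 6, 12), c(1 / 3, 6 + 1 / 3, 20),
                             c(12000, 12000, 300))
  tr <- pk_simulate(ref_params(), sched, horizon = 24, output_step = 0.5)
  expect_true(all(diff(tr$time_h) > 0))
  expect_equal(tail(tr$cum_dose_mg, 1), schedule_total_dose(sched, 24))
  ix <- which(tr$time_h == 12)
  expect_equal(tr$cum_dose_mg[ix], 8000)
})

test_that("schedule validation and serialization round-trip", {
  expect_error(infusion_schedule(c(0, 0.5), c(1, 2), c(10, 10)), "overlap")
  expect_error(infusion_schedule(0, 1, -5), "non-negative")
  expect_error(infusion_schedule(1, 1, 5), "end_h")

  sched <- protocol1_bolus()
  f <- tempfile(fileext = ".json")
  write_schedule_json(sched, f)
  back <- read_schedule_json(f)
  expect_equal(as.data.frame(unclass(back)), as.data.frame(unclass(sched)))

  tr <- pk_simulate(ref_params(), sched, horizon = 2, output_step = 0.5)
  f2 <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f2)
  expect_equal(read_trace_csv(f2)$serum_mg_per_L, tr$serum_mg_per_L,
               tolerance = 1e-9)
})
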