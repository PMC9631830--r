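test_that("gain coefficients follow Kd = Kp/Td and Ki = Kp*Ti", {
  cfg <- pid_config(Kp = 5, Td = 1, Ti = 0.5)
  expect_equal(cfg$Ki, 2.5)
  expect_equal(cfg$Kd, 5)
  cfg_tb <- pid_config(Kp = 5, Td = 1, Ti = 0.5, textbook_gains = TRUE)
  expect_equal(cfg_tb$Ki, 10)
  expect_equal(cfg_tb$Kd, 5)
})

test_that("zero error yields the basal rate", {
  for (sign in c("negative_feedback", "as_printed")) {
    cfg <- pid_config(error_sign = sign)
    st <- pid_state(cfg)
    for (k in 1:5) {
      res <- pid_step(C_V = cfg$setpoint, t_h = 2.5 + 0.5 * k, cfg, st)
      st <- res$state
      expect_equal(res$u, cfg$basal)
      expect_equal(res$log$constraint_applied, "none")
    }
  }
})

test_that("the discrete law reproduces the hand-computed worked example", {
  # history e = -10 then e = -8 (all earlier zero), as-printed sign:
  # u = 300 + 5*(-8) + 2.5*(-18)*0.5 + 5*((-8+10)/0.5) = 257.5 mg/h
  cfg <- pid_config(Kp = 5, Td = 1, Ti = 0.5, error_sign = "as_printed")
  st <- pid_state(cfg, u_prev = 300)
  st <- pid_step(60, 0, cfg, st)$state                    # e = 0 history
  st <- pid_step(cfg$setpoint - 10, 0.5, cfg, st)$state   # e = -10
  res <- pid_step(cfg$setpoint - 8, 1.0, cfg, st)         # e = -8
  expect_equal(res$u, 257.5)
  expect_equal(res$log$u_raw, 257.5)
})

test_that("safety constraints clip in the prescribed order", {
  cfg <- pid_config()
  st <- pid_state(cfg, u_prev = 300)

  # halt above the upper control bound, regardless of history
  expect_equal(apply_constraints(400, C_V = 101, cfg, st)$u, 0)
  expect_equal(apply_constraints(400, C_V = 101, cfg, st)$constraint, "halt")
  res <- pid_step(110, 3, cfg, st)
  expect_equal(res$u, 0)

  # cap at 5x basal
  con <- apply_constraints(2000, C_V = 50, cfg, st)
  expect_equal(con$u, 1500)
  expect_equal(con$constraint, "cap")

  # floor at 50% of the previous commanded rate
  con <- apply_constraints(100, C_V = 50, cfg, st)
  expect_equal(con$u, 150)
  expect_equal(con$constraint, "floor")

  # inactive constraints leave the rate untouched
  expect_equal(apply_constraints(400, C_V = 50, cfg, st)$u, 400)

  # rates never negative even with a tiny previous rate
  st0 <- pid_state(cfg, u_prev = 0)
  expect_gte(apply_constraints(-50, C_V = 50, cfg, st0)$u, 0)
})

test_that("halting is not latched and the floor references the last nonzero rate", {
  cfg <- pid_config()
  st <- pid_state(cfg, u_prev = 400)
  res <- pid_step(120, 3, cfg, st)      # halt
  expect_equal(res$u, 0)
  expect_equal(res$state$u_prev, 400)   # nonzero-rate memory survives a halt
  res2 <- pid_step(60, 3.5, cfg, res$state)
  expect_gte(res2$u, 0.5 * 400 * 0 + 0) # must return a rate
  expect_gt(res2$u, 0)
})

test_that("integral reset zeroes the error window but not the rate memory", {
  cfg <- pid_config(error_sign = "as_printed")
  st <- pid_state(cfg, u_prev = 777)
  for (k in 1:6) st <- pid_step(80, k * 0.5, cfg, st)$state
  expect_gt(sum(abs(st$errors)), 0)
  u_prev_before <- st$u_prev
  expect_gt(u_prev_before, 0)
  res <- pid_step(cfg$setpoint, 3.5, cfg, st, reset_integral = TRUE)
  expect_equal(res$log$I_term, 0)
  expect_length(res$state$errors, 1)
  # rate memory survived the reset: the 50% floor still references it
  expect_equal(res$u, max(cfg$basal, 0.5 * u_prev_before))
})

test_that("the integral term is bounded by the sliding window", {
  cfg <- pid_config()
  st <- pid_state(cfg)
  max_e <- 0
  set.seed(31)
  for (k in 1:60) {
    cv <- runif(1, 0, 100)
    max_e <- max(max_e, abs(cv - cfg$setpoint))
    res <- pid_step(cv, k * 0.5, cfg, st)
    st <- res$state
    bound <- cfg$Ki * cfg$dt * cfg$n_window * max_e
    expect_lte(abs(res$log$I_term), bound + 1e-9)
  }
  expect_lte(length(st$errors), cfg$n_window)
})

test_that("the closed loop settles near the set point on a toy plant", {
  # one-compartment plant, Ke = 0.5 1/h, V = 15 L, noise-free sensing
  cfg <- pid_config()
  st <- pid_state(cfg, u_prev = 300)
  Ke <- 0.5; V <- 15
  C <- 0; u <- 300
  conc <- numeric(60)
  for (k in 1:60) {
    C <- toy_plant_step(C, u, Ke, V, cfg$dt)
    res <- pid_step(C, k * cfg$dt, cfg, st)
    st <- res$state
    u <- res$u
    conc[k] <- C
  }
  late <- conc[31:60]
  expect_true(all(abs(late - cfg$setpoint) / cfg$setpoint < 0.10))
  # no sustained oscillation growth
  expect_lte(diff(range(conc[46:60])), diff(range(conc[31:45])) + 1e-6)
})

test_that("identical measurement sequences give identical rate sequences", {
  cfg <- pid_config()
  run <- function() {
    st <- pid_state(cfg)
    sapply(c(55, 70, 40, 62, 58, 90, 101, 30), function(cv) {
      res <- pid_step(cv, 3, cfg, st)
      st <<- res$state
      res$u
    })
  }
  expect_identical(run(), run())
})

test_that("the adaptive-tuning hook is an identity that counts invocations", {
  cfg <- pid_config()
  cfg1 <- adapt_tuning(cfg)
  expect_equal(unclass(cfg1)[names(unclass(cfg))], unclass(cfg))
  cfg2 <- adapt_tuning(cfg1)
  expect_equal(attr(cfg2, "adapt_calls"), 2L)
  expect_equal(cfg2$Kp, cfg$Kp)
})
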