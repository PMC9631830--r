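# Independent oracles used to cross-check the implementation.

# Reference PK parameter set used across tests.
ref_params <- function() {
  pk_parameters(V = 17, Visf = 12.4, CL = 14,
                KCP = 2, KPC = 1.5, Kisf = 1, Kub = 1.5)
}

# Fixed-step explicit-Euler integration of the three-compartment model,
# written directly from the mass balance (independent of pk_simulate and of
# the compiled right-hand side).
euler_simulate <- function(params, schedule, horizon, step = 1e-4,
                           ke_mult = function(t) 1, initial = c(0, 0, 0)) {
  n <- ceiling(horizon / step)
  x <- initial
  t <- 0
  out_t <- seq(0, horizon, length.out = 61)
  out <- matrix(NA_real_, length(out_t), 3)
  out[1, ] <- x
  oi <- 2L
  for (i in seq_len(n)) {
    r <- schedule_rate_at(schedule, t)
    ke <- params$Ke_base * ke_mult(t)
    dx <- c(r + params$KPC * x[3] + params$Kub * x[2] -
              (ke + params$KCP + params$Kisf) * x[1],
            params$Kisf * x[1] - params$Kub * x[2],
            params$KCP * x[1] - params$KPC * x[3])
    x <- x + step * dx
    t <- t + step
    while (oi <= length(out_t) && t >= out_t[oi] - step / 2) {
      out[oi, ] <- x
      oi <- oi + 1L
    }
  }
  list(time = out_t, X = out)
}

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration of the
# 2^n sign assignments (zero differences dropped, |d| mid-ranked).
wilcoxon_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Brute-force metric counter: sample the piecewise-linear serum trace on a
# very fine grid and count samples per band.
brute_metrics <- function(trace, eval_range = c(32, 64), window = c(0, 30),
                          n_grid = 300001L) {
  tg <- seq(window[1], window[2], length.out = n_grid)
  y <- approx(trace$time_h, trace$serum_mg_per_L, xout = tg)$y
  c(TIR = 100 * mean(y >= eval_range[1] & y <= eval_range[2]),
    TBR = 100 * mean(y < eval_range[1]),
    TAR = 100 * mean(y > eval_range[2]),
    MEAN = mean(y))
}

# Exact one-compartment plant used as a toy closed-loop test bed:
# dC/dt = u/V - Ke*C, advanced analytically over one sampling period.
toy_plant_step <- function(C, u, Ke, V, dt) {
  C * exp(-Ke * dt) + u / (Ke * V) * (1 - exp(-Ke * dt))
}
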