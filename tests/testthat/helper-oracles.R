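# Independent oracles for the progress-curve machinery. These deliberately
# avoid the package's integrator/optimizer code paths.

# Continuous-time Michaelis-Menten depletion: solve the implicit equation
# ks*ln(s0/s) + (s0 - s) = vmax * t for s at each time (t in minutes),
# by root bracketing. Returns 0 once the zero-order budget is exhausted
# (for ks = 0 the solution reaches zero in finite time).
mm_implicit_oracle <- function(s0, vmax, ks, t_min) {
  vapply(t_min, function(tt) {
    if (tt <= 0 || vmax == 0) {
      return(s0)
    }
    f <- function(s) ks * log(s0 / s) + (s0 - s) - vmax * tt
    if (ks == 0 && s0 - vmax * tt <= 0) {
      return(0)
    }
    if (f(s0 * 1e-12) < 0) {
      return(0)
    }
    stats::uniroot(f, c(s0 * 1e-12, s0), tol = 1e-12)$root
  }, numeric(1))
}

# Exhaustive log-grid search for the best SSE of the depletion model against
# an observed series; the brute-force counterpart of the package optimizer.
grid_best_sse <- function(conc, dt = 1, n_grid = 200) {
  s0 <- conc[1]
  duration <- (length(conc) - 1) * dt
  vmax_grid <- exp(seq(log(1), log(1e5), length.out = n_grid))
  ks_grid <- exp(seq(log(0.5), log(s0 * 10), length.out = n_grid))
  best <- Inf
  for (v in vmax_grid) {
    for (k in ks_grid) {
      pred <- integrate_mm_depletion(s0, v, k, dt, duration)
      sse <- sum((conc - pred)^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# A minimal noiseless trace: one calibration addition then analyte pulses,
# constructed through the generator with noise switched off.
noiseless_trace <- function(..., seed = NULL) {
  simulate_mims_trace(mims_sim_params(..., noise = "none", seed = seed))
}
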