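# Independent oracles used across the suite. These deliberately avoid the
# package's own compiled code paths.

# Steady-state curve evaluated directly from its definition in plain R.
ss_ref <- function(p, v) {
  x <- (v - p$V_i_mV) / p$k_a_mV
  sp <- ifelse(x > 30, x, log1p(exp(x)))  # naive softplus is fine off-test
  p$theta_offset_mV + p$alpha * (v - p$V_i_mV) +
    (p$beta - p$alpha) * p$k_a_mV * sp
}

# Brute-force explicit-Euler integration of the threshold ODE on a grid
# `refine` times finer than the sampling grid (voltage interpolated linearly),
# returning values at the original sample times.
euler_threshold_ref <- function(v, dt, p, theta0, refine = 20) {
  n <- length(v)
  h <- dt / refine
  th <- numeric(n)
  th[1] <- cur <- theta0
  for (i in 1:(n - 1)) {
    for (k in 0:(refine - 1)) {
      # voltage held constant over the sampling interval, as in the model
      cur <- cur + h / p$tau_theta_ms * (ss_ref(p, v[i]) - cur)
    }
    th[i + 1] <- cur
  }
  th
}

# Maximum-cardinality one-to-one matching within delta, by exhaustive
# recursion (feasible for n <= 8 per train).
max_matching_ref <- function(rec, pred, delta) {
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (length(rec) - i + 1) <= best) return()
    if (i > length(rec)) {
      best <<- max(best, count)
      return()
    }
    # option: leave rec[i] unmatched
    recurse(i + 1L, used, count)
    for (j in seq_along(pred)) {
      if (!used[j] && abs(rec[i] - pred[j]) <= delta) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(pred)), 0L)
  best
}

# Gamma factor recomputed from its definition, independent of the package.
gamma_ref <- function(n_coinc, n_rec, n_pred, delta, duration) {
  nu <- n_rec / duration
  (n_coinc - 2 * nu * delta * n_pred) / ((n_rec + n_pred) / 2) /
    (1 - 2 * nu * delta)
}

# A short OU-driven subthreshold-like voltage trace (no spikes), for
# integrator tests.
ou_voltage_fixture <- function(duration_ms = 1000, dt = 1 / 42, seed = 42,
                               mean_mV = -65, sd_mV = 4, tau_ms = 3) {
  set.seed(seed)
  n <- floor(duration_ms / dt)
  a <- exp(-dt / tau_ms)
  dev <- stats::filter(sd_mV * sqrt(1 - a^2) * rnorm(n - 1), a,
                       method = "recursive", init = 0)
  voltage_trace(mean_mV + c(0, as.numeric(dev)), dt)
}
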