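#' Ornstein-Uhlenbeck injected current
#'
#' Gaussian colored noise with exponential autocorrelation, the standard
#' fluctuating-current drive for simulated neurons. Generated with the exact
#' discretization
#' \eqn{I_{n+1} = \mu + (I_n - \mu) e^{-dt/\tau_I} + \sigma
#' \sqrt{1 - e^{-2 dt/\tau_I}}\, \xi_n}, so the sampled process has exactly
#' the stationary moments regardless of `dt`.
#'
#' @param duration_ms Duration (ms).
#' @param dt_ms Sampling interval (ms); default the 42 kHz simulation rate.
#' @param mean_pA Stationary mean (pA); default 40.
#' @param sd_pA Stationary standard deviation (pA); default 120.
#' @param tau_ms Autocorrelation time constant (ms); default 3.
#' @param seed Integer seed; every source of randomness in the generators
#'   flows from it.
#' @return A tibble with columns `time_ms`, `i_pA`, carrying `dt_ms` as an
#'   attribute.
#' @export
ou_current <- function(duration_ms, dt_ms = 1 / 42, mean_pA = 40,
                       sd_pA = 120, tau_ms = 3, seed = 1L) {
  if (sd_pA < 0) abort("sd_pA must be >= 0")
  if (tau_ms <= 0) abort("tau_ms must be > 0")
  n <- floor(duration_ms / dt_ms)
  a <- exp(-dt_ms / tau_ms)
  b <- sd_pA * sqrt(1 - a^2)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  xi <- rnorm(n - 1)
  # recursive filter x[k] = a x[k-1] + b xi[k], x[1] = 0 (deviation from mean)
  dev <- c(0, as.numeric(stats::filter(b * xi, a, method = "recursive",
                                       init = 0)))
  out <- tibble(time_ms = (seq_len(n) - 1) * dt_ms, i_pA = mean_pA + dev)
  attr(out, "dt_ms") <- dt_ms
  out
}

#' Exponential integrate-and-fire neuron parameters
#'
#' Defaults produce firing rates of tens of Hz under an OU current with mean
#' 40 pA and SD 120 pA, with sharp spike initiation (`delta_T_mV` = 1 mV; a
#' 3 mV variant can be requested where shallower initiation is wanted).
#'
#' @param tau_m_ms Membrane time constant (ms).
#' @param E_L_mV Leak reversal potential (mV).
#' @param delta_T_mV Spike-initiation sharpness (mV).
#' @param R_MOhm Membrane resistance (MOhm).
#' @param V_reset_mV Post-spike reset voltage (mV).
#' @param refractory_ms Simulator refractory period (ms); default 0.8.
#' @param V_detect_mV Numerical spike-detection ceiling (mV).
#' @return A list of class `eif_params`.
#' @export
eif_params <- function(tau_m_ms = 5, E_L_mV = -70, delta_T_mV = 1,
                       R_MOhm = 100, V_reset_mV = -70, refractory_ms = 0.8,
                       V_detect_mV = 0) {
  stopifnot(tau_m_ms > 0, delta_T_mV > 0, R_MOhm > 0)
  structure(list(tau_m_ms = tau_m_ms, E_L_mV = E_L_mV,
                 delta_T_mV = delta_T_mV, R_MOhm = R_MOhm,
                 V_reset_mV = V_reset_mV, refractory_ms = refractory_ms,
                 V_detect_mV = V_detect_mV), class = "eif_params")
}

#' Simulate an EIF neuron with an explicit adaptive threshold
#'
#' Ground-truth generator: integrates
#' \eqn{\tau_m dV/dt = (E_L - V) + \Delta_T e^{(V-\theta)/\Delta_T} + R I}
#' by explicit Euler at the sampling rate of the current, with the threshold
#' \eqn{\theta} following the first-order adaptation equation (exact
#' per-sample update). When V reaches the detection ceiling a spike is
#' logged, V is reset and clamped for the refractory period while the
#' threshold keeps evolving. A stylized 0.25 ms upstroke to +10 mV (sharp,
#' kink-like initiation accelerating from the spike's own initiation dV/dt)
#' is superimposed on the *emitted* voltage trace so that dV/dt onset
#' detection is exercised on simulated data; the hidden true threshold and
#' spike times are returned alongside.
#'
#' @param current Output of [ou_current()] (or a data frame with `time_ms`,
#'   `i_pA`).
#' @param thr [threshold_params()] of the ground-truth adaptive threshold.
#' @param eif [eif_params()].
#' @param V0_mV Initial voltage; defaults to the leak reversal.
#' @param onset_criterion_mV_per_ms Depolarization-rate criterion (mV/ms) at
#'   which the simulator logs spike initiation, matching the measurement
#'   convention of [detect_spike_onsets()]; detection/reset bookkeeping uses
#'   `V_detect_mV`.
#' @return A list of class `eif_simulation`: `trace` (a [voltage_trace()]
#'   with spike waveforms), `theta_true` (tibble `time_ms`, `theta_mV`),
#'   `spike_times_ms` (hidden truth), `thr`, `eif`.
#' @export
simulate_eif_adaptive <- function(current, thr, eif = eif_params(),
                                  V0_mV = NULL, onset_criterion_mV_per_ms = 25) {
  validate_threshold_params(thr)
  dt <- attr(current, "dt_ms")
  if (is.null(dt)) dt <- current$time_ms[2] - current$time_ms[1]
  if (is.null(V0_mV)) V0_mV <- eif$E_L_mV
  res <- simulate_eif_cpp(current$i_pA, dt, eif$tau_m_ms, eif$E_L_mV,
                          eif$delta_T_mV, eif$R_MOhm, eif$V_reset_mV,
                          eif$refractory_ms, eif$V_detect_mV,
                          thr$tau_theta_ms, thr$V_i_mV, thr$theta_offset_mV,
                          thr$alpha, thr$beta, thr$k_a_mV, V0_mV,
                          wave_ms = 0.25, wave_peak = 10,
                          criterion = onset_criterion_mV_per_ms)
  structure(list(
    trace = voltage_trace(res$v, dt),
    theta_true = tibble(time_ms = (seq_along(res$theta) - 1) * dt,
                        theta_mV = res$theta),
    spike_times_ms = res$spike_times,
    thr = thr, eif = eif
  ), class = "eif_simulation")
}

#' @export
print.eif_simulation <- function(x, ...) {
  cat(sprintf("<eif_simulation> %d samples, %d spikes (%.3g Hz)\n",
              nrow(x$trace), length(x$spike_times_ms),
              1000 * length(x$spike_times_ms) / trace_duration(x$trace)))
  invisible(x)
}

# Ground-truth threshold parameter sets for the named validation scenarios.
# Knee/offset/curvature chosen once to sit in the upper part of the
# subthreshold voltage distribution produced by the default EIF constants
# under the default OU statistics.
scenario_threshold <- function(scenario) {
  switch(scenario,
    constant = threshold_params(3, -60, -55, 0, 0, 3),
    rectified = threshold_params(3, -63, -62, 0, 1, 3),
    linear = threshold_params(5, -60, -55, 1, 1, 3),
    fast_rectified = threshold_params(0.3, -64, -66, 0, 1, 2),
    current_grid = threshold_params(0.3, -64, -66, 0, 1, 2),
    abort(sprintf("unknown scenario '%s'", scenario))
  )
}

scenario_ou <- function(scenario) {
  if (scenario %in% c("fast_rectified", "current_grid")) {
    list(mean = 40, sd = 120, tau = 0.5)
  } else {
    list(mean = 40, sd = 120, tau = 3)
  }
}

#' Generate a named ground-truth fixture suite
#'
#' Emits the validation scenarios used throughout the package: EIF neurons
#' driven by OU currents with a known adaptive threshold. Scenarios:
#' `constant` (fixed threshold, alpha = beta = 0), `rectified` (adapts only
#' above the knee, tau = 3 ms), `linear` (adapts over the whole range, tau =
#' 5 ms), `fast_rectified` (tau = 0.3 ms with a 0.5 ms input autocorrelation),
#' and `current_grid` (fast_rectified neuron across a grid of input means
#' 20-200 pA and SDs 50-400 pA, screened to cells eliciting at least 20
#' spikes at below 200 Hz).
#'
#' @param scenario Scenario name.
#' @param seed Integer seed; the suite is byte-identical for equal seeds.
#' @param duration_ms Trace duration (ms); default 20000 (20 s).
#' @param dt_ms Simulation sampling interval; default the 42 kHz rate.
#' @param grid_means_pA,grid_sds_pA Current grid (current_grid scenario).
#' @return A list of class `fixture_suite`: `scenario`, `seed`, `thr` (true
#'   parameters), `eif`, `sims` (list of `eif_simulation`), and `manifest`
#'   (tibble: `sim_id`, `mean_pA`, `sd_pA`, `tau_I_ms`, `n_spikes`,
#'   `rate_hz`, `screened_out`).
#' @export
make_fixture_suite <- function(scenario = c("constant", "rectified", "linear",
                                            "fast_rectified", "current_grid"),
                               seed = 1L, duration_ms = 20000,
                               dt_ms = 1 / 42,
                               grid_means_pA = c(20, 100, 200),
                               grid_sds_pA = c(50, 150, 400)) {
  scenario <- match.arg(scenario)
  thr <- scenario_threshold(scenario)
  ou <- scenario_ou(scenario)
  eif <- eif_params()
  grid <- if (scenario == "current_grid") {
    tidyr::expand_grid(mean_pA = grid_means_pA, sd_pA = grid_sds_pA)
  } else {
    tibble(mean_pA = ou$mean, sd_pA = ou$sd)
  }
  sims <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cur <- ou_current(duration_ms, dt_ms, grid$mean_pA[k], grid$sd_pA[k],
                      ou$tau, seed = seed * 1000L + k)
    sim <- simulate_eif_adaptive(cur, thr, eif)
    n_sp <- length(sim$spike_times_ms)
    rate <- 1000 * n_sp / duration_ms
    sims[[k]] <- sim
    rows[[k]] <- tibble(
      sim_id = sprintf("%s_%02d", scenario, k),
      mean_pA = grid$mean_pA[k], sd_pA = grid$sd_pA[k], tau_I_ms = ou$tau,
      n_spikes = n_sp, rate_hz = rate,
      screened_out = n_sp < 20 || rate >= 200
    )
  }
  manifest <- dplyr::bind_rows(rows)
  if (scenario == "current_grid") {
    sims <- sims[!manifest$screened_out]
  }
  structure(list(scenario = scenario, seed = seed, thr = thr, eif = eif,
                 duration_ms = duration_ms, sims = sims, manifest = manifest),
            class = "fixture_suite")
}

#' @export
print.fixture_suite <- function(x, ...) {
  cat(sprintf("<fixture_suite> '%s', seed %d: %d simulation(s)\n",
              x$scenario, x$seed, length(x$sims)))
  print(x$manifest)
  invisible(x)
}

#' Single-PSP voltage trace
#'
#' An alpha-function postsynaptic potential on a constant baseline,
#' \eqn{V(t) = V_0 + A\,(t - t_0)/\tau\, e^{1 - (t - t_0)/\tau}} for
#' \eqn{t \ge t_0}, peaking at exactly `amplitude_mV` a time `tau_decay_ms`
#' after onset. Used to demonstrate the effective shortening of PSPs by
#' threshold adaptation.
#'
#' @param amplitude_mV Peak amplitude above baseline (mV, > 0; 0 allowed for
#'   a flat control trace).
#' @param tau_decay_ms Alpha-function time constant (ms).
#' @param baseline_mV Baseline voltage (mV).
#' @param duration_ms Trace duration (ms).
#' @param onset_ms PSP onset time (ms).
#' @param dt_ms Sampling interval (ms).
#' @return A [voltage_trace()].
#' @export
make_psp_trace <- function(amplitude_mV, tau_decay_ms = 3, baseline_mV = -65,
                           duration_ms = 100, onset_ms = 20, dt_ms = 1 / 42) {
  if (amplitude_mV < 0) abort("amplitude_mV must be >= 0")
  t <- seq(0, duration_ms - dt_ms, by = dt_ms)
  s <- pmax(t - onset_ms, 0) / tau_decay_ms
  v <- baseline_mV + amplitude_mV * s * exp(1 - s)
  voltage_trace(v, dt_ms)
}
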