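#' Adaptive-threshold model parameters
#'
#' Six scalars define the model: the steady-state threshold curve (a smooth
#' function with slope `alpha` far below the critical voltage `V_i`, slope
#' `beta` far above it, curvature scale `k_a`, and offset `theta_offset` at
#' the lower asymptote) and the adaptation time constant `tau_theta` with
#' which the dynamic threshold relaxes toward that curve.
#'
#' The steady-state curve is
#' \deqn{\theta_\infty(V) = \theta_0 + \alpha (V - V_i) +
#'   (\beta - \alpha)\, k_a \log(1 + e^{(V - V_i)/k_a})}
#' which is constant-slope `alpha` for \eqn{V \ll V_i}, bends upward around
#' `V_i` over a scale `k_a`, and has slope `beta` for \eqn{V \gg V_i}.
#'
#' @param tau_theta_ms Adaptation time constant (ms, > 0).
#' @param V_i_mV Critical ("knee") voltage (mV).
#' @param theta_offset_mV Threshold offset at the lower asymptote (mV).
#' @param alpha Dimensionless slope below the knee (typically near 0).
#' @param beta Dimensionless slope above the knee (typically near 1);
#'   must satisfy `beta >= alpha` so the curve bends upward.
#' @param k_a_mV Curvature scale (mV, > 0).
#' @return A list of class `threshold_params`.
#' @examples
#' p <- threshold_params(tau_theta_ms = 0.26, V_i_mV = -59,
#'                       theta_offset_mV = -61, alpha = 0.1, beta = 1,
#'                       k_a_mV = 7)
#' steady_state_threshold(p, c(-75, -59, -45))
#' @export
threshold_params <- function(tau_theta_ms, V_i_mV, theta_offset_mV,
                             alpha, beta, k_a_mV) {
  p <- list(tau_theta_ms = as.numeric(tau_theta_ms),
            V_i_mV = as.numeric(V_i_mV),
            theta_offset_mV = as.numeric(theta_offset_mV),
            alpha = as.numeric(alpha), beta = as.numeric(beta),
            k_a_mV = as.numeric(k_a_mV))
  validate_threshold_params(p)
  structure(p, class = "threshold_params")
}

validate_threshold_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("tau_theta_ms", "V_i_mV", "theta_offset_mV", "alpha", "beta",
              "k_a_mV")) {
    if (!num1(p[[f]])) abort(sprintf("parameter %s must be a finite scalar", f))
  }
  if (p$tau_theta_ms <= 0) abort("tau_theta_ms must be > 0")
  if (p$k_a_mV <= 0) abort("k_a_mV must be > 0")
  if (p$beta < p$alpha) abort("beta must be >= alpha (upward-bending curve)")
  invisible(p)
}

#' @export
print.threshold_params <- function(x, ...) {
  cat(sprintf(
    paste0("<threshold_params> tau = %.4g ms, V_i = %.4g mV, ",
           "theta_offset = %.4g mV,\n  alpha = %.4g, beta = %.4g, ",
           "k_a = %.4g mV\n"),
    x$tau_theta_ms, x$V_i_mV, x$theta_offset_mV, x$alpha, x$beta, x$k_a_mV))
  invisible(x)
}

#' @export
format.threshold_params <- function(x, ...) {
  sprintf("tau=%.3g Vi=%.3g off=%.3g a=%.3g b=%.3g k=%.3g",
          x$tau_theta_ms, x$V_i_mV, x$theta_offset_mV, x$alpha, x$beta,
          x$k_a_mV)
}

#' Steady-state threshold curve
#'
#' Evaluates \eqn{\theta_\infty(V)}: the threshold the dynamic model would
#' reach if the membrane potential were clamped at `v` indefinitely. The
#' softplus term is computed in its numerically stable form.
#'
#' @param params A [threshold_params()].
#' @param v Voltage(s) in mV, finite; applied elementwise.
#' @return Numeric vector of thresholds (mV), same length as `v`.
#' @export
steady_state_threshold <- function(params, v) {
  validate_threshold_params(params)
  if (!is.numeric(v) || length(v) == 0 || !all(is.finite(v))) {
    abort("v must be finite numeric")
  }
  steady_state_threshold_cpp(as.numeric(v), params$V_i_mV,
                             params$theta_offset_mV, params$alpha,
                             params$beta, params$k_a_mV)
}

#' Integrate the dynamic threshold along a voltage trace
#'
#' Passes a voltage trace through the first-order threshold equation
#' \eqn{\tau_\theta\, d\theta/dt = \theta_\infty(V) - \theta} using the exact
#' exponential per-sample update (voltage held constant over each sampling
#' interval), which is unconditionally stable even when `tau_theta` is far
#' below the sampling interval.
#'
#' @param trace A [voltage_trace()] (or a data frame with `time_ms`, `v_mV`).
#' @param params A [threshold_params()].
#' @param theta0 Initial threshold (mV). Defaults to the steady-state value at
#'   the first sample, which removes an arbitrary-length transient.
#' @return A tibble (`threshold_trace`) with columns `time_ms`, `theta_mV`,
#'   aligned sample-for-sample with `trace`.
#' @export
integrate_threshold <- function(trace, params, theta0 = NULL) {
  trace <- as_voltage_trace(trace)
  validate_threshold_params(params)
  dt <- trace_dt(trace)
  if (dt <= 0) abort("dt must be positive")
  if (params$tau_theta_ms < dt / 100) {
    warn("tau_theta is below dt/100; threshold follows theta_inf essentially instantaneously")
  }
  if (is.null(theta0)) {
    theta0 <- steady_state_threshold(params, trace$v_mV[1])
  }
  th <- integrate_threshold_cpp(trace$v_mV, dt, params$tau_theta_ms,
                                params$V_i_mV, params$theta_offset_mV,
                                params$alpha, params$beta, params$k_a_mV,
                                theta0)
  out <- tibble(time_ms = trace$time_ms, theta_mV = th)
  class(out) <- c("threshold_trace", class(out))
  out
}

#' Predict spikes from a voltage trace
#'
#' Integrates the dynamic threshold along the trace and emits a predicted
#' spike at each sample where the voltage reaches the threshold, subject to a
#' refractory period; the threshold continues to evolve through spikes and
#' refractoriness (no reset).
#'
#' @inheritParams integrate_threshold
#' @param refractory_ms Prediction refractory period (ms); default 0.5.
#' @return A list of class `spike_prediction` with elements `spikes` (tibble
#'   with column `time_ms`), `theta` (the threshold trace tibble), and
#'   `duration_ms`.
#' @export
predict_spikes <- function(trace, params, refractory_ms = 0.5,
                           theta0 = NULL) {
  trace <- as_voltage_trace(trace)
  validate_threshold_params(params)
  dt <- trace_dt(trace)
  if (is.null(theta0)) theta0 <- steady_state_threshold(params, trace$v_mV[1])
  res <- predict_spikes_cpp(trace$v_mV, dt, params$tau_theta_ms,
                            params$V_i_mV, params$theta_offset_mV,
                            params$alpha, params$beta, params$k_a_mV,
                            theta0, refractory_ms, TRUE)
  t0 <- trace_t0(trace)
  structure(list(
    spikes = tibble(time_ms = t0 + (res$spike_idx - 1) * dt),
    theta = structure(tibble(time_ms = trace$time_ms, theta_mV = res$theta),
                      class = c("threshold_trace", class(tibble()))),
    duration_ms = trace_duration(trace)
  ), class = "spike_prediction")
}

# Fast path for the optimizer: spike times only (ms, relative to trace start).
predict_spike_times <- function(v, dt, params, refractory_ms = 0.5) {
  theta0 <- steady_state_threshold_cpp(v[1], params$V_i_mV,
                                       params$theta_offset_mV, params$alpha,
                                       params$beta, params$k_a_mV)
  res <- predict_spikes_cpp(v, dt, params$tau_theta_ms, params$V_i_mV,
                            params$theta_offset_mV, params$alpha,
                            params$beta, params$k_a_mV, theta0,
                            refractory_ms, FALSE)
  (res$spike_idx - 1) * dt
}

#' @export
print.spike_prediction <- function(x, ...) {
  cat(sprintf("<spike_prediction> %d spikes over %.4g ms (%.3g Hz)\n",
              nrow(x$spikes), x$duration_ms,
              1000 * nrow(x$spikes) / x$duration_ms))
  invisible(x)
}

#' Serialize threshold parameters to/from JSON
#'
#' Parameters round-trip as a flat JSON object with keys `tau_theta_ms`,
#' `V_i_mV`, `theta_offset_mV`, `alpha`, `beta`, `k_a_mV`.
#'
#' @param params A [threshold_params()].
#' @param path File path; for `write_threshold_params` the destination, for
#'   `read_threshold_params` the source.
#' @return `read_threshold_params` returns a [threshold_params()];
#'   `write_threshold_params` returns `path` invisibly.
#' @export
write_threshold_params <- function(params, path) {
  validate_threshold_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_params
#' @export
read_threshold_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(threshold_params, p[c("tau_theta_ms", "V_i_mV", "theta_offset_mV",
                                "alpha", "beta", "k_a_mV")])
}
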