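#' Plot a steady-state threshold curve
#'
#' Draws \eqn{\theta_\infty(V)} against the diagonal \eqn{\theta = V}; where
#' the curve stays above the diagonal, slow depolarizations cannot reach
#' threshold.
#'
#' @param params A [threshold_params()] or list of them.
#' @param v_range_mV Voltage range to draw (mV).
#' @return A ggplot object.
#' @export
plot_steady_state <- function(params, v_range_mV = c(-80, -40)) {
  if (inherits(params, "threshold_params")) params <- list(params)
  if (is.null(names(params))) names(params) <- seq_along(params)
  vg <- seq(v_range_mV[1], v_range_mV[2], length.out = 400)
  df <- dplyr::bind_rows(purrr::imap(params, function(p, nm) {
    tibble(curve = as.character(nm), v_mV = vg,
           theta_mV = steady_state_threshold(p, vg))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$v_mV, .data$theta_mV,
                                   colour = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "membrane potential (mV)",
                  y = expression(theta[infinity] ~ "(mV)")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_steady_state
#' @param object A `threshold_fit`.
#' @param ... Unused.
#' @export
autoplot.threshold_fit <- function(object, v_range_mV = c(-80, -40), ...) {
  plot_steady_state(object$params, v_range_mV) +
    ggplot2::labs(subtitle = sprintf("gamma_train = %.3f",
                                     object$gamma_train)) +
    ggplot2::guides(colour = "none")
}

#' Plot a voltage trace with its predicted dynamic threshold
#'
#' @param trace A [voltage_trace()].
#' @param prediction A `spike_prediction` from [predict_spikes()] (optional;
#'   computed from `params` if missing).
#' @param params A [threshold_params()], used when `prediction` is missing.
#' @param window_ms Optional `c(from, to)` time window (ms).
#' @return A ggplot object.
#' @export
plot_prediction <- function(trace, prediction = NULL, params = NULL,
                            window_ms = NULL) {
  trace <- as_voltage_trace(trace)
  if (is.null(prediction)) {
    if (is.null(params)) abort("provide a prediction or params")
    prediction <- predict_spikes(trace, params)
  }
  df <- tibble(time_ms = trace$time_ms, v = trace$v_mV,
               theta = prediction$theta$theta_mV)
  sp <- prediction$spikes
  if (!is.null(window_ms)) {
    df <- dplyr::filter(df, .data$time_ms >= window_ms[1],
                        .data$time_ms <= window_ms[2])
    sp <- dplyr::filter(sp, .data$time_ms >= window_ms[1],
                        .data$time_ms <= window_ms[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$v), colour = "#2b6cb0",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theta), colour = "#c53030",
                       linewidth = 0.3) +
    ggplot2::geom_rug(data = sp, ggplot2::aes(.data$time_ms), sides = "t",
                      colour = "#c53030") +
    ggplot2::labs(x = "time (ms)", y = "V, theta (mV)") +
    ggplot2::theme_minimal()
}

#' @rdname autocorrelogram
#' @param object An `acf_table`.
#' @param ... Unused.
#' @export
autoplot.acf_table <- function(object, ...) {
  hhw <- tryCatch(acf_hhw(object), error = function(e) NA_real_)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag_ms, .data$acf)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "lag (ms)", y = "autocorrelation") +
    ggplot2::theme_minimal()
  if (is.finite(hhw)) {
    p <- p + ggplot2::annotate("segment", x = 0, xend = hhw / 2, y = 0.5,
                               yend = 0.5, colour = "#c53030") +
      ggplot2::labs(subtitle = sprintf("HHW = %.3g ms", hhw))
  }
  p
}

#' Plot a fixed-tau sweep profile
#'
#' @param sweep Output of [sweep_fixed_tau()].
#' @return A ggplot object showing gamma (and EV when present) against the
#'   fixed adaptation time constant, log-scaled.
#' @export
plot_tau_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, dplyr::any_of(c("gamma", "ev")),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$tau_theta_ms, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fixed tau_theta (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
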