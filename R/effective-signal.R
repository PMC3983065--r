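#' Effective signal: voltage minus dynamic threshold
#'
#' The effective signal \eqn{ES(t) = V(t) - \theta(t)} recasts the adaptive
#' threshold as a fixed one: a spike is produced when the ES crosses 0 mV
#' from below, so the membrane-potential dynamics with an adaptive threshold
#' are equivalent to the ES dynamics with a fixed threshold at 0.
#'
#' @param trace A [voltage_trace()].
#' @param theta Either a threshold trace from [integrate_threshold()] (same
#'   length) or a [threshold_params()] (integrated on the fly).
#' @return A tibble with columns `time_ms`, `es_mV`.
#' @export
effective_signal <- function(trace, theta) {
  trace <- as_voltage_trace(trace)
  if (inherits(theta, "threshold_params")) {
    theta <- integrate_threshold(trace, theta)
  }
  if (nrow(theta) != nrow(trace)) {
    abort("voltage and threshold traces have different lengths")
  }
  tibble(time_ms = trace$time_ms, es_mV = trace$v_mV - theta$theta_mV)
}

# logical mask of samples outside [onset, onset + excision_ms) windows
excision_mask <- function(n, dt, t0, onsets_ms, excision_ms) {
  keep <- rep(TRUE, n)
  if (length(onsets_ms) == 0) return(keep)
  for (on in onsets_ms) {
    i0 <- floor((on - t0) / dt) + 1L
    i1 <- min(n, i0 + ceiling(excision_ms / dt))
    if (i1 >= 1 && i0 <= n) keep[max(1L, i0):i1] <- FALSE
  }
  keep
}

#' Autocorrelogram with spike excision
#'
#' Mean-subtracted autocorrelation normalized to 1 at lag 0, computed after
#' excising a window starting at each spike onset. Lagged products are
#' accumulated only over index pairs with both samples outside excisions
#' (FFT-based masked correlation), and each lag is normalized by its valid
#' pair count before the lag-0 normalization.
#'
#' @param x Numeric signal samples (voltage or effective signal, mV).
#' @param dt_ms Sampling interval (ms).
#' @param onsets_ms Spike onset times (ms, same clock as the trace start
#'   `t0_ms`); may be empty.
#' @param excision_ms Excision window after each onset (ms); default 1.
#' @param max_lag_ms Largest lag (ms); default 20. The trace must be longer
#'   than 10 times this.
#' @param t0_ms Trace start time (ms); default 0.
#' @return A tibble (`acf_table`) with columns `lag_ms`, `acf`.
#' @export
autocorrelogram <- function(x, dt_ms, onsets_ms = numeric(0),
                            excision_ms = 1, max_lag_ms = 20, t0_ms = 0) {
  n <- length(x)
  if (n * dt_ms <= 10 * max_lag_ms) {
    abort("trace must be longer than 10x max_lag_ms")
  }
  keep <- excision_mask(n, dt_ms, t0_ms, onsets_ms, excision_ms)
  if (mean(keep) < 0.5) abort("more than 50% of samples excised")
  mu <- mean(x[keep])
  if (var(x[keep]) == 0) abort("signal has zero variance; autocorrelation degenerate")
  xc <- ifelse(keep, x - mu, 0)
  m <- as.numeric(keep)
  nlag <- floor(max_lag_ms / dt_ms)
  # masked autocorrelation via FFT: r[l] = sum_i xc[i] xc[i+l],
  # c[l] = sum_i m[i] m[i+l]
  nfft <- stats::nextn(n + nlag + 1, 2)
  fx <- fft(c(xc, rep(0, nfft - n)))
  fm <- fft(c(m, rep(0, nfft - n)))
  r <- Re(fft(fx * Conj(fx), inverse = TRUE))[1:(nlag + 1)] / nfft
  cnt <- Re(fft(fm * Conj(fm), inverse = TRUE))[1:(nlag + 1)] / nfft
  cnt <- pmax(round(cnt), 1)
  ac <- (r / cnt) / (r[1] / cnt[1])
  out <- tibble(lag_ms = (0:nlag) * dt_ms, acf = ac)
  class(out) <- c("acf_table", class(out))
  out
}

#' Half-height width of an autocorrelogram
#'
#' Full width of the region around lag 0 where the autocorrelation stays at
#' or above 0.5, i.e. twice the first downward 0.5-crossing lag (linear
#' interpolation between the bracketing lags). A proxy for the signal's
#' correlation timescale; for a membrane filtering white noise,
#' `HHW / (2 log 2)` estimates the membrane time constant.
#'
#' @param acf_tbl An `acf_table` from [autocorrelogram()] (lag 0 value 1).
#' @return HHW in ms.
#' @export
acf_hhw <- function(acf_tbl) {
  lag <- acf_tbl$lag_ms
  a <- acf_tbl$acf
  if (abs(a[1] - 1) > 1e-8) abort("acf must be normalized to 1 at lag 0")
  below <- which(a < 0.5)
  if (length(below) == 0) {
    abort("acf never drops below 0.5 within max_lag; increase max_lag_ms")
  }
  k <- below[1]
  l <- lag[k - 1] + (0.5 - a[k - 1]) * (lag[k] - lag[k - 1]) / (a[k] - a[k - 1])
  2 * l
}

#' Summarize the effective signal of a trace
#'
#' Computes the standard deviation and autocorrelation half-height width of
#' both the membrane potential and the effective signal, on spike-excised
#' data, plus the membrane-time-constant estimate `hhw_v / (2 log 2)`.
#' Threshold adaptation high-pass filters the voltage, so for thresholds that
#' adapt faster than the input fluctuates both `sigma_es < sigma_v` and
#' `hhw_es < hhw_v`.
#'
#' @param trace A [voltage_trace()].
#' @param params Fitted or true [threshold_params()].
#' @param onsets_ms Spike onset times (ms); excised before statistics.
#' @param excision_ms Excision window (ms); default 1.
#' @param max_lag_ms Autocorrelation lag range (ms); default 20.
#' @return A one-row tibble (`es_summary`): `sigma_v_mV`, `sigma_es_mV`,
#'   `hhw_v_ms`, `hhw_es_ms`, `tau_m_est_ms`.
#' @export
es_summary <- function(trace, params, onsets_ms = numeric(0),
                       excision_ms = 1, max_lag_ms = 20) {
  trace <- as_voltage_trace(trace)
  dt <- trace_dt(trace)
  t0 <- trace_t0(trace)
  es <- effective_signal(trace, params)$es_mV
  keep <- excision_mask(nrow(trace), dt, t0, onsets_ms, excision_ms)
  acf_v <- autocorrelogram(trace$v_mV, dt, onsets_ms, excision_ms,
                           max_lag_ms, t0)
  acf_es <- autocorrelogram(es, dt, onsets_ms, excision_ms, max_lag_ms, t0)
  hhw_v <- acf_hhw(acf_v)
  out <- tibble(
    sigma_v_mV = sd(trace$v_mV[keep]),
    sigma_es_mV = sd(es[keep]),
    hhw_v_ms = hhw_v,
    hhw_es_ms = acf_hhw(acf_es),
    tau_m_est_ms = hhw_v / (2 * log(2))
  )
  class(out) <- c("es_summary", class(out))
  out
}
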