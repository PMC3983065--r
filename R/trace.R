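#' Construct a voltage trace
#'
#' A voltage trace is the universal input of the package: a uniformly sampled
#' membrane potential. It is stored as a tibble with columns `time_ms` and
#' `v_mV`, carrying the sampling interval and free-text metadata as
#' attributes, so it pipes directly into dplyr/ggplot2 while keeping the
#' sampling rate attached.
#'
#' @param v Numeric vector of membrane potential samples (mV). All finite.
#' @param dt_ms Sampling interval in ms (> 0). 24 kHz recordings correspond to
#'   `1/24`, 42 kHz simulations to `1/42`.
#' @param t0_ms Time of the first sample (ms).
#' @param cell,condition,protocol Optional free-text metadata.
#' @return A tibble of class `voltage_trace` with columns `time_ms`, `v_mV`.
#' @examples
#' tr <- voltage_trace(rep(-65, 100), dt_ms = 1 / 24)
#' trace_dt(tr)
#' @export
voltage_trace <- function(v, dt_ms, t0_ms = 0, cell = NA_character_,
                          condition = NA_character_, protocol = NA_character_) {
  v <- as.numeric(v)
  if (length(v) == 0L) abort("voltage trace must be non-empty")
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v))
    abort(sprintf(
      "voltage trace contains %d non-finite sample(s), first at index %d",
      length(bad), bad[1]
    ))
  }
  if (!is.numeric(dt_ms) || length(dt_ms) != 1L || !is.finite(dt_ms) ||
      dt_ms <= 0) {
    abort("dt_ms must be a single positive number")
  }
  out <- tibble(time_ms = t0_ms + (seq_along(v) - 1) * dt_ms, v_mV = v)
  attr(out, "dt_ms") <- dt_ms
  attr(out, "t0_ms") <- t0_ms
  attr(out, "meta") <- list(cell = cell, condition = condition,
                            protocol = protocol)
  class(out) <- c("voltage_trace", class(out))
  out
}

#' Trace accessors
#'
#' @param trace A [voltage_trace()].
#' @return `trace_dt()` the sampling interval (ms); `trace_t0()` the start
#'   time (ms); `trace_duration()` the spanned duration (ms);
#'   `trace_meta()` the metadata list.
#' @export
trace_dt <- function(trace) {
  dt <- attr(trace, "dt_ms")
  if (is.null(dt)) {
    t <- trace$time_ms
    if (is.null(t) || length(t) < 2) abort("trace has no sampling interval")
    dt <- t[2] - t[1]
  }
  dt
}

#' @rdname trace_dt
#' @export
trace_t0 <- function(trace) {
  t0 <- attr(trace, "t0_ms")
  if (is.null(t0)) t0 <- trace$time_ms[1]
  t0
}

#' @rdname trace_dt
#' @export
trace_duration <- function(trace) nrow(trace) * trace_dt(trace)

#' @rdname trace_dt
#' @export
trace_meta <- function(trace) {
  m <- attr(trace, "meta")
  if (is.null(m)) list(cell = NA, condition = NA, protocol = NA) else m
}

as_voltage_trace <- function(x, dt_ms = NULL) {
  if (inherits(x, "voltage_trace")) return(x)
  if (is.data.frame(x) && all(c("time_ms", "v_mV") %in% names(x))) {
    dt <- if (is.null(dt_ms)) x$time_ms[2] - x$time_ms[1] else dt_ms
    return(voltage_trace(x$v_mV, dt, t0_ms = x$time_ms[1]))
  }
  if (is.numeric(x)) {
    if (is.null(dt_ms)) abort("dt_ms required to interpret a bare vector")
    return(voltage_trace(x, dt_ms))
  }
  abort("cannot interpret input as a voltage trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf(
    "<voltage_trace> %d samples, dt = %.6g ms (%.4g kHz), %.4g ms%s\n",
    nrow(x), trace_dt(x), 1 / trace_dt(x), trace_duration(x),
    if (!is.na(m$cell)) paste0(", cell ", m$cell) else ""
  ))
  NextMethod()
}

#' Blank spike waveforms in a voltage trace
#'
#' Replaces each spike waveform with its onset voltage, holding
#' `[onset, onset + blank_ms)` flat. By default the threshold equation is
#' driven by the raw trace, waveforms included; blanking is an optional
#' sensitivity switch for checking how much the post-onset waveform pulls
#' the integrated threshold.
#'
#' @param trace A [voltage_trace()].
#' @param onsets_ms Spike onset times (ms).
#' @param blank_ms Blanking window from each onset (ms); default 1.
#' @return A [voltage_trace()] with the same sampling and metadata.
#' @export
blank_spike_waveforms <- function(trace, onsets_ms, blank_ms = 1) {
  trace <- as_voltage_trace(trace)
  dt <- trace_dt(trace)
  t0 <- trace_t0(trace)
  v <- trace$v_mV
  n <- length(v)
  for (on in onsets_ms) {
    i0 <- max(1L, floor((on - t0) / dt) + 1L)
    i1 <- min(n, i0 + ceiling(blank_ms / dt))
    if (i0 <= n) v[i0:i1] <- v[i0]
  }
  m <- trace_meta(trace)
  voltage_trace(v, dt, t0_ms = t0, cell = m$cell, condition = m$condition,
                protocol = m$protocol)
}
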