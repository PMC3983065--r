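#' Detect spike onsets with a dV/dt criterion
#'
#' Empirical spike threshold measurement. Action-potential peaks are located
#' first (local maxima passing a prominence gate); for each peak the onset is
#' the earliest sample of the contiguous upstroke on which the centered
#' finite-difference dV/dt exceeds the criterion — i.e. the first time before
#' the peak at which the derivative crosses the criterion. The voltage at that
#' sample is the measured spike threshold.
#'
#' @param trace A [voltage_trace()].
#' @param criterion_mV_per_ms dV/dt criterion (mV/ms); default 25. The exact
#'   value makes little difference because the derivative rises abruptly at
#'   spike initiation.
#' @param min_peak_prominence_mV Prominence gate for peak detection (mV);
#'   default 10. Rejects subthreshold bumps.
#' @return A tibble with one row per spike: `onset_time_ms`, `onset_v_mV`
#'   (the measured threshold), `peak_time_ms`, `peak_v_mV`,
#'   `preceding_isi_ms` (NA for the first spike).
#' @export
detect_spike_onsets <- function(trace, criterion_mV_per_ms = 25,
                                min_peak_prominence_mV = 10) {
  trace <- as_voltage_trace(trace)
  v <- trace$v_mV
  n <- length(v)
  dt <- trace_dt(trace)
  empty <- tibble(onset_time_ms = numeric(), onset_v_mV = numeric(),
                  peak_time_ms = numeric(), peak_v_mV = numeric(),
                  preceding_isi_ms = numeric())
  if (n < 3) return(empty)
  peaks <- find_peaks_cpp(v, min_peak_prominence_mV)
  if (length(peaks) == 0) return(empty)
  # centered finite difference at the recording rate, no smoothing
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA)
  onset_idx <- vapply(peaks, function(p) {
    i <- p
    # walk back over the upstroke while the derivative is above criterion
    while (i > 2 && !is.na(dvdt[i - 1]) &&
           dvdt[i - 1] >= criterion_mV_per_ms) i <- i - 1
    if (i == p) {
      # derivative never reached criterion right at the peak: scan back for
      # the nearest suprathreshold-derivative sample of this upstroke
      j <- p - 1
      while (j > 1 && (is.na(dvdt[j]) || dvdt[j] < criterion_mV_per_ms) &&
             v[j] < v[p]) j <- j - 1
      i <- if (j > 1 && !is.na(dvdt[j]) && dvdt[j] >= criterion_mV_per_ms) {
        while (j > 2 && !is.na(dvdt[j - 1]) &&
               dvdt[j - 1] >= criterion_mV_per_ms) j <- j - 1
        j
      } else NA_integer_
    }
    as.integer(i)
  }, integer(1))
  keep <- !is.na(onset_idx)
  peaks <- peaks[keep]
  onset_idx <- onset_idx[keep]
  if (length(peaks) == 0) return(empty)
  # duplicates within the same upstroke: one onset per peak already; merge
  # peaks that share an onset sample (double-peaked waveforms)
  first <- !duplicated(onset_idx)
  peaks <- peaks[first]
  onset_idx <- onset_idx[first]
  t <- trace$time_ms
  onset_t <- t[onset_idx]
  tibble(
    onset_time_ms = onset_t,
    onset_v_mV = v[onset_idx],
    peak_time_ms = t[peaks],
    peak_v_mV = v[peaks],
    preceding_isi_ms = c(NA_real_, diff(onset_t))
  )
}

#' Pre-spike statistics
#'
#' Enriches a spike table with the mean membrane potential over a window
#' preceding each onset and the least-squares depolarization slope over a
#' shorter window, the two predictors classically correlated with measured
#' spike threshold. Windows that run off the trace start or contain a previous
#' spike's waveform yield NA (kept, flagged, excluded downstream).
#'
#' @param trace A [voltage_trace()].
#' @param spikes Spike table from [detect_spike_onsets()].
#' @param mean_window_ms Averaging window before onset (ms); default 5.
#' @param slope_window_ms Regression window before onset (ms); default 1.5.
#' @return The spike table with columns `prespike_mean_v_mV` and
#'   `depol_rate_mV_per_ms` added.
#' @export
prespike_stats <- function(trace, spikes, mean_window_ms = 5,
                           slope_window_ms = 1.5) {
  trace <- as_voltage_trace(trace)
  dt <- trace_dt(trace)
  t0 <- trace_t0(trace)
  v <- trace$v_mV
  n <- length(v)
  onset_idx <- round((spikes$onset_time_ms - t0) / dt) + 1L
  peak_idx <- round((spikes$peak_time_ms - t0) / dt) + 1L
  win_stat <- function(k, i0, win_ms, fun) {
    nw <- floor(win_ms / dt)
    lo <- i0 - nw
    if (lo < 1) return(NA_real_)  # window precedes trace start
    if (k > 1 && any(peak_idx[seq_len(k - 1)] >= lo)) return(NA_real_)
    idx <- lo:(i0 - 1L)  # [onset - win, onset)
    fun(idx)
  }
  means <- vapply(seq_len(nrow(spikes)), function(k) {
    win_stat(k, onset_idx[k], mean_window_ms, function(idx) mean(v[idx]))
  }, numeric(1))
  slopes <- vapply(seq_len(nrow(spikes)), function(k) {
    win_stat(k, onset_idx[k], slope_window_ms, function(idx) {
      tt <- (idx - 1) * dt
      cov(tt, v[idx]) / var(tt)  # OLS slope
    })
  }, numeric(1))
  spikes$prespike_mean_v_mV <- means
  spikes$depol_rate_mV_per_ms <- slopes
  spikes
}

#' Correlations between measured threshold and its predictors
#'
#' Pearson correlation and ordinary-least-squares slope of the measured onset
#' voltage against pre-spike mean voltage, depolarization rate and preceding
#' interspike interval. Degenerate inputs (no variance) are reported as r = 0
#' with a flag rather than an error.
#'
#' @param spikes Spike table enriched by [prespike_stats()].
#' @return A tibble with one row per predictor: columns `predictor`, `r`,
#'   `slope`, `n`, `degenerate`. Slope units: mV/mV for the mean-voltage
#'   predictor, ms for the depolarization rate (mV per mV/ms), mV/ms for the
#'   ISI predictor.
#' @export
threshold_correlations <- function(spikes) {
  predictors <- list(
    prespike_mean_v = spikes$prespike_mean_v_mV,
    depol_rate = spikes$depol_rate_mV_per_ms,
    preceding_isi = spikes$preceding_isi_ms
  )
  y_all <- spikes$onset_v_mV
  rows <- purrr::map2(predictors, names(predictors), function(x, nm) {
    ok <- is.finite(x) & is.finite(y_all)
    if (sum(ok) < 3) {
      abort(sprintf("fewer than 3 spikes with usable %s", nm))
    }
    x <- x[ok]; y <- y_all[ok]
    degen <- sd(x) == 0 || sd(y) == 0
    if (degen) {
      tibble(predictor = nm, r = 0, slope = 0, n = sum(ok), degenerate = TRUE)
    } else {
      b <- cov(x, y) / var(x)
      tibble(predictor = nm, r = cor(x, y), slope = b, n = sum(ok),
             degenerate = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

#' @importFrom stats cov
NULL

#' Read/write spike tables as CSV
#'
#' One row per spike; columns as produced by [detect_spike_onsets()] and
#' [prespike_stats()], all times in ms and voltages in mV.
#'
#' @param spikes A spike tibble.
#' @param path File path.
#' @return `read_spike_table` returns a tibble; `write_spike_table` returns
#'   `path` invisibly.
#' @export
write_spike_table <- function(spikes, path) {
  utils::write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  as_tibble(utils::read.csv(path))
}
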