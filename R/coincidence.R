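#' Count coincidences between two spike trains
#'
#' One-to-one matching: both trains are swept in time order and each recorded
#' spike is paired with at most one predicted spike with
#' \eqn{|t_{rec} - t_{pred}| \le \delta}. The greedy earliest-first sweep
#' attains the maximum-cardinality matching for interval constraints of this
#' form (verified against an exhaustive oracle in the tests).
#'
#' @param rec,pred Sorted numeric vectors of spike times (ms).
#' @param delta_ms Coincidence half-window (ms); default 0.084 (84 µs, about
#'   two samples at 24 kHz).
#' @return Integer count of matched pairs.
#' @export
count_coincidences <- function(rec, pred, delta_ms = 0.084) {
  rec <- as.numeric(rec); pred <- as.numeric(pred)
  if (is.unsorted(rec) || is.unsorted(pred)) abort("spike trains must be sorted")
  i <- 1L; j <- 1L; n <- 0L
  while (i <= length(rec) && j <= length(pred)) {
    d <- rec[i] - pred[j]
    if (abs(d) <= delta_ms) {
      n <- n + 1L; i <- i + 1L; j <- j + 1L
    } else if (d > 0) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  n
}

#' Gamma coincidence factor
#'
#' Normalized measure of coincidence between a recorded and a predicted spike
#' train within a window \eqn{\delta}:
#' \deqn{\Gamma = \frac{1}{1 - 2\nu\delta}\;
#'   \frac{N_{coinc} - 2\nu\delta N_{pred}}{(N_{rec} + N_{pred})/2}}
#' where \eqn{\nu} is the firing rate of the recorded train and
#' \eqn{2\nu\delta N_{pred}} the expected number of chance coincidences of a
#' rate-\eqn{\nu} Poisson process. \eqn{\Gamma = 1} for a spike-for-spike
#' perfect prediction; \eqn{\Gamma \approx 0} when coincidences are at chance
#' level.
#'
#' @inheritParams count_coincidences
#' @param duration_ms Trace duration (ms) over which the rate is computed.
#' @return A one-row tibble (`gamma_score`): `gamma`, `n_coinc`, `n_rec`,
#'   `n_pred`, `rate_rec_hz`, `delta_ms`.
#' @export
gamma_factor <- function(rec, pred, delta_ms = 0.084, duration_ms) {
  if (length(rec) == 0) abort("recorded train is empty; gamma undefined")
  if (duration_ms <= 0) abort("duration_ms must be positive")
  n_rec <- length(rec); n_pred <- length(pred)
  n_coinc <- count_coincidences(rec, pred, delta_ms)
  nu <- n_rec / duration_ms           # spikes per ms
  corr <- 2 * nu * delta_ms           # chance coincidence probability factor
  if (corr >= 1) abort("2*nu*delta >= 1: gamma normalization undefined")
  gamma <- (n_coinc - corr * n_pred) / ((n_rec + n_pred) / 2) / (1 - corr)
  tibble(gamma = gamma, n_coinc = n_coinc, n_rec = n_rec, n_pred = n_pred,
         rate_rec_hz = 1000 * nu, delta_ms = delta_ms)
}

#' False alarm rate
#'
#' Predicted spikes not coincident with any recorded spike, as a percentage
#' of recorded spikes. May exceed 100%.
#'
#' @inheritParams gamma_factor
#' @return Percentage (scalar).
#' @export
false_alarm_rate <- function(rec, pred, delta_ms = 0.084) {
  if (length(rec) == 0) abort("recorded train is empty; false alarm rate undefined")
  n_coinc <- count_coincidences(rec, pred, delta_ms)
  100 * (length(pred) - n_coinc) / length(rec)
}

#' Explained variance of measured spike threshold
#'
#' Fraction of the variance of the measured onset voltages captured by the
#' model threshold at the matched spikes:
#' \eqn{EV = 1 - \sum_i(\hat\theta_i - \theta_i)^2 / \sum_i(\theta_i -
#' \bar\theta)^2}. At most 1; can be negative for predictions worse than the
#' mean.
#'
#' @param measured Measured onset voltages (mV), one per matched spike.
#' @param predicted Model thresholds at the same spikes (mV).
#' @return Scalar EV.
#' @export
explained_variance <- function(measured, predicted) {
  if (length(measured) != length(predicted)) abort("paired vectors required")
  if (length(measured) < 3) abort("at least 3 matched spikes required")
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) abort("measured thresholds have zero variance; EV degenerate")
  1 - sum((predicted - measured)^2) / ss_tot
}

#' Distances between steady-state threshold curves
#'
#' Mean absolute distance between steady-state curves over a voltage range,
#' \eqn{\frac{1}{V_{max}-V_{min}} \int |\theta_{\infty,i}(V) -
#' \theta_{\infty,j}(V)|\,dV}, averaged over all unordered pairs, and the mean
#' distance of each curve to the diagonal \eqn{\theta = V}. The range is
#' normally the sub-threshold voltage range of the traces under study.
#'
#' @param params_list List of [threshold_params()] (>= 2 for the pairwise
#'   distance; a single set still yields a diagonal distance).
#' @param v_min_mV,v_max_mV Integration range (mV), `v_min_mV < v_max_mV`.
#' @param n_grid Trapezoid grid size; default 1000.
#' @return A tibble with `mean_pairwise_mV` (NA if fewer than 2 curves) and
#'   `mean_to_diagonal_mV`.
#' @export
curve_distance <- function(params_list, v_min_mV, v_max_mV, n_grid = 1000) {
  if (inherits(params_list, "threshold_params")) params_list <- list(params_list)
  if (v_min_mV >= v_max_mV) abort("degenerate voltage range")
  vg <- seq(v_min_mV, v_max_mV, length.out = n_grid)
  curves <- lapply(params_list, steady_state_threshold, v = vg)
  trap <- function(y) {
    h <- (v_max_mV - v_min_mV) / (n_grid - 1)
    (sum(y) - (y[1] + y[n_grid]) / 2) * h / (v_max_mV - v_min_mV)
  }
  m <- length(curves)
  pw <- NA_real_
  if (m >= 2) {
    acc <- 0; cnt <- 0
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      acc <- acc + trap(abs(curves[[i]] - curves[[j]])); cnt <- cnt + 1
    }
    pw <- acc / cnt
  }
  diag_d <- mean(vapply(curves, function(cv) trap(abs(cv - vg)), numeric(1)))
  tibble(mean_pairwise_mV = pw, mean_to_diagonal_mV = diag_d)
}

#' Read/write spike trains as text
#'
#' Single trains round-trip as one time (ms) per line; labelled collections
#' as a two-column CSV (`train`, `time_ms`).
#'
#' @param times Numeric spike times (ms), or for the multi-train writer a
#'   named list of numeric vectors.
#' @param path File path.
#' @return Readers return the times (vector) or a tibble; writers return
#'   `path` invisibly.
#' @export
write_spike_train <- function(times, path) {
  writeLines(sprintf("%.17g", as.numeric(times)), path)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (is.unsorted(x)) abort("spike train file is not sorted")
  x
}

#' @rdname write_spike_train
#' @export
write_spike_trains <- function(times, path) {
  stopifnot(is.list(times), !is.null(names(times)))
  df <- dplyr::bind_rows(purrr::imap(times, function(tt, nm) {
    tibble(train = nm, time_ms = as.numeric(tt))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_trains <- function(path) {
  as_tibble(utils::read.csv(path))
}
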