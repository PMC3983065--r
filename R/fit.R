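#' Fitting configuration
#'
#' Bounds and optimizer settings for [fit_threshold_model()]. The default
#' bounds bracket the parameter values typically reported for fast auditory
#' neurons (adaptation time constants of a few hundred µs to a few ms, knee
#' voltages around -60 mV, low-side slope near 0, high-side slope near 1,
#' curvature of a few mV). The adaptation time constant is searched on a log
#' scale.
#'
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @param delta_ms Coincidence half-window for the objective (ms).
#' @param refractory_ms Prediction refractory period (ms).
#' @param population CMA-ES population size.
#' @param max_evals Total objective-evaluation budget (across restarts).
#' @param restarts Number of CMA-ES restarts after the first run.
#' @param sigma0 Initial step size, as a fraction of each box width.
#' @param onset_exclusion_ms Initial stretch of every trace excluded from
#'   scoring, in addition to `5 * tau_theta` (threshold initialization
#'   transient); default 5 ms.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(bounds = list(
                         tau_theta_ms = c(0.05, 20),
                         V_i_mV = c(-80, -40),
                         theta_offset_mV = c(-80, -40),
                         alpha = c(0, 1),
                         beta = c(0, 2),
                         k_a_mV = c(0.5, 20)
                       ),
                       delta_ms = 0.084, refractory_ms = 0.5,
                       population = 16L, max_evals = 3000L, restarts = 2L,
                       sigma0 = 0.3, onset_exclusion_ms = 5) {
  structure(list(bounds = bounds, delta_ms = delta_ms,
                 refractory_ms = refractory_ms, population = population,
                 max_evals = max_evals, restarts = restarts, sigma0 = sigma0,
                 onset_exclusion_ms = onset_exclusion_ms),
            class = "fit_config")
}

param_names <- c("tau_theta_ms", "V_i_mV", "theta_offset_mV", "alpha",
                 "beta", "k_a_mV")

# unit-box coordinates <-> parameters (tau on log10 scale; the beta
# coordinate spans [alpha, upper] so the upward-bending constraint
# beta >= alpha holds for every search point)
box_to_params <- function(x, bounds, fixed = NULL) {
  p <- list()
  i <- 1L
  for (nm in param_names) {
    if (!is.null(fixed) && nm %in% names(fixed)) {
      p[[nm]] <- fixed[[nm]]
      next
    }
    b <- bounds[[nm]]
    p[[nm]] <- if (nm == "tau_theta_ms") {
      10^(log10(b[1]) + x[i] * (log10(b[2]) - log10(b[1])))
    } else if (nm == "beta") {
      lo <- max(b[1], p$alpha %||% fixed$alpha %||% b[1])
      lo + x[i] * (max(b[2], lo) - lo)
    } else {
      b[1] + x[i] * (b[2] - b[1])
    }
    i <- i + 1L
  }
  if (p$beta < p$alpha) p$beta <- p$alpha  # fixed-beta edge case
  structure(p, class = "threshold_params")
}

#' Group traces into subsets for fitting
#'
#' Two grouping modes mirror the train/test protocol: `"protocol"` groups
#' traces by their stimulation-protocol tag; `"mean_vm"` orders traces by
#' mean sub-threshold membrane potential and accumulates consecutive traces
#' until each subset holds at least `min_spikes` spikes (a trailing subset
#' below the minimum merges into its predecessor).
#'
#' @param manifest A data frame with one row per trace: columns `trace_id`,
#'   `n_spikes`, plus `protocol` (protocol mode) or `mean_v_mV` (mean_vm
#'   mode).
#' @param mode `"mean_vm"` or `"protocol"`.
#' @param min_spikes Minimum spikes per subset; default 120.
#' @return The manifest with a `subset_id` column added (ordered by mean V in
#'   mean_vm mode).
#' @export
make_subsets <- function(manifest, mode = c("mean_vm", "protocol"),
                         min_spikes = 120) {
  mode <- match.arg(mode)
  manifest <- as_tibble(manifest)
  if (mode == "protocol") {
    if (!"protocol" %in% names(manifest)) abort("protocol column required")
    manifest$subset_id <- paste0("protocol_", manifest$protocol)
    return(manifest)
  }
  if (!"mean_v_mV" %in% names(manifest)) abort("mean_v_mV column required")
  manifest <- dplyr::arrange(manifest, .data$mean_v_mV)
  if (sum(manifest$n_spikes) < min_spikes) {
    warn(sprintf("only %d spikes in total (< %d): a single subset is formed",
                 sum(manifest$n_spikes), min_spikes))
    manifest$subset_id <- "vm_1"
    return(manifest)
  }
  ids <- integer(nrow(manifest))
  cur <- 1L; acc <- 0
  for (i in seq_len(nrow(manifest))) {
    ids[i] <- cur
    acc <- acc + manifest$n_spikes[i]
    if (acc >= min_spikes && i < nrow(manifest)) {
      cur <- cur + 1L; acc <- 0
    }
  }
  # trailing subset below the minimum merges into its predecessor
  last <- ids == max(ids)
  if (sum(manifest$n_spikes[last]) < min_spikes && max(ids) > 1L) {
    ids[last] <- max(ids) - 1L
  }
  manifest$subset_id <- paste0("vm_", ids)
  manifest
}

# Per-trace precomputation for the objective: raw samples, dt, recorded
# onset times relative to trace start.
prep_fit_traces <- function(traces, spikes) {
  if (inherits(traces, "voltage_trace")) traces <- list(traces)
  if (is.data.frame(spikes)) spikes <- list(spikes)
  if (length(traces) != length(spikes)) {
    abort("one spike table per trace required")
  }
  purrr::map2(traces, spikes, function(tr, sp, ...) {
    tr <- as_voltage_trace(tr)
    list(v = tr$v_mV, dt = trace_dt(tr),
         duration = trace_duration(tr),
         rec = sort(sp$onset_time_ms - trace_t0(tr)))
  })
}

# Mean gamma across traces for one parameter set; spikes inside the initial
# exclusion window (5*tau + onset_exclusion) are not scored.
gamma_objective <- function(prep, params, config) {
  excl <- 5 * params$tau_theta_ms + config$onset_exclusion_ms
  g <- vapply(prep, function(pr) {
    rec <- pr$rec[pr$rec >= excl]
    if (length(rec) == 0) return(NA_real_)
    pred <- predict_spike_times(pr$v, pr$dt, params, config$refractory_ms)
    pred <- pred[pred >= excl]
    if (length(pred) == 0) return(-1)  # penalized: no predicted spikes
    gamma_factor(rec, pred, config$delta_ms, pr$duration - excl)$gamma
  }, numeric(1))
  mean(g, na.rm = TRUE)
}

#' Fit the adaptive-threshold model by maximizing the gamma factor
#'
#' Optimizes the six model parameters with CMA-ES so that spikes predicted by
#' threshold crossings match the recorded spike onsets, scored by the mean
#' gamma coincidence factor across the subset's traces at a stringent
#' coincidence window. Deterministic given `seed`.
#'
#' @param traces A [voltage_trace()] or list of them (one subset).
#' @param spikes Matching spike table(s) from [detect_spike_onsets()].
#' @param config A [fit_config()].
#' @param seed Integer seed for the optimizer.
#' @param fixed Optional named list of parameters to hold fixed (e.g.
#'   `list(tau_theta_ms = 1)`); the remaining parameters are optimized.
#' @param subset_id Optional label stored in the result.
#' @return A `threshold_fit` object: `params`, `gamma_train`,
#'   `optimizer_evals`, `seed`, `bounds_used`, `subset_id`, `diagnostic`
#'   (`"ok"` or `"no_prediction"` when no candidate predicted spikes).
#' @export
fit_threshold_model <- function(traces, spikes, config = fit_config(),
                                seed = 1L, fixed = NULL,
                                subset_id = NA_character_) {
  prep <- prep_fit_traces(traces, spikes)
  n_rec <- sum(vapply(prep, function(pr) length(pr$rec), integer(1)))
  if (n_rec < 20) {
    warn(sprintf("subset has only %d spikes (< 20); fit may be unreliable",
                 n_rec))
  }
  free <- setdiff(param_names, names(fixed))
  nfree <- length(free)
  fn <- function(x) {
    params <- box_to_params(x, config$bounds, fixed)
    -gamma_objective(prep, params, config)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  res <- cma_es_restarts(fn, nfree, sigma0 = config$sigma0,
                         lambda = config$population,
                         max_evals = config$max_evals,
                         restarts = config$restarts)
  params <- box_to_params(res$x, config$bounds, fixed)
  gamma_train <- gamma_objective(prep, params, config)  # penalty-free score
  structure(list(
    params = params,
    gamma_train = gamma_train,
    optimizer_evals = res$evals,
    seed = seed,
    bounds_used = config$bounds,
    fixed = fixed,
    config = config,
    subset_id = subset_id,
    n_rec_spikes = n_rec,
    diagnostic = if (gamma_train <= -1 + 1e-12) "no_prediction" else "ok"
  ), class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> gamma_train = %.3f (%d evals, seed %d)\n",
              x$gamma_train, x$optimizer_evals, x$seed))
  print(x$params)
  invisible(x)
}

#' Profile fit quality against a fixed adaptation time constant
#'
#' Re-fits the five curve parameters while holding the adaptation time
#' constant at each value of a grid, tracing how the gamma factor (and, when
#' onset voltages are available, the explained variance) degrade away from
#' the optimal time constant.
#'
#' @inheritParams fit_threshold_model
#' @param tau_grid_ms Time constants to profile (ms).
#' @return A tibble with one row per grid value: `tau_theta_ms`, `gamma`,
#'   `ev`, plus the fitted parameter columns.
#' @export
sweep_fixed_tau <- function(traces, spikes, tau_grid_ms,
                            config = fit_config(), seed = 1L) {
  rows <- purrr::imap(as.numeric(tau_grid_ms), function(tau, k) {
    fit <- fit_threshold_model(traces, spikes, config, seed = seed + k - 1L,
                               fixed = list(tau_theta_ms = tau))
    ev <- tryCatch(
      mean(cross_validate(fit, traces, spikes)$ev, na.rm = TRUE),
      error = function(e) NA_real_
    )
    dplyr::bind_cols(
      tibble(tau_theta_ms = tau, gamma = fit$gamma_train, ev = ev),
      as_tibble(unclass(fit$params)[setdiff(param_names, "tau_theta_ms")])
    )
  })
  dplyr::bind_rows(rows)
}

#' Test a fitted model on held-out recordings
#'
#' Applies a frozen fitted model to other traces of the same cell and
#' reports, per trace: the gamma factor, the false-alarm percentage, and the
#' explained variance of the measured onset voltages at coincidence-matched
#' spikes.
#'
#' @param fit A `threshold_fit`.
#' @param traces Held-out [voltage_trace()] (or list).
#' @param spikes Matching spike table(s) (need `onset_time_ms`; EV requires
#'   `onset_v_mV`).
#' @return A tibble with one row per held-out trace: `gamma`, `fa_pct`, `ev`,
#'   `n_rec`, `n_pred`.
#' @export
cross_validate <- function(fit, traces, spikes) {
  config <- fit$config
  params <- fit$params
  if (inherits(traces, "voltage_trace")) traces <- list(traces)
  if (is.data.frame(spikes)) spikes <- list(spikes)
  excl <- 5 * params$tau_theta_ms + config$onset_exclusion_ms
  rows <- purrr::map2(traces, spikes, function(tr, sp) {
    tr <- as_voltage_trace(tr)
    t0 <- trace_t0(tr)
    rec_t <- sort(sp$onset_time_ms - t0)
    keep <- rec_t >= excl
    rec <- rec_t[keep]
    pred <- predict_spike_times(tr$v_mV, trace_dt(tr), params,
                                config$refractory_ms)
    pred <- pred[pred >= excl]
    if (length(rec) == 0) {
      return(tibble(gamma = NA_real_, fa_pct = NA_real_, ev = NA_real_,
                    n_rec = 0L, n_pred = length(pred)))
    }
    g <- gamma_factor(rec, pred, config$delta_ms,
                      trace_duration(tr) - excl)$gamma
    fa <- false_alarm_rate(rec, pred, config$delta_ms)
    ev <- NA_real_
    if ("onset_v_mV" %in% names(sp)) {
      m <- match_pairs(rec, pred, config$delta_ms)
      if (nrow(m) >= 3) {
        th <- integrate_threshold(tr, params)
        pred_idx <- round(pred[m$pred] / trace_dt(tr)) + 1L
        measured <- sp$onset_v_mV[order(sp$onset_time_ms)][keep][m$rec]
        ev <- tryCatch(explained_variance(measured, th$theta_mV[pred_idx]),
                       error = function(e) NA_real_)
      }
    }
    tibble(gamma = g, fa_pct = fa, ev = ev, n_rec = length(rec),
           n_pred = length(pred))
  })
  dplyr::bind_rows(rows)
}

# indices of greedily matched (rec, pred) pairs within delta
match_pairs <- function(rec, pred, delta_ms) {
  i <- 1L; j <- 1L
  ri <- integer(0); pj <- integer(0)
  while (i <= length(rec) && j <= length(pred)) {
    d <- rec[i] - pred[j]
    if (abs(d) <= delta_ms) {
      ri <- c(ri, i); pj <- c(pj, j); i <- i + 1L; j <- j + 1L
    } else if (d > 0) j <- j + 1L else i <- i + 1L
  }
  tibble(rec = ri, pred = pj)
}
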