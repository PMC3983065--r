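#' Tidy a fitted threshold model
#'
#' One row per model parameter with its fitted value, search bounds, and
#' whether it was held fixed.
#'
#' @param x A `threshold_fit` from [fit_threshold_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `lower`, `upper`,
#'   `fixed`.
#' @export
tidy.threshold_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(param_names, function(nm) {
    b <- x$bounds_used[[nm]]
    tibble(term = nm, estimate = x$params[[nm]],
           lower = b[1], upper = b[2],
           fixed = nm %in% names(x$fixed))
  }))
}

#' Glance at a fitted threshold model
#'
#' @param x A `threshold_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `gamma_train`, `n_rec_spikes`,
#'   `optimizer_evals`, `seed`, `subset_id`, `diagnostic`.
#' @export
glance.threshold_fit <- function(x, ...) {
  tibble(gamma_train = x$gamma_train, n_rec_spikes = x$n_rec_spikes,
         optimizer_evals = x$optimizer_evals, seed = x$seed,
         subset_id = x$subset_id, diagnostic = x$diagnostic)
}

#' Collate cross-validation results into a per-subset report
#'
#' Binds per-trace test metrics from [cross_validate()] runs into the
#' per-cell, per-subset summary table used to compare conditions: one row
#' per (cell, subset) with mean gamma, false-alarm percentage and explained
#' variance.
#'
#' @param results A tibble (or list of tibbles) of [cross_validate()] rows
#'   carrying `cell` and `subset_id` columns.
#' @return A tibble with one row per (cell, subset_id).
#' @export
collate_crossval <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  dplyr::summarise(
    dplyr::group_by(results, .data$cell, .data$subset_id),
    gamma = mean(.data$gamma, na.rm = TRUE),
    fa_pct = mean(.data$fa_pct, na.rm = TRUE),
    ev = mean(.data$ev, na.rm = TRUE),
    n_traces = dplyr::n(),
    .groups = "drop"
  )
}
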