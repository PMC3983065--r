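#' Read and write voltage traces
#'
#' Two on-disk formats. `"text"` is a plain one-column file of voltages (mV)
#' with `# key=value` header lines carrying `dt_ms` (mandatory), `t0_ms` and
#' metadata; values are written with 17 significant digits so doubles
#' round-trip exactly. `"h5"` is an HDF5 container (dataset `V`, attributes
#' `dt_ms`, `t0_ms`, `cell`, `condition`, `protocol`), available when the
#' rhdf5 package is installed; it round-trips bit-exactly.
#'
#' A missing sampling interval is an error, never guessed; non-finite samples
#' are an error naming the offending indices.
#'
#' @param trace A [voltage_trace()].
#' @param path File path.
#' @param format `"text"` or `"h5"`.
#' @return `read_voltage_trace` returns a [voltage_trace()];
#'   `write_voltage_trace` returns `path` invisibly.
#' @export
write_voltage_trace <- function(trace, path, format = c("text", "h5")) {
  format <- match.arg(format)
  trace <- as_voltage_trace(trace)
  m <- trace_meta(trace)
  if (format == "text") {
    hdr <- c(
      sprintf("# dt_ms=%.17g", trace_dt(trace)),
      sprintf("# t0_ms=%.17g", trace_t0(trace)),
      sprintf("# cell=%s", m$cell),
      sprintf("# condition=%s", m$condition),
      sprintf("# protocol=%s", m$protocol)
    )
    writeLines(c(hdr, sprintf("%.17g", trace$v_mV)), path)
  } else {
    require_rhdf5()
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(trace$v_mV, path, "V")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "V")
    rhdf5::h5writeAttribute(trace_dt(trace), did, "dt_ms")
    rhdf5::h5writeAttribute(trace_t0(trace), did, "t0_ms")
    for (nm in c("cell", "condition", "protocol")) {
      val <- m[[nm]]
      rhdf5::h5writeAttribute(if (is.na(val)) "NA" else as.character(val),
                              did, nm)
    }
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
read_voltage_trace <- function(path, format = c("text", "h5")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "text") {
    lines <- readLines(path)
    is_hdr <- startsWith(lines, "#")
    kv <- list()
    for (h in lines[is_hdr]) {
      h <- sub("^#\\s*", "", h)
      eq <- regexpr("=", h, fixed = TRUE)
      if (eq > 0) kv[[substr(h, 1, eq - 1)]] <- substr(h, eq + 1, nchar(h))
    }
    if (is.null(kv$dt_ms)) {
      abort("trace file has no dt_ms header; the sampling rate is never guessed")
    }
    v <- as.numeric(lines[!is_hdr])
    if (any(!is.finite(v))) {
      abort(sprintf("non-finite samples at indices: %s",
                    paste(head(which(!is.finite(v)), 10), collapse = ", ")))
    }
    na_or <- function(x, d) if (is.null(x) || x == "NA") d else x
    voltage_trace(v, as.numeric(kv$dt_ms),
                  t0_ms = as.numeric(na_or(kv$t0_ms, "0")),
                  cell = na_or(kv$cell, NA_character_),
                  condition = na_or(kv$condition, NA_character_),
                  protocol = na_or(kv$protocol, NA_character_))
  } else {
    require_rhdf5()
    v <- as.numeric(rhdf5::h5read(path, "V"))
    at <- rhdf5::h5readAttributes(path, "V")
    if (is.null(at$dt_ms)) abort("h5 trace has no dt_ms attribute")
    if (any(!is.finite(v))) {
      abort(sprintf("non-finite samples at indices: %s",
                    paste(head(which(!is.finite(v)), 10), collapse = ", ")))
    }
    sc <- function(x, d) {
      if (is.null(x) || identical(as.character(x), "NA")) d
      else as.character(x)
    }
    voltage_trace(v, as.numeric(at$dt_ms),
                  t0_ms = if (is.null(at$t0_ms)) 0 else as.numeric(at$t0_ms),
                  cell = sc(at$cell, NA_character_),
                  condition = sc(at$condition, NA_character_),
                  protocol = sc(at$protocol, NA_character_))
  }
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    abort("the h5 format requires the rhdf5 package; use format = \"text\"")
  }
}

#' Read and write trace manifests
#'
#' A manifest is a CSV with one row per trace: `trace_id`, `path`, `format`,
#' `dt_ms`, `cell`, `condition`, `protocol`. Paths are resolved relative to
#' the manifest's directory.
#'
#' @param manifest A tibble with the columns above.
#' @param path Manifest file path.
#' @return `read_trace_manifest` returns the manifest tibble with an
#'   attribute `dir`; `write_trace_manifest` returns `path` invisibly.
#' @export
write_trace_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_manifest
#' @export
read_trace_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such manifest: %s", path))
  mf <- as_tibble(utils::read.csv(path))
  if (anyDuplicated(mf$trace_id)) abort("trace ids must be unique")
  attr(mf, "dir") <- dirname(path)
  mf
}

# load all traces listed in a manifest (list named by trace_id)
load_manifest_traces <- function(manifest) {
  dir <- attr(manifest, "dir") %||% "."
  out <- purrr::pmap(manifest, function(trace_id, path, format, ...) {
    p <- if (file.exists(path)) path else file.path(dir, path)
    read_voltage_trace(p, format = format)
  })
  names(out) <- manifest$trace_id
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run metadata record
#'
#' A small JSON sidecar written next to every artifact a pipeline run
#' produces: seed, package version, R version, timestamp, and the
#' configuration actually used.
#'
#' @param path Output path.
#' @param seed Integer seed of the run.
#' @param config A list (e.g. a [fit_config()]).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, seed, config = list()) {
  meta <- list(
    seed = seed,
    package = "spikethresh",
    version = as.character(utils::packageVersion("spikethresh")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
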