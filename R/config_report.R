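# Layered run configuration and versioned JSON reports.  The analysis
# drivers under analysis/ consume these; every report embeds the effective
# configuration so runs are reproducible from the report alone.

REPORT_SCHEMA_VERSION <- "1.0"

default_run_config <- function() {
  list(
    temperature_K = 300,
    stride_mmpbsa_ps = 6,
    stride_scan_ps = 120,
    stride_nma_ps = 750,
    stride_highlevel_ps = 1500,
    convergence_window_ps = 12000,
    convergence_tol_kcal = 1.0,
    pb = unclass(pb_settings()),
    sasa_gamma_kcal_A2 = 0.00542,
    sasa_offset_kcal = 0.92,
    hbond_distance_cutoff_A = 3.5,
    hbond_angle_cutoff_deg = 120,
    softcore_alpha = 0.5,
    softcore_power = 1,
    ch_cap_length_A = 1.09,
    rmsd_bound_A = 2.0,
    seed = 1,
    output_dir = "results"
  )
}

merge_config <- function(base, overrides, path = "") {
  for (key in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && is.list(overrides[[key]])) {
      base[[key]] <- merge_config(base[[key]], overrides[[key]], full)
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}

#' Build a run configuration
#'
#' Starts from the package defaults, applies an optional YAML-like
#' hierarchical config file (parsed with a minimal two-level
#' `key: value` / indented-subkey reader), then named overrides.  Unknown
#' keys are rejected at every level (no silent defaults for typos).
#'
#' @param file optional config file path.
#' @param ... named overrides (nested lists allowed, e.g.
#'   `pb = list(grid_spacing = 1)`).
#' @return list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- default_run_config()
  if (!is.null(file)) cfg <- merge_config(cfg, read_simple_yaml(file))
  overrides <- list(...)
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("configuration overrides must be named")
    cfg <- merge_config(cfg, overrides)
  }
  structure(cfg, class = "run_config")
}

# minimal hierarchical "key: value" reader (two levels, numbers and
# logicals coerced); avoids committing to a full YAML dialect
read_simple_yaml <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  current <- NULL
  coerce <- function(v) {
    v <- trimws(v)
    if (v %in% c("true", "TRUE")) return(TRUE)
    if (v %in% c("false", "FALSE")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  for (ln in lines) {
    indented <- grepl("^\\s+", ln)
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- if (length(kv) > 1) paste(kv[-1], collapse = ":") else ""
    if (!indented && !nzchar(trimws(val))) {
      current <- key
      out[[current]] <- list()
    } else if (indented) {
      if (is.null(current)) stop("indented key without a parent in ", path)
      out[[current]][[key]] <- coerce(val)
    } else {
      current <- NULL
      out[[key]] <- coerce(val)
    }
  }
  out
}

#' Write a versioned JSON report
#'
#' Numeric fields should carry units in their key names; the effective
#' configuration and the schema version are embedded.
#'
#' @param results named list of results.
#' @param path output JSON path.
#' @param config the `run_config` used for the run.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = run_config()) {
  payload <- list(schema_version = REPORT_SCHEMA_VERSION,
                  config = unclass(config),
                  results = results)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path JSON path.
#' @return list with `schema_version`, `config`, `results`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
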