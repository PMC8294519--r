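## Run configuration.  Every weight, threshold and detector parameter the
## engine uses is a config key, so alternative constant sets (e.g. values
## calibrated on a curated benchmark) can be dropped in without code
## changes.  Files are YAML; unknown keys are rejected.

#' Default configuration
#'
#' Returns the full default configuration as a nested list with four
#' sections:
#' \describe{
#'   \item{`weights`}{per-evidence increments: `sp_sec`, `sp_lipo`,
#'     `sp_tat`, `tm_helix`, `signature`, `go`, `vote` (all +1) and the
#'     single negative weight `sp_tm_overlap` (-1) that discounts a lone
#'     N-terminal helix co-located with a signal peptide. Scores floor at
#'     zero.}
#'   \item{`thresholds`}{minimum score per compartment tag:
#'     `extra` = 2 (concordant support from at least two sources),
#'     `lipo` = `tm` = `cw` = 1.}
#'   \item{`detectors`}{every window/threshold of the built-in scans
#'     (see the individual `scan_*` functions for semantics).}
#'   \item{`builtin`}{`mode` = `"auto"` (run the built-in panel only for
#'     records lacking supplied evidence; `"always"`/`"never"` force or
#'     suppress it) and `sec_sources`, the panel slots a built-in Sec
#'     signal-peptide call is attributed to.}
#'   \item{`evaluation`}{`unknown` policy for scoring (`"negative"` or
#'     `"exclude"`).}
#' }
#' @return A named list of class `scl_config`.
#' @export
default_config <- function() {
  structure(list(
    weights = list(sp_sec = 1, sp_lipo = 1, sp_tat = 1, tm_helix = 1,
                   signature = 1, go = 1, vote = 1, sp_tm_overlap = -1),
    thresholds = list(extra = 2, lipo = 1, tm = 1, cw = 1),
    detectors = list(
      lipobox_c_min = 15L, lipobox_c_max = 40L,
      lipobox_min_hydrophobic = 6L,
      tat_window = 35L, tat_min_consensus = 2L, tat_hydro_within = 25L,
      lpxtg_window = 50L, lpxtg_min_hydrophobic = 15L,
      lpxtg_min_positive = 2L,
      tm_window = 19L, tm_threshold = 1.6,
      sec_h_min = 7L, sec_site_min = 15L, sec_site_max = 45L,
      sec_c_max_after = 10L),
    builtin = list(mode = "auto",
                   sec_sources = c("sp_predictor_a", "sp_predictor_b",
                                   "predisi_like")),
    evaluation = list(unknown = "negative")
  ), class = "scl_config")
}

#' Load a configuration file over the defaults
#'
#' Reads a YAML file and merges it into [default_config()]. Keys absent
#' from the defaults are rejected (typo protection); values replace the
#' defaults wholesale per key.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An `scl_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) config_error("config file not found: ", path)
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e) config_error(
                     "cannot parse config '", path, "': ",
                     conditionMessage(e)))
  if (is.null(user)) return(cfg)
  if (!is.list(user)) config_error(path, ": config must be a YAML mapping")
  merged <- merge_config(cfg, user, path, character())
  class(merged) <- "scl_config"
  validate_config(merged)
  merged
}

merge_config <- function(base, user, path, trail) {
  for (key in names(user)) {
    full <- paste(c(trail, key), collapse = ".")
    if (!key %in% names(base)) {
      config_error(path, ": unknown config key '", full, "'")
    }
    if (is.list(base[[key]]) && !key %in% c("sec_sources")) {
      if (!is.list(user[[key]])) {
        config_error(path, ": '", full, "' must be a mapping")
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], path,
                                  c(trail, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (any(!vapply(th, is.numeric, logical(1L))) ||
      any(unlist(th) < 0)) {
    config_error("thresholds must be non-negative numbers")
  }
  if (!cfg$builtin$mode %in% c("auto", "always", "never")) {
    config_error("builtin.mode must be auto, always or never")
  }
  bad <- setdiff(unlist(cfg$builtin$sec_sources), EVIDENCE_SOURCES)
  if (length(bad)) {
    config_error("unknown builtin.sec_sources entry: ", bad[1L])
  }
  if (!cfg$evaluation$unknown %in% c("negative", "exclude")) {
    config_error("evaluation.unknown must be 'negative' or 'exclude'")
  }
  invisible(cfg)
}

#' Dump the effective configuration as YAML
#'
#' @param config An `scl_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
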