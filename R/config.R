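#' Run configuration
#'
#' Validated configuration for simulation/analysis runs, with every field
#' defaulting to the package's standard study conditions. Loadable from a
#' YAML file; unknown keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param path Optional YAML file whose keys override the defaults.
#' @param overrides Optional named list applied after the file.
#' @return A named list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    holding_mV = -60,
    step_start_s = 0.1,
    step_duration_s = 0.8,
    test_potentials_mV = seq(-140, 40, by = 20),
    sample_rate_hz = 1000,
    voltage_range_mV = c(-120, 20),
    fit_window_s = c(0.005, NA),
    tail_s = 0.1,
    smooth_window = 0,
    plateau_threshold = 0.1,
    noise_sd_nA = 1,
    seed = NULL,
    out_dir = ".",
    log_level = "info"
  )
  apply_over <- function(cfg, ov, origin) {
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(cfg, ov)
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  if (length(overrides) > 0) cfg <- apply_over(cfg, overrides, "overrides")
  .validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

.validate_run_config <- function(cfg) {
  stopifnot(cfg$step_duration_s > 0, cfg$sample_rate_hz > 0,
            cfg$tail_s > 0, cfg$tail_s <= cfg$step_duration_s,
            cfg$plateau_threshold > 0, cfg$noise_sd_nA >= 0,
            length(cfg$voltage_range_mV) == 2,
            cfg$voltage_range_mV[1] < cfg$voltage_range_mV[2],
            length(cfg$fit_window_s) == 2)
  if (!is.null(cfg$seed)) stopifnot(is.finite(cfg$seed))
  invisible(cfg)
}

#' Configuration hash
#'
#' MD5 digest of the semantically meaningful configuration fields (output
#' directory and log level are excluded), computed over a canonical JSON
#' serialization with sorted keys. The hash recorded in run outputs
#' therefore changes iff an analysis-relevant field changes.
#'
#' @param cfg A `run_config` (or plain named list).
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  cfg$log_level <- NULL
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else {
      x
    }
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(canon(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  unname(tools::md5sum(tmp))
}

.log_levels <- c(debug = 1, info = 2, warn = 3, error = 4)

#' Run logger
#'
#' Minimal leveled logger writing human-readable lines to a text file (and
#' optionally to stderr) plus a JSON sidecar with the structured run record
#' (inputs, seed, config hash, package version).
#'
#' @param dir Directory for `run_log.txt` / `run_log.json`; `NULL` logs to
#'   stderr only.
#' @param level Minimum level to emit (`"debug"`, `"info"`, `"warn"`,
#'   `"error"`).
#' @param echo Also print to stderr?
#' @return List with functions `log(level, msg)` and
#'   `finalize(record)`.
#' @export
run_logger <- function(dir = NULL, level = "info", echo = FALSE) {
  threshold <- .log_levels[[level]]
  txt_path <- if (!is.null(dir)) file.path(dir, "run_log.txt") else NULL
  json_path <- if (!is.null(dir)) file.path(dir, "run_log.json") else NULL
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(lvl, msg) {
    if (.log_levels[[lvl]] < threshold) return(invisible(NULL))
    line <- sprintf("[%s] %s: %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    toupper(lvl), msg)
    if (!is.null(txt_path)) cat(line, "\n", file = txt_path, append = TRUE,
                                sep = "")
    if (echo || is.null(txt_path)) message(line)
    invisible(NULL)
  }
  finalize <- function(record) {
    record$version <- as.character(utils::packageVersion("gatkit"))
    record$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    if (!is.null(json_path)) write_report_json(record, json_path)
    invisible(record)
  }
  list(log = log, finalize = finalize)
}
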