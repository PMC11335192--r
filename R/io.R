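#' Canonical sweep CSV format
#'
#' A recording set is written as a plain-text CSV preceded by `#`-prefixed
#' metadata lines (`# key: value`). Required keys: `condition_label`,
#' `holding_mV`, `step_start_s`, `step_duration_s`, `sample_rate_hz`. The
#' first column is `time_s`; each remaining column is one test potential,
#' named `I_<V>mV` (e.g. `I_-140mV`). Numbers are written with 17
#' significant digits so a write/read round trip is exact to double
#' precision, with `.` as the decimal separator regardless of locale.
#'
#' @param rs A [recording_set()].
#' @param path Output file path.
#' @param extra_header Optional named character vector of additional
#'   metadata lines (e.g. seed and generator parameters).
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(rs, path, extra_header = NULL) {
  stopifnot(inherits(rs, "recording_set"))
  p <- rs$protocol
  hdr <- c(condition_label = rs$condition_label,
           holding_mV = sprintf("%.17g", p$holding_mV),
           step_start_s = sprintf("%.17g", p$step_start_s),
           step_duration_s = sprintf("%.17g", p$step_duration_s),
           sample_rate_hz = sprintf("%.17g", p$sample_rate_hz))
  if (!is.null(extra_header)) hdr <- c(hdr, extra_header)
  lines <- sprintf("# %s: %s", names(hdr), unname(hdr))
  cols <- c("time_s", sprintf("I_%smV", format(p$test_potentials_mV,
                                               trim = TRUE, scientific = FALSE)))
  t <- rs$sweeps[[1]]$time_s
  mat <- vapply(rs$sweeps, function(s) s$current_nA, numeric(length(t)))
  body <- cbind(sprintf("%.17g", t),
                apply(mat, 2, function(x) sprintf("%.17g", x)))
  lines <- c(lines, paste(cols, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

.parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  stats::setNames(vals, trimws(keys))
}

#' Read a canonical sweep CSV
#'
#' Parses the format written by [write_sweep_csv()]. Potential columns are
#' reordered ascending on load; a missing metadata key, a non-uniform time
#' grid, duplicate potential columns, or a truncated row raise a format
#' error naming the offending line or column.
#'
#' @param path File path.
#' @return A [recording_set()] (its `solution` holds the parsed metadata).
#' @export
read_sweep_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  n_hdr <- match(FALSE, is_hdr) - 1
  if (is.na(n_hdr) || n_hdr < 1) {
    stop("format error in ", path, ": no '#' metadata header", call. = FALSE)
  }
  meta <- .parse_header(lines[seq_len(n_hdr)])
  required <- c("condition_label", "holding_mV", "step_start_s",
                "step_duration_s", "sample_rate_hz")
  missing_keys <- setdiff(required, names(meta))
  if (length(missing_keys) > 0) {
    stop("format error in ", path, ": missing metadata key(s) ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  data_lines <- lines[!is_hdr]
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  ncol_expect <- length(fields[[1]])
  bad <- which(lengths(fields) != ncol_expect)
  if (length(bad) > 0) {
    stop("format error in ", path, ": row ", bad[1] + n_hdr,
         " has ", lengths(fields)[bad[1]], " fields (expected ",
         ncol_expect, ")", call. = FALSE)
  }
  cols <- fields[[1]]
  if (cols[1] != "time_s") {
    stop("format error in ", path, ": first column must be time_s",
         call. = FALSE)
  }
  pot_cols <- cols[-1]
  m <- regmatches(pot_cols, regexec("^I_(-?[0-9.]+)mV$", pot_cols))
  bad_col <- which(lengths(m) != 2)
  if (length(bad_col) > 0) {
    stop("format error in ", path, ": column '", pot_cols[bad_col[1]],
         "' is not of the form I_<V>mV", call. = FALSE)
  }
  pots <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  if (anyDuplicated(pots)) {
    stop("format error in ", path, ": duplicate potential column ",
         pots[duplicated(pots)][1], " mV", call. = FALSE)
  }
  num <- matrix(as.numeric(unlist(fields[-1])), ncol = ncol_expect,
                byrow = TRUE)
  if (any(is.na(num))) {
    bad_row <- which(apply(num, 1, anyNA))[1]
    stop("format error in ", path, ": non-numeric value in row ",
         bad_row + n_hdr + 1, call. = FALSE)
  }
  t <- num[, 1]
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("format error in ", path, ": non-uniform time grid near row ",
         which.max(abs(dt - dt[1])) + n_hdr + 1, call. = FALSE)
  }
  ord <- order(pots)
  protocol <- voltage_step_protocol(
    holding_mV = as.numeric(meta[["holding_mV"]]),
    step_start_s = as.numeric(meta[["step_start_s"]]),
    step_duration_s = as.numeric(meta[["step_duration_s"]]),
    test_potentials_mV = pots[ord],
    sample_rate_hz = as.numeric(meta[["sample_rate_hz"]])
  )
  sweeps <- lapply(ord, function(j) sweep_trace(pots[j], t, num[, j + 1]))
  recording_set(condition_label = meta[["condition_label"]],
                solution = as.list(meta),
                sweeps = sweeps, protocol = protocol)
}

#' Condition manifest I/O
#'
#' A manifest lists the sweep CSV files of one analysis group: columns
#' `file_path`, `condition_label`, `gaba_uM`, `betaine_mM`, `blocker`
#' (logical), `cell_id`, `batch_id`. File paths must be unique and exactly
#' one condition per group must be the blocker.
#'
#' @param manifest `data.frame` with the columns above.
#' @param path CSV file path.
#' @return `write_manifest_csv`: `path` invisibly; `read_manifest_csv`: the
#'   validated manifest `data.frame`.
#' @export
write_manifest_csv <- function(manifest, path) {
  .validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_manifest(manifest)
  manifest
}

.validate_manifest <- function(manifest) {
  need <- c("file_path", "condition_label", "blocker")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$file_path)) {
    stop("manifest file paths must be unique", call. = FALSE)
  }
  if (sum(as.logical(manifest$blocker)) != 1) {
    stop("manifest must mark exactly one blocker condition", call. = FALSE)
  }
  invisible(manifest)
}

#' Dose-response CSV I/O
#'
#' Columns: `conc`, `unit`, `mean_current_nA`, `sem_nA`, `n`.
#'
#' @param table A [dose_response_table()].
#' @param path CSV file path.
#' @return `write_dose_csv`: `path` invisibly; `read_dose_csv`: a
#'   [dose_response_table()].
#' @export
write_dose_csv <- function(table, path) {
  stopifnot(inherits(table, "dose_response_table"))
  df <- data.frame(conc = table$concentration,
                   unit = attr(table, "unit") %||% "mM",
                   mean_current_nA = table$mean_current_nA,
                   sem_nA = table$sem_nA,
                   n = table$n_cells)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_dose_csv
#' @export
read_dose_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conc", "unit", "mean_current_nA")
  if (!all(need %in% names(df))) {
    stop("dose CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(df$unit)) != 1) {
    stop("inconsistent concentration units in ", path, call. = FALSE)
  }
  ord <- order(df$conc)
  dose_response_table(df$conc[ord], df$mean_current_nA[ord],
                      sem_nA = if ("sem_nA" %in% names(df)) df$sem_nA[ord]
                               else NA_real_,
                      n_cells = if ("n" %in% names(df)) df$n[ord] else 1L,
                      unit = df$unit[1])
}

#' Competition long-format CSV I/O
#'
#' Columns: `gaba_uM`, `betaine_mM`, `current_nA`, `cell_id`, `batch_id`.
#'
#' @param records Long-format `data.frame` (see
#'   [simulate_competition_records()]).
#' @param path CSV file path.
#' @return `write_competition_csv`: `path` invisibly;
#'   `read_competition_csv`: the records `data.frame`.
#' @export
write_competition_csv <- function(records, path) {
  need <- c("gaba_uM", "betaine_mM", "current_nA")
  stopifnot(all(need %in% names(records)))
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_competition_csv
#' @export
read_competition_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gaba_uM", "betaine_mM", "current_nA")
  if (!all(need %in% names(df))) {
    stop("competition CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Efflux CSV I/O
#'
#' One row per (well, fraction) with columns `well_id`, `condition`, `dose`,
#' `dose_unit`, `monensin`, `fraction_index`, `released_counts`, plus one
#' row per well with empty `fraction_index` carrying `remaining_counts`.
#'
#' @param time_courses Named list of [efflux_time_course()] objects (names
#'   are well ids).
#' @param path CSV file path.
#' @return `write_efflux_csv`: `path` invisibly; `read_efflux_csv`: a named
#'   list of [efflux_time_course()] objects.
#' @export
write_efflux_csv <- function(time_courses, path) {
  stopifnot(is.list(time_courses), length(time_courses) >= 1,
            !is.null(names(time_courses)))
  rows <- lapply(names(time_courses), function(w) {
    tc <- time_courses[[w]]
    stopifnot(inherits(tc, "efflux_time_course"))
    k <- length(tc$released_counts)
    rbind(
      data.frame(well_id = w,
                 condition = tc$condition$drug %||% "drug",
                 dose = tc$condition$dose %||% NA_real_,
                 dose_unit = tc$condition$dose_unit %||% "mM",
                 monensin = isTRUE(tc$condition$monensin),
                 fraction_minutes = tc$fraction_minutes,
                 n_basal = tc$n_basal,
                 fraction_index = seq_len(k),
                 released_counts = tc$released_counts,
                 remaining_counts = NA_real_),
      data.frame(well_id = w,
                 condition = tc$condition$drug %||% "drug",
                 dose = tc$condition$dose %||% NA_real_,
                 dose_unit = tc$condition$dose_unit %||% "mM",
                 monensin = isTRUE(tc$condition$monensin),
                 fraction_minutes = tc$fraction_minutes,
                 n_basal = tc$n_basal,
                 fraction_index = NA_integer_,
                 released_counts = NA_real_,
                 remaining_counts = tc$remaining_counts)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' @rdname write_efflux_csv
#' @export
read_efflux_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "dose", "fraction_index", "released_counts",
            "remaining_counts")
  if (!all(need %in% names(df))) {
    stop("efflux CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$well_id), function(d) {
    fr <- d[!is.na(d$fraction_index), ]
    fr <- fr[order(fr$fraction_index), ]
    rem <- d$remaining_counts[is.na(d$fraction_index)]
    if (length(rem) != 1) {
      stop("well ", d$well_id[1],
           " must have exactly one remaining_counts row", call. = FALSE)
    }
    efflux_time_course(
      released_counts = fr$released_counts,
      remaining_counts = rem,
      fraction_minutes = fr$fraction_minutes[1] %||% 2,
      condition = list(drug = fr$condition[1], dose = fr$dose[1],
                       dose_unit = fr$dose_unit[1],
                       monensin = isTRUE(as.logical(fr$monensin[1]))),
      n_basal = fr$n_basal[1] %||% 4
    )
  })
  out[unique(df$well_id)]
}

#' Fit-report JSON I/O and validation
#'
#' Reports are plain nested lists written with scalars unboxed and full
#' numeric precision. [validate_report()] checks a report against the JSON
#' schema shipped with the package (`inst/schema/fit-report.schema.json`):
#' the required top-level fields and their types.
#'
#' @param report Named list.
#' @param path JSON file path.
#' @return `write_report_json`: `path` invisibly; `read_report_json`: the
#'   parsed list; `validate_report`: `TRUE` or an error.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_report_json
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "fit-report.schema.json",
                             package = "gatkit")
  schema <- jsonlite::read_json(schema_path)
  req <- unlist(schema$required)
  missing_keys <- setdiff(req, names(report))
  if (length(missing_keys) > 0) {
    stop("report is missing required field(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  types <- vapply(schema$properties[req], function(p) p$type %||% "object",
                  character(1))
  for (k in req) {
    v <- report[[k]]
    ok <- switch(types[[k]],
                 string = is.character(v),
                 number = is.numeric(v),
                 integer = is.numeric(v),
                 object = is.list(v),
                 array = TRUE,
                 TRUE)
    if (!ok) {
      stop("report field '", k, "' has the wrong type (expected ",
           types[[k]], ")", call. = FALSE)
    }
  }
  TRUE
}

#' Write the table outputs of a PSS analysis
#'
#' Emits `QV.csv` (V_mV, Q_nC, se), `tauV.csv` (V_mV, tau_s, se),
#' `rates.csv` (V_mV, inrate_per_s, outrate_per_s), `iv.csv` (V_mV, I_nA)
#' and `fit_report.json` (all parameters, standard errors, windows and
#' excluded potentials) into a directory.
#'
#' @param pss A [run_pss_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_pss_outputs <- function(pss, dir) {
  stopifnot(inherits(pss, "pss_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(pss$qv)) wr(pss$qv, "QV.csv")
  if (!is.null(pss$tauv)) wr(pss$tauv, "tauV.csv")
  if (!is.null(pss$rates)) {
    wr(pss$rates[, c("V_mV", "inrate_per_s", "outrate_per_s")], "rates.csv")
  }
  if (!is.null(pss$iv)) wr(pss$iv, "iv.csv")
  b <- pss$boltzmann
  report <- list(
    tool = "gatkit",
    version = as.character(utils::packageVersion("gatkit")),
    analysis = "pss_pipeline",
    boltzmann = if (isTRUE(b$converged)) {
      list(Qmax_nC = b$Qmax_nC, V_half_mV = b$V_half_mV,
           sigma_mV = b$sigma_mV, Q_offset_nC = b$Q_offset_nC,
           se = as.list(b$se), decreasing = b$decreasing, converged = TRUE)
    } else {
      list(converged = FALSE)
    },
    fit_window_s = pss$config$fit_window_offsets_s,
    voltage_range_mV = pss$config$voltage_range_mV,
    excluded = pss$excluded
  )
  p <- file.path(dir, "fit_report.json")
  write_report_json(report, p)
  paths <- c(paths, p)
  invisible(paths)
}
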