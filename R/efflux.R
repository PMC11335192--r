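#' Superfusion efflux time course
#'
#' Per-fraction released tracer counts from one well plus the tracer left in
#' the cells at the end; the total (released + remaining) defines 100%.
#'
#' @param released_counts Tracer counts released per fraction (>= 0,
#'   at least 2 fractions).
#' @param remaining_counts Tracer counts left in the cells (>= 0).
#' @param fraction_minutes Fraction length in minutes (default 2).
#' @param condition List describing the condition (`drug`, `dose`,
#'   `monensin`).
#' @param n_basal Number of leading drug-free (basal) fractions.
#' @return Object of class `efflux_time_course`.
#' @export
efflux_time_course <- function(released_counts, remaining_counts,
                               fraction_minutes = 2,
                               condition = list(), n_basal = 4) {
  stopifnot(length(released_counts) >= 2, all(released_counts >= 0),
            length(remaining_counts) == 1, remaining_counts >= 0,
            fraction_minutes > 0, n_basal >= 0,
            n_basal <= length(released_counts))
  structure(list(released_counts = as.numeric(released_counts),
                 remaining_counts = as.numeric(remaining_counts),
                 fraction_minutes = fraction_minutes,
                 condition = condition,
                 n_basal = as.integer(n_basal)),
            class = "efflux_time_course")
}

#' @export
print.efflux_time_course <- function(x, ...) {
  cat(sprintf(
    "Efflux time course: %d fractions of %g min (%d basal), dose = %s\n",
    length(x$released_counts), x$fraction_minutes, x$n_basal,
    format(x$condition$dose %||% NA)))
  invisible(x)
}

#' Per-fraction fractional release
#'
#' Expresses each fraction's released tracer as a percentage of the total
#' radioactivity (all supernatants plus the remaining cell content = 100%).
#' By construction the percent series plus the remaining percentage sums to
#' exactly 100.
#'
#' @param time_course An [efflux_time_course()].
#' @return Numeric vector of per-fraction percentages, with the remaining
#'   percentage as attribute `"remaining_percent"`.
#' @export
fractional_release <- function(time_course) {
  stopifnot(inherits(time_course, "efflux_time_course"))
  total <- sum(time_course$released_counts) + time_course$remaining_counts
  if (total <= 0) stop("total tracer content must be positive", call. = FALSE)
  pct <- 100 * time_course$released_counts / total
  attr(pct, "remaining_percent") <- 100 * time_course$remaining_counts / total
  pct
}

#' Basal efflux rate
#'
#' Mean fractional release over the leading drug-free fractions divided by
#' the fraction length, in % min^-1, with the SE taken from the
#' between-fraction scatter.
#'
#' @param time_course An [efflux_time_course()].
#' @param n_basal Number of basal fractions to use; defaults to the time
#'   course's own count. At least 2 are required.
#' @return List with `rate_pct_per_min`, `se`, `n`.
#' @export
basal_rate <- function(time_course, n_basal = NULL) {
  stopifnot(inherits(time_course, "efflux_time_course"))
  nb <- n_basal %||% time_course$n_basal
  if (nb < 2) stop("need at least 2 basal fractions", call. = FALSE)
  if (nb > length(time_course$released_counts)) {
    stop("n_basal exceeds the number of fractions", call. = FALSE)
  }
  pct <- fractional_release(time_course)[seq_len(nb)]
  rates <- pct / time_course$fraction_minutes
  list(rate_pct_per_min = mean(rates),
       se = stats::sd(rates) / sqrt(nb),
       n = nb)
}

#' Drug-induced efflux from the plateau fraction
#'
#' Identifies the plateau of the drug phase as the first drug fraction whose
#' percent differs from the next fraction by less than
#' `plateau_threshold` x (drug-phase range); a flat drug phase plateaus at
#' its first fraction, and when no plateau is detectable the final fraction
#' is used and flagged. The induced efflux is the plateau-fraction percent
#' divided by the fraction length; it is reported both uncorrected and with
#' the basal rate subtracted, since published values do not always state
#' which convention was used.
#'
#' @param time_course An [efflux_time_course()].
#' @param n_basal Number of leading basal fractions; defaults to the time
#'   course's own count.
#' @param plateau_threshold Fraction of the drug-phase range below which two
#'   successive fractions count as plateaued (default 0.1).
#' @return List with `uncorrected_pct_per_min`, `corrected_pct_per_min`,
#'   `plateau_fraction` (index within the drug phase), `no_plateau` flag.
#' @export
induced_efflux <- function(time_course, n_basal = NULL,
                           plateau_threshold = 0.1) {
  stopifnot(inherits(time_course, "efflux_time_course"),
            plateau_threshold > 0)
  nb <- n_basal %||% time_course$n_basal
  pct <- fractional_release(time_course)
  if (length(pct) - nb < 2) {
    stop("need at least 2 drug-phase fractions", call. = FALSE)
  }
  d <- pct[(nb + 1):length(pct)]
  rng <- diff(range(d))
  no_plateau <- FALSE
  if (rng < .Machine$double.eps) {
    plateau <- 1L  # a flat series is already a plateau
  } else {
    hits <- which(abs(diff(d)) < plateau_threshold * rng)
    if (length(hits) > 0) {
      plateau <- hits[1]
    } else {
      plateau <- length(d)
      no_plateau <- TRUE
    }
  }
  unc <- d[plateau] / time_course$fraction_minutes
  bas <- tryCatch(basal_rate(time_course, nb)$rate_pct_per_min,
                  error = function(e) NA_real_)
  list(uncorrected_pct_per_min = unc,
       corrected_pct_per_min = unc - bas,
       plateau_fraction = plateau,
       no_plateau = no_plateau)
}

#' Concentration-response fit of induced efflux
#'
#' Logistic (Hill) fit of the induced efflux rates against drug dose,
#' `induced(d) = max_induced * d^p / (d^p + K_half^p)`. Datasets with and
#' without monensin are fitted independently; a degenerate (all-equal)
#' response yields `converged = FALSE`.
#'
#' @param doses Drug doses (> 0, >= 4 values).
#' @param induced_values Induced efflux per dose (% min^-1).
#' @param with_monensin Logical label recorded with the fit.
#' @param fix_p Optional fixed Hill exponent.
#' @param basal Optional basal rate (list or number) stored with the fit.
#' @param unit Dose unit label.
#' @return Object of class `efflux_kinetics`: `K_half`, `max_induced`, `p`,
#'   `se`, `cov`, `converged`, `with_monensin`, `basal`, `unit`.
#' @export
fit_efflux_kinetics <- function(doses, induced_values, with_monensin = FALSE,
                                fix_p = NULL, basal = NULL, unit = "mM") {
  stopifnot(length(doses) == length(induced_values))
  if (length(doses) < 4) stop("need >= 4 doses", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  blank <- structure(list(K_half = NA_real_, max_induced = NA_real_,
                          p = fix_p %||% NA_real_, se = NULL, cov = NULL,
                          converged = FALSE, with_monensin = with_monensin,
                          basal = basal, unit = unit,
                          doses = doses, induced = induced_values),
                     class = "efflux_kinetics")
  if (diff(range(induced_values)) < 1e-12) return(blank)

  tab <- dose_response_table(sort(doses),
                             induced_values[order(doses)], unit = unit)
  fit <- tryCatch(suppressMessages(fit_dose_response(tab, fix_p = fix_p)),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(blank)
  se <- fit$se
  if (!is.null(se)) {
    names(se) <- sub("^Imax$", "max_induced", names(se))
    names(se) <- sub("^K$", "K_half", names(se))
  }
  structure(list(K_half = fit$K_half, max_induced = fit$Imax_nA, p = fit$p,
                 se = se, cov = fit$cov, converged = TRUE,
                 with_monensin = with_monensin, basal = basal, unit = unit,
                 doses = doses, induced = induced_values),
            class = "efflux_kinetics")
}

#' @export
print.efflux_kinetics <- function(x, ...) {
  if (!x$converged) {
    cat("Efflux kinetics: NOT converged (degenerate or failed fit)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Efflux kinetics%s: K_half = %.4g %s, max induced = %.4g %%/min, p = %.3g\n",
    if (isTRUE(x$with_monensin)) " (with monensin)" else "",
    x$K_half, x$unit, x$max_induced, x$p))
  invisible(x)
}
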