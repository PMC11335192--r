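#' Default configuration of the pre-steady-state pipeline
#'
#' @param voltage_range_mV Analysis range (mV); potentials outside it are
#'   not analyzed. Default -120 to +20 mV even when the protocol spans
#'   -140 to +40 mV, excluding the extremes where relaxations are fastest.
#' @param fit_window_offsets_s Relaxation fit window, seconds after step
#'   onset; `NA` as the second element means the step end.
#' @param tail_s Steady-current averaging window (s).
#' @param smooth_window Adjacent-averaging window in samples; 0 disables
#'   smoothing (simulated traces are band-limited already).
#' @return A list of class `pss_config`.
#' @export
pss_config <- function(voltage_range_mV = c(-120, 20),
                       fit_window_offsets_s = c(0.005, NA),
                       tail_s = 0.1,
                       smooth_window = 0) {
  stopifnot(length(voltage_range_mV) == 2,
            voltage_range_mV[1] < voltage_range_mV[2],
            length(fit_window_offsets_s) == 2)
  structure(list(voltage_range_mV = voltage_range_mV,
                 fit_window_offsets_s = fit_window_offsets_s,
                 tail_s = tail_s,
                 smooth_window = smooth_window),
            class = "pss_config")
}

#' Full pre-steady-state analysis pipeline
#'
#' Runs the complete charge-movement analysis on a pair of recording sets:
#' blocker subtraction, optional smoothing, per-potential single-exponential
#' relaxation fitting, charge integration, Boltzmann Q-V fitting, derivation
#' of unidirectional rate constants, and the steady-current I-V table.
#' Potentials whose relaxation fit does not converge are excluded from the
#' Q-V/tau-V tables and reported in `excluded`; a failed Boltzmann stage is
#' flagged rather than raised.
#'
#' @param test [recording_set()] of the test condition.
#' @param blocker [recording_set()] of the blocker condition.
#' @param config A [pss_config()].
#' @return Object of class `pss_analysis`: list with `qv` (V_mV, Q_nC, se),
#'   `tauv` (V_mV, tau_s, se), `boltzmann` ([fit_boltzmann()] result or a
#'   non-converged placeholder), `rates` ([derive_rates()] table or `NULL`),
#'   `iv` (V_mV, I_nA), `excluded` (V_mV, stage, reason), `subtracted`
#'   (the difference recording set), `config`.
#' @export
run_pss_pipeline <- function(test, blocker, config = pss_config()) {
  stopifnot(inherits(config, "pss_config"))
  sub <- subtract_blocker(test, blocker)
  protocol <- sub$protocol
  pots <- protocol$test_potentials_mV
  pots <- pots[pots >= config$voltage_range_mV[1] &
                 pots <= config$voltage_range_mV[2]]

  w1 <- config$fit_window_offsets_s[2]
  if (is.na(w1)) w1 <- NULL

  qv <- tauv <- NULL
  excluded <- data.frame(V_mV = numeric(0), stage = character(0),
                         reason = character(0))
  relax_fits <- list()
  for (v in pots) {
    if (v == protocol$holding_mV) {
      # a step to the holding potential displaces no charge by construction;
      # it enters the Q-V table as the exact reference point below
      next
    }
    sw <- get_sweep(sub, v)
    if (config$smooth_window > 1) {
      sw <- smooth_adjacent_average(sw, config$smooth_window)
    }
    fit <- tryCatch(
      fit_relaxation(sw, protocol,
                     window_start_offset_s = config$fit_window_offsets_s[1],
                     window_end_offset_s = w1),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      excluded <- rbind(excluded,
                        data.frame(V_mV = v, stage = "relaxation",
                                   reason = conditionMessage(fit)))
      next
    }
    relax_fits[[as.character(v)]] <- fit
    if (!fit$converged) {
      excluded <- rbind(excluded,
                        data.frame(V_mV = v, stage = "relaxation",
                                   reason = "fit did not converge"))
      next
    }
    qp <- integrate_charge(fit)
    qv <- rbind(qv, data.frame(V_mV = v, Q_nC = qp$Q_nC, se = qp$se_nC))
    tauv <- rbind(tauv, data.frame(V_mV = v, tau_s = fit$tau_s,
                                   se = unname(fit$se[["tau"]])))
  }

  # integrated charge is referenced to the holding potential, so dQ(Vh) = 0
  # exactly; include the reference as an anchor point when Vh lies in the
  # analysis range
  if (!is.null(qv) && protocol$holding_mV >= config$voltage_range_mV[1] &&
      protocol$holding_mV <= config$voltage_range_mV[2]) {
    qv <- rbind(qv, data.frame(V_mV = protocol$holding_mV, Q_nC = 0,
                               se = min(qv$se, na.rm = TRUE)))
    qv <- qv[order(qv$V_mV), ]
    rownames(qv) <- NULL
  }

  boltz <- structure(list(converged = FALSE), class = "boltzmann_fit")
  if (!is.null(qv) && nrow(qv) >= 5 && diff(range(qv$V_mV)) >= 80) {
    w <- if (all(is.finite(qv$se)) && all(qv$se > 0)) 1 / qv$se^2 else NULL
    boltz <- tryCatch(fit_boltzmann(qv[, c("V_mV", "Q_nC")], weights = w),
                      error = function(e) boltz)
  }
  rates <- NULL
  if (isTRUE(boltz$converged) && !is.null(tauv)) {
    rates <- derive_rates(boltz, tauv[, c("V_mV", "tau_s")])
  }

  iv <- do.call(rbind, lapply(pots, function(v) {
    data.frame(V_mV = v,
               I_nA = measure_steady_current(get_sweep(sub, v), protocol,
                                             config$tail_s))
  }))

  structure(list(qv = qv, tauv = tauv, boltzmann = boltz, rates = rates,
                 iv = iv, excluded = excluded, relaxations = relax_fits,
                 subtracted = sub, config = config),
            class = "pss_analysis")
}

#' @export
print.pss_analysis <- function(x, ...) {
  cat("Pre-steady-state analysis\n")
  cat(sprintf("  analyzed potentials: %d; excluded: %d\n",
              if (is.null(x$qv)) 0L else nrow(x$qv), nrow(x$excluded)))
  if (isTRUE(x$boltzmann$converged)) print(x$boltzmann)
  else cat("  Boltzmann fit: not available\n")
  invisible(x)
}
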