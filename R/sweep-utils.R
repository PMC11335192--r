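#' Adjacent-averaging smoothing of a sweep
#'
#' Replaces each sample by the mean of a window centred on it, truncating the
#' window at the trace edges. An even `window` is widened by one so the
#' window can be centred (the conventional 10-point setting becomes 11).
#'
#' @param sweep A [sweep_trace()].
#' @param window Window width in samples (>= 1).
#' @return The smoothed [sweep_trace()].
#' @export
#' @examples
#' sw <- sweep_trace(-60, (0:4) / 1000, c(0, 0, 3, 0, 0))
#' smooth_adjacent_average(sw, 3)$current_nA  # 0 1 1 1 0
smooth_adjacent_average <- function(sweep, window = 10) {
  stopifnot(inherits(sweep, "sweep"), window >= 1,
            window == round(window))
  n <- length(sweep$current_nA)
  if (window > n) {
    stop("smoothing window (", window, ") exceeds trace length (", n, ")",
         call. = FALSE)
  }
  if (window %% 2 == 0) window <- window + 1
  if (window == 1) return(sweep)
  half <- (window - 1) / 2
  y <- sweep$current_nA
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  sweep$current_nA <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  sweep
}

#' Isolate transporter currents by blocker subtraction
#'
#' Subtracts, potential by potential and sample by sample, the sweeps
#' recorded in the presence of a saturating transporter blocker from the
#' corresponding test sweeps. The blocker condition carries only the
#' capacitive transient and leak, so the difference isolates the
#' transporter-associated pre-steady-state and steady currents.
#'
#' @param test [recording_set()] of the test condition.
#' @param blocker [recording_set()] of the blocker condition.
#' @return A [recording_set()] of the differences, labelled
#'   `"<test> - <blocker>"`.
#' @export
subtract_blocker <- function(test, blocker) {
  stopifnot(inherits(test, "recording_set"),
            inherits(blocker, "recording_set"))
  bad <- .protocols_equal(test$protocol, blocker$protocol)
  if (!is.null(bad)) {
    stop("protocol mismatch between test and blocker: field '", bad, "'",
         call. = FALSE)
  }
  sweeps <- vector("list", length(test$sweeps))
  for (i in seq_along(test$sweeps)) {
    a <- test$sweeps[[i]]
    b <- blocker$sweeps[[i]]
    if (length(a$current_nA) != length(b$current_nA)) {
      stop("protocol mismatch between test and blocker: field 'sample count'",
           call. = FALSE)
    }
    sweeps[[i]] <- sweep_trace(a$test_potential_mV, a$time_s,
                               a$current_nA - b$current_nA)
  }
  recording_set(
    condition_label = paste(test$condition_label, "-",
                            blocker$condition_label),
    solution = test$solution,
    sweeps = sweeps,
    protocol = test$protocol
  )
}

#' Steady transport current of a sweep
#'
#' Mean current over the final `tail_s` seconds of the voltage step, minus
#' the pre-step holding baseline. At the default 100 ms tail the
#' pre-steady-state relaxation (time constants of tens of ms ending > 10
#' time constants earlier) has fully decayed.
#'
#' @param sweep A [sweep_trace()].
#' @param protocol The [voltage_step_protocol()] defining the step timing.
#' @param tail_s Length of the averaging window at the end of the step (s).
#' @return Steady current in nA (baseline-subtracted).
#' @export
measure_steady_current <- function(sweep, protocol, tail_s = 0.1) {
  stopifnot(inherits(sweep, "sweep"),
            inherits(protocol, "voltage_step_protocol"))
  if (tail_s <= 0 || tail_s > protocol$step_duration_s) {
    stop("tail_s must lie in (0, step_duration_s]", call. = FALSE)
  }
  t <- sweep$time_s
  t_on <- protocol$step_start_s
  t_off <- t_on + protocol$step_duration_s
  tail_idx <- t >= t_off - tail_s & t < t_off
  if (!any(tail_idx)) stop("tail window contains no samples", call. = FALSE)
  pre_idx <- t < t_on
  if (!any(pre_idx)) {
    stop("sweep has no pre-step samples for the holding baseline",
         call. = FALSE)
  }
  mean(sweep$current_nA[tail_idx]) - mean(sweep$current_nA[pre_idx])
}

#' Current-voltage table of a recording set
#'
#' Applies [measure_steady_current()] at every protocol potential.
#'
#' @param rs A [recording_set()].
#' @param tail_s Averaging window at the end of the step (s).
#' @return `data.frame` with columns `V_mV`, `I_nA`.
#' @export
measure_iv <- function(rs, tail_s = 0.1) {
  stopifnot(inherits(rs, "recording_set"))
  v <- rs$protocol$test_potentials_mV
  i <- vapply(v, function(vv) {
    measure_steady_current(get_sweep(rs, vv), rs$protocol, tail_s)
  }, numeric(1))
  data.frame(V_mV = v, I_nA = i)
}

#' Plateau current of a perfusion record
#'
#' Mean and standard deviation of the current over a closed time window,
#' the standard read-out for automated patch-clamp perfusion records where
#' the transport current plateaus a few seconds after substrate application
#' (default window 4-6 s).
#'
#' @param trace A [sweep_trace()] or any list/data.frame with elements
#'   `time_s` and `current_nA`.
#' @param t_start_s,t_end_s Window bounds (s), closed on both sides.
#' @return List with `mean_nA`, `sd_nA`, `n`.
#' @export
measure_plateau_current <- function(trace, t_start_s = 4, t_end_s = 6) {
  stopifnot(is.numeric(trace$time_s), is.numeric(trace$current_nA),
            t_end_s > t_start_s)
  t <- trace$time_s
  if (min(t) > t_start_s || max(t) < t_end_s) {
    stop("record does not cover the window [", t_start_s, ", ", t_end_s,
         "] s", call. = FALSE)
  }
  idx <- t >= t_start_s & t <= t_end_s
  y <- trace$current_nA[idx]
  list(mean_nA = mean(y),
       sd_nA = if (length(y) > 1) stats::sd(y) else 0,
       n = length(y))
}
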