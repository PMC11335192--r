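#' Voltage-step protocol
#'
#' Timing and potentials of a square-pulse voltage-step protocol. The default
#' is the standard two-electrode voltage-clamp protocol for transporter
#' pre-steady-state analysis: holding potential -60 mV, 0.8 s test pulses
#' from -140 to +40 mV in 20 mV increments, sampled at 1 kHz. Each sweep
#' contains a pre-step segment of `step_start_s` at the holding potential and
#' a post-step tail of equal length.
#'
#' @param holding_mV Holding potential between steps (mV).
#' @param step_start_s Time of the step onset within the sweep (s, > 0).
#' @param step_duration_s Duration of the test pulse (s, > 0).
#' @param test_potentials_mV Strictly increasing test potentials (mV).
#' @param sample_rate_hz Sampling rate (Hz, > 0).
#' @return An object of class `voltage_step_protocol`.
#' @export
#' @examples
#' voltage_step_protocol()
voltage_step_protocol <- function(holding_mV = -60,
                                  step_start_s = 0.1,
                                  step_duration_s = 0.8,
                                  test_potentials_mV = seq(-140, 40, by = 20),
                                  sample_rate_hz = 1000) {
  stopifnot(is.finite(holding_mV),
            step_start_s >= 0, step_duration_s > 0, sample_rate_hz > 0,
            length(test_potentials_mV) >= 1,
            all(is.finite(test_potentials_mV)))
  if (is.unsorted(test_potentials_mV, strictly = TRUE)) {
    stop("test_potentials_mV must be strictly increasing", call. = FALSE)
  }
  structure(
    list(holding_mV = holding_mV,
         step_start_s = step_start_s,
         step_duration_s = step_duration_s,
         test_potentials_mV = as.numeric(test_potentials_mV),
         sample_rate_hz = sample_rate_hz),
    class = "voltage_step_protocol"
  )
}

#' @export
print.voltage_step_protocol <- function(x, ...) {
  cat("Voltage-step protocol\n")
  cat(sprintf("  holding: %g mV; step: %g s starting at %g s; %g Hz\n",
              x$holding_mV, x$step_duration_s, x$step_start_s,
              x$sample_rate_hz))
  cat(sprintf("  test potentials: %s mV\n",
              paste(x$test_potentials_mV, collapse = ", ")))
  invisible(x)
}

.protocol_sweep_times <- function(protocol) {
  total_s <- 2 * protocol$step_start_s + protocol$step_duration_s
  n <- round(total_s * protocol$sample_rate_hz)
  (seq_len(n) - 1) / protocol$sample_rate_hz
}

.protocols_equal <- function(a, b) {
  for (field in c("holding_mV", "step_start_s", "step_duration_s",
                  "sample_rate_hz")) {
    if (!isTRUE(all.equal(a[[field]], b[[field]]))) return(field)
  }
  if (length(a$test_potentials_mV) != length(b$test_potentials_mV) ||
      !isTRUE(all.equal(a$test_potentials_mV, b$test_potentials_mV))) {
    return("test_potentials_mV")
  }
  NULL
}

#' Single voltage-step sweep
#'
#' A current trace recorded (or simulated) at one test potential. Time
#' samples must be uniformly spaced; currents are in nA with inward currents
#' negative.
#'
#' @param test_potential_mV Test potential of the step (mV).
#' @param time_s Uniformly spaced sample times (s), strictly increasing.
#' @param current_nA Current samples (nA), same length as `time_s`.
#' @return An object of class `sweep`.
#' @export
sweep_trace <- function(test_potential_mV, time_s, current_nA) {
  stopifnot(length(time_s) == length(current_nA), length(time_s) >= 2,
            is.finite(test_potential_mV))
  dt <- diff(time_s)
  if (any(dt <= 0) ||
      max(abs(dt - dt[1])) > 1e-9 * max(dt[1], .Machine$double.eps)) {
    stop("time_s must be strictly increasing with constant spacing",
         call. = FALSE)
  }
  structure(list(test_potential_mV = test_potential_mV,
                 time_s = as.numeric(time_s),
                 current_nA = as.numeric(current_nA)),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("Sweep at %+g mV: %d samples, %.3g s\n",
              x$test_potential_mV, length(x$time_s),
              x$time_s[length(x$time_s)] - x$time_s[1]))
  invisible(x)
}

#' Recording set: one sweep per protocol potential under one condition
#'
#' @param condition_label Text label of the solution condition.
#' @param solution Free-form descriptor of the solution (list; e.g. substrate
#'   concentrations and a blocker flag).
#' @param sweeps List with exactly one [sweep_trace()] per protocol test
#'   potential, in protocol order.
#' @param protocol The [voltage_step_protocol()] shared by all sweeps.
#' @return An object of class `recording_set`.
#' @export
recording_set <- function(condition_label, solution = list(), sweeps,
                          protocol) {
  stopifnot(is.character(condition_label), length(condition_label) == 1,
            inherits(protocol, "voltage_step_protocol"), is.list(sweeps))
  pots <- vapply(sweeps, function(s) s$test_potential_mV, numeric(1))
  if (length(pots) != length(protocol$test_potentials_mV) ||
      !isTRUE(all.equal(sort(pots), protocol$test_potentials_mV))) {
    stop("recording_set needs exactly one sweep per protocol potential",
         call. = FALSE)
  }
  sweeps <- sweeps[order(pots)]
  names(sweeps) <- as.character(protocol$test_potentials_mV)
  n <- vapply(sweeps, function(s) length(s$time_s), integer(1))
  if (length(unique(n)) != 1) {
    stop("all sweeps must share the protocol timing (sample counts differ)",
         call. = FALSE)
  }
  structure(list(condition_label = condition_label, solution = solution,
                 sweeps = sweeps, protocol = protocol),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("Recording set '%s': %d sweeps (%s mV)\n",
              x$condition_label, length(x$sweeps),
              paste(range(x$protocol$test_potentials_mV), collapse = " to ")))
  invisible(x)
}

#' Extract the sweep at a given test potential
#'
#' @param rs A [recording_set()].
#' @param test_potential_mV One of the protocol's test potentials.
#' @return The matching [sweep_trace()].
#' @export
get_sweep <- function(rs, test_potential_mV) {
  stopifnot(inherits(rs, "recording_set"))
  key <- as.character(test_potential_mV)
  sw <- rs$sweeps[[key]]
  if (is.null(sw)) {
    stop("no sweep at ", test_potential_mV, " mV in condition '",
         rs$condition_label, "'", call. = FALSE)
  }
  sw
}
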