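#' Boltzmann fit of a charge-voltage relationship
#'
#' Least-squares fit of the Boltzmann sigmoid
#' `Q(V) = Q_offset + Qmax / (1 + exp(-(V - V_half)/sigma))`
#' to displaced-charge points. A fitted offset is included because charge
#' integrated from step relaxations is only defined relative to the holding
#' potential. The slope sign is unconstrained during fitting; the reported
#' parameters are normalized so `sigma > 0`, with the orientation recorded
#' in the `decreasing` flag (`Qmax < 0` in the canonical form means the
#' displaced charge saturates on hyperpolarization, the usual case for ON
#' transients of sodium-coupled transporters).
#'
#' @param points `data.frame` with columns `V_mV` and `Q_nC` (at least 5
#'   points spanning at least 80 mV).
#' @param weights Optional fit weights (e.g. `1/se^2`).
#' @return An object of class `boltzmann_fit` with elements `Qmax_nC`,
#'   `V_half_mV`, `sigma_mV`, `Q_offset_nC`, `se` (named vector), `cov`,
#'   `converged`, `decreasing`.
#' @export
fit_boltzmann <- function(points, weights = NULL) {
  stopifnot(is.data.frame(points), all(c("V_mV", "Q_nC") %in% names(points)))
  points <- points[order(points$V_mV), ]
  v <- points$V_mV
  q <- points$Q_nC
  if (length(v) < 5) {
    stop("need at least 5 Q-V points (4 free parameters)", call. = FALSE)
  }
  if (diff(range(v)) < 80) {
    stop("Q-V points must span at least 80 mV", call. = FALSE)
  }
  q_lo <- mean(q[1:2])
  q_hi <- mean(q[(length(q) - 1):length(q)])
  qmax0 <- q_hi - q_lo
  if (qmax0 == 0) qmax0 <- max(diff(range(q)), .Machine$double.eps)
  mid <- q_lo + qmax0 / 2
  vh0 <- v[which.min(abs(q - mid))]
  start <- list(off = q_lo, qmax = qmax0, vh = vh0, sig = diff(range(v)) / 6)

  nls_args <- list(q ~ off + qmax / (1 + exp(-(v - vh) / sig)),
                   start = start,
                   control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(weights)) nls_args$weights <- weights
  fit <- tryCatch(
    suppressWarnings(do.call(minpack.lm::nlsLM, nls_args)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(Qmax_nC = NA_real_, V_half_mV = NA_real_,
                          sigma_mV = NA_real_, Q_offset_nC = NA_real_,
                          se = NULL, cov = NULL, converged = FALSE,
                          decreasing = NA, points = points),
                     class = "boltzmann_fit"))
  }
  cf <- stats::coef(fit)
  cov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  off <- cf[["off"]]; qmax <- cf[["qmax"]]
  vh <- cf[["vh"]]; sig <- cf[["sig"]]
  if (sig < 0) {
    # identical curve in the canonical sigma > 0 form:
    # off + qmax/(1+exp(-x/sig)) == (off + qmax) + (-qmax)/(1+exp(-x/|sig|))
    jac <- matrix(0, 4, 4, dimnames = list(NULL, c("off", "qmax", "vh", "sig")))
    jac[1, c("off", "qmax")] <- c(1, 1)
    jac[2, "qmax"] <- -1
    jac[3, "vh"] <- 1
    jac[4, "sig"] <- -1
    if (!is.null(cov)) cov <- jac %*% cov %*% t(jac)
    tmp <- c(off + qmax, -qmax, vh, -sig)
    off <- tmp[1]; qmax <- tmp[2]; vh <- tmp[3]; sig <- tmp[4]
  } else if (!is.null(cov)) {
    cov <- cov[c("off", "qmax", "vh", "sig"), c("off", "qmax", "vh", "sig")]
  }
  if (!is.null(cov)) {
    dimnames(cov) <- list(c("Q_offset", "Qmax", "V_half", "sigma"),
                          c("Q_offset", "Qmax", "V_half", "sigma"))
  }
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else NULL
  converged <- is.finite(sig) && sig != 0 && is.finite(qmax) && abs(qmax) > 0
  structure(
    list(Qmax_nC = qmax, V_half_mV = vh, sigma_mV = sig, Q_offset_nC = off,
         se = se, cov = cov, converged = converged,
         decreasing = qmax < 0, points = points),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Boltzmann fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Boltzmann Q-V fit (%s with V):\n  Qmax = %.4g nC, V_half = %.4g mV, sigma = %.4g mV, offset = %.4g nC\n",
    if (x$decreasing) "decreasing" else "increasing",
    abs(x$Qmax_nC), x$V_half_mV, x$sigma_mV, x$Q_offset_nC))
  if (!is.null(x$se)) {
    cat(sprintf("  SE: Qmax %.3g, V_half %.3g, sigma %.3g\n",
                x$se[["Qmax"]], x$se[["V_half"]], x$se[["sigma"]]))
  }
  invisible(x)
}

#' Evaluate a fitted Boltzmann curve
#'
#' @param object A converged [fit_boltzmann()] result.
#' @param V_mV Potentials at which to evaluate (mV).
#' @param ... Unused.
#' @return Fitted Q values (nC).
#' @export
predict.boltzmann_fit <- function(object, V_mV, ...) {
  stopifnot(isTRUE(object$converged))
  object$Q_offset_nC + object$Qmax_nC /
    (1 + exp(-(V_mV - object$V_half_mV) / object$sigma_mV))
}

#' Fraction of charge in the inner position
#'
#' The offset-free Boltzmann fraction `Q_in/Qmax` at each potential, taken
#' on the limb that approaches 1 on hyperpolarization when the fitted Q-V is
#' decreasing (the physically expected orientation for inward charge
#' movement).
#'
#' @param boltz A converged [fit_boltzmann()] result.
#' @param V_mV Potentials (mV).
#' @return Fractions in (0, 1).
#' @export
boltzmann_fraction_in <- function(boltz, V_mV) {
  stopifnot(inherits(boltz, "boltzmann_fit"), isTRUE(boltz$converged))
  f <- stats::plogis((V_mV - boltz$V_half_mV) / boltz$sigma_mV)
  if (isTRUE(boltz$decreasing)) 1 - f else f
}

#' Unidirectional rate constants from Q-V and tau-V relationships
#'
#' At each analyzed potential the relaxation rate `1/tau` is split into the
#' unidirectional components using the offset-free Boltzmann fraction
#' `Q_in/Qmax`:
#' `inrate = (1/tau) * Q_in/Qmax` and `outrate = (1/tau) * (1 - Q_in/Qmax)`.
#' The identity `inrate + outrate = 1/tau` holds exactly by construction,
#' and at `V = V_half` both rates equal `1/(2 tau)`. `inrate`/`outrate` are
#' the unidirectional constants often displayed as beta/alpha.
#'
#' @param boltz A converged [fit_boltzmann()] result.
#' @param tau_table `data.frame` with columns `V_mV` and `tau_s` (> 0).
#' @return `data.frame` of class `rate_table` with columns `V_mV`, `tau_s`,
#'   `inrate_per_s`, `outrate_per_s`.
#' @export
derive_rates <- function(boltz, tau_table) {
  stopifnot(inherits(boltz, "boltzmann_fit"),
            is.data.frame(tau_table),
            all(c("V_mV", "tau_s") %in% names(tau_table)))
  if (!isTRUE(boltz$converged)) {
    stop("Boltzmann fit did not converge; cannot derive rates",
         call. = FALSE)
  }
  if (any(!is.finite(tau_table$tau_s)) || any(tau_table$tau_s <= 0)) {
    stop("all tau values must be finite and > 0", call. = FALSE)
  }
  f_in <- boltzmann_fraction_in(boltz, tau_table$V_mV)
  out <- data.frame(V_mV = tau_table$V_mV,
                    tau_s = tau_table$tau_s,
                    inrate_per_s = f_in / tau_table$tau_s,
                    outrate_per_s = (1 - f_in) / tau_table$tau_s)
  class(out) <- c("rate_table", "data.frame")
  out
}
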