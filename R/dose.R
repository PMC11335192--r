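#' Dose-response table
#'
#' Per-concentration summary of transport currents. Concentrations must be
#' positive and strictly increasing; the unit travels with the table so
#' downstream fits report `K_half` in the right unit.
#'
#' @param concentration Concentrations (> 0, strictly increasing).
#' @param mean_current_nA Mean current per concentration (nA).
#' @param sem_nA SEM per concentration (nA; `NA` when unknown).
#' @param n_cells Number of cells per concentration (>= 1).
#' @param n_batches Number of batches per concentration.
#' @param unit Concentration unit, e.g. `"mM"` or `"uM"`.
#' @return `data.frame` of class `dose_response_table`.
#' @export
dose_response_table <- function(concentration, mean_current_nA,
                                sem_nA = NA_real_, n_cells = 1L,
                                n_batches = 1L, unit = "mM") {
  if (any(concentration <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (is.unsorted(concentration, strictly = TRUE)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  n <- length(concentration)
  out <- data.frame(concentration = concentration,
                    mean_current_nA = mean_current_nA,
                    sem_nA = rep_len(sem_nA, n),
                    n_cells = rep_len(as.integer(n_cells), n),
                    n_batches = rep_len(as.integer(n_batches), n))
  if (any(out$n_cells < 1)) stop("n_cells must be >= 1", call. = FALSE)
  attr(out, "unit") <- unit
  class(out) <- c("dose_response_table", "data.frame")
  out
}

.hill <- function(S, Imax, K, p) Imax * S^p / (S^p + K^p)

#' Hill/logistic dose-response fit
#'
#' Weighted least-squares fit of the logistic (Hill) model through the
#' origin, `I(S) = Imax * S^p / (S^p + K_half^p)`, to a dose-response table.
#' Weights are `1/sem^2` when every SEM is available and positive, otherwise
#' the fit is unweighted (with a notice). The exponent defaults to free with
#' initialization 1 and is reported so it can be fixed for comparison.
#'
#' @param table A [dose_response_table()] (or data.frame with the same
#'   columns).
#' @param fix_p Optional fixed Hill exponent; when given, only `Imax` and
#'   `K_half` are fitted (and 3 concentrations suffice).
#' @return Object of class `dose_response_fit` with `Imax_nA`, `K_half`,
#'   `p`, `unit`, `se` (named), `cov`, `converged`.
#' @export
fit_dose_response <- function(table, fix_p = NULL) {
  stopifnot(is.data.frame(table),
            all(c("concentration", "mean_current_nA") %in% names(table)))
  S <- table$concentration
  if (any(S <= 0)) stop("concentrations must be positive", call. = FALSE)
  y <- table$mean_current_nA
  unit <- attr(table, "unit") %||% "mM"
  min_n <- if (is.null(fix_p)) 4 else 3
  if (length(S) < min_n) {
    stop("need >= ", min_n, " concentrations", call. = FALSE)
  }

  blank <- structure(list(Imax_nA = NA_real_, K_half = NA_real_,
                          p = fix_p %||% NA_real_, unit = unit, se = NULL,
                          cov = NULL, converged = FALSE, table = table),
                     class = "dose_response_fit")
  if (all(abs(y) < 1e-12)) {
    blank$Imax_nA <- 0
    return(blank)
  }

  w <- NULL
  sem <- table$sem_nA
  if (!is.null(sem) && all(is.finite(sem)) && all(sem > 0)) {
    w <- 1 / sem^2
  } else {
    message("fit_dose_response: SEM unavailable or zero; unweighted fit")
  }

  i_top <- y[which.max(abs(y))]
  k0 <- S[which.min(abs(abs(y) - abs(i_top) / 2))]
  if (k0 <= min(S)) k0 <- stats::median(S)
  nls_args <- if (is.null(fix_p)) {
    list(y ~ Imax * S^p / (S^p + K^p),
         start = list(Imax = i_top, K = k0, p = 1),
         lower = c(Imax = -Inf, K = 1e-12, p = 1e-3),
         upper = c(Imax = Inf, K = Inf, p = 20),
         control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    p <- fix_p
    list(y ~ Imax * S^p / (S^p + K^p),
         start = list(Imax = i_top, K = k0),
         lower = c(Imax = -Inf, K = 1e-12),
         upper = c(Imax = Inf, K = Inf),
         control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  if (!is.null(w)) nls_args$weights <- w
  fit <- tryCatch(suppressWarnings(do.call(minpack.lm::nlsLM, nls_args)),
                  error = function(e) NULL)
  if (is.null(fit)) return(blank)

  cf <- stats::coef(fit)
  cov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else NULL
  p_hat <- if (is.null(fix_p)) unname(cf["p"]) else fix_p
  converged <- is.finite(cf[["K"]]) && cf[["K"]] > 0 && p_hat > 0
  structure(
    list(Imax_nA = unname(cf["Imax"]), K_half = unname(cf["K"]), p = p_hat,
         unit = unit, se = se, cov = cov, converged = converged,
         table = table),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Dose-response fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Hill/logistic fit: Imax = %.4g nA, K_half = %.4g %s, p = %.3g\n",
    x$Imax_nA, x$K_half, x$unit, x$p))
  eff <- transport_efficiency(x)
  cat(sprintf("  transport efficiency Imax/K_half = %.4g nA/%s",
              eff$efficiency, x$unit))
  if (is.finite(eff$se %||% NA_real_)) cat(sprintf(" (SE %.3g)", eff$se))
  cat("\n")
  invisible(x)
}

#' Evaluate a fitted dose-response curve
#'
#' @param object A converged [fit_dose_response()] result.
#' @param concentration Concentrations at which to evaluate.
#' @param ... Unused.
#' @return Fitted currents (nA).
#' @export
predict.dose_response_fit <- function(object, concentration, ...) {
  stopifnot(isTRUE(object$converged))
  .hill(concentration, object$Imax_nA, object$K_half, object$p)
}

#' Transport efficiency Imax/K_half
#'
#' The lumped low-substrate transport capacity `Imax / K_half` (nA per
#' concentration unit), with a first-order (delta-method) standard error
#' propagated from the fit covariance. When the covariance is unavailable
#' the value is still returned with `se = NA`.
#'
#' @param fit A converged [fit_dose_response()] result.
#' @return List with `efficiency`, `se`, `unit` (e.g. `"nA/mM"`).
#' @export
transport_efficiency <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!isTRUE(fit$converged)) {
    stop("dose-response fit did not converge", call. = FALSE)
  }
  if (fit$K_half <= 0) stop("K_half must be positive", call. = FALSE)
  eff <- fit$Imax_nA / fit$K_half
  se <- NA_real_
  if (!is.null(fit$cov) && all(c("Imax", "K") %in% rownames(fit$cov))) {
    gr <- c(1 / fit$K_half, -fit$Imax_nA / fit$K_half^2)
    v <- fit$cov[c("Imax", "K"), c("Imax", "K")]
    se <- sqrt(max(0, drop(t(gr) %*% v %*% gr)))
  }
  list(efficiency = eff, se = se, unit = paste0("nA/", fit$unit))
}
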