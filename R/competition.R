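#' Build a two-substrate competition grid from long-format measurements
#'
#' Aggregates replicate steady-current measurements into a GABA x betaine
#' grid of mean +/- SEM. Both axes should carry a zero level so the
#' substrate-only margins and the buffer-only reference cell exist; the full
#' crossing of 6 non-zero GABA and 11 non-zero betaine levels plus the two
#' margins and the buffer cell gives the canonical 84-condition composition.
#' Any composition is accepted; missing cells are `NA` and a mismatch with
#' the full crossing only warns.
#'
#' @param records `data.frame` with columns `gaba_uM`, `betaine_mM`,
#'   `current_nA` (one row per cell/measurement; extra columns ignored).
#' @return Object of class `competition_grid`: list with sorted axes
#'   `gaba_uM`, `betaine_mM`, matrices `mean_nA`, `sem_nA`, `n`
#'   (rows = GABA, cols = betaine), and `n_conditions`.
#' @export
build_competition_grid <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("gaba_uM", "betaine_mM", "current_nA")
  if (!all(need %in% names(records))) {
    stop("records must have columns gaba_uM, betaine_mM, current_nA ",
         "(inconsistent units/format?)", call. = FALSE)
  }
  if (any(!is.finite(records$current_nA))) {
    stop("non-finite current values in records", call. = FALSE)
  }
  g_lev <- sort(unique(records$gaba_uM))
  b_lev <- sort(unique(records$betaine_mM))
  fg <- factor(records$gaba_uM, levels = g_lev)
  fb <- factor(records$betaine_mM, levels = b_lev)
  mean_m <- tapply(records$current_nA, list(fg, fb), mean)
  n_m <- tapply(records$current_nA, list(fg, fb), length)
  sd_m <- tapply(records$current_nA, list(fg, fb), stats::sd)
  n_m[is.na(n_m)] <- 0
  sem_m <- sd_m / sqrt(n_m)  # NA when a single measurement (SEM undefined)
  if (!(0 %in% g_lev) || !(0 %in% b_lev) || n_m["0", "0"] == 0) {
    stop("grid must contain the buffer-only (0, 0) reference cell",
         call. = FALSE)
  }
  n_conditions <- sum(n_m > 0)
  if (n_conditions != length(g_lev) * length(b_lev)) {
    warning("grid composition incomplete: ", n_conditions, " of ",
            length(g_lev) * length(b_lev), " cells measured", call. = FALSE)
  }
  structure(list(gaba_uM = g_lev, betaine_mM = b_lev,
                 mean_nA = unclass(mean_m), sem_nA = unclass(sem_m),
                 n = unclass(n_m), n_conditions = n_conditions),
            class = "competition_grid")
}

#' @export
print.competition_grid <- function(x, ...) {
  cat(sprintf(
    "Competition grid: %d GABA x %d betaine levels, %d measured conditions\n",
    length(x$gaba_uM), length(x$betaine_mM), x$n_conditions))
  invisible(x)
}

.grid_row <- function(grid, gaba_uM) {
  i <- which(abs(grid$gaba_uM - gaba_uM) < 1e-12)
  if (length(i) != 1) {
    stop("no GABA row at ", gaba_uM, " uM in the grid", call. = FALSE)
  }
  i
}

#' Dual-effect (biphasic) analysis of one GABA row
#'
#' Characterizes the concentration-dependent dual action of the millimolar
#' substrate along one GABA row of a competition grid. The row is split at
#' the betaine level minimizing the current magnitude (ties broken toward
#' the lower concentration). When that minimum is interior and each limb
#' (split level included, since it anchors both) holds at least 3 levels,
#' the row is flagged biphasic: the descending limb (inhibition of the GABA
#' current) is fitted with a decreasing IC50-style logistic on the current
#' magnitude, and the ascending limb (added transport) with the Hill model
#' on the increments above the minimum (fitted only when at least 3 levels
#' lie strictly above the split; otherwise reported as unavailable).
#'
#' @param grid A [build_competition_grid()] result.
#' @param gaba_uM The GABA level of the row to analyze (uM).
#' @param fix_transport_p Hill exponent for the ascending-limb fit (default
#'   fixed at 1; `NULL` frees it when >= 4 points are available).
#' @return Object of class `dual_effect_fit`: `gaba_uM`,
#'   `split_betaine_mM`, `inhibition` (list with `top_nA`, `bottom_nA`,
#'   `IC50_mM`, `p`, `converged`, or `NULL`), `transport`
#'   ([fit_dose_response()] result on the increment, or `NULL`), `biphasic`,
#'   `reason`.
#' @export
analyze_dual_effect <- function(grid, gaba_uM, fix_transport_p = 1) {
  stopifnot(inherits(grid, "competition_grid"))
  i <- .grid_row(grid, gaba_uM)
  b <- grid$betaine_mM
  y <- grid$mean_nA[i, ]
  if (any(is.na(y))) {
    stop("row has unmeasured cells; cannot analyze", call. = FALSE)
  }
  mag <- abs(y)
  split_idx <- which.min(mag)  # first minimum = lowest betaine on ties
  split_b <- b[split_idx]
  interior <- split_idx > 1 && split_idx < length(b)
  enough <- split_idx >= 3 && (length(b) - split_idx + 1) >= 3
  reason <- if (!interior) {
    "current magnitude is monotone along the row (minimum at a boundary)"
  } else if (!enough) {
    "fewer than 3 betaine levels on one side of the split"
  } else {
    NA_character_
  }

  inhibition <- NULL
  if (interior && split_idx >= 3) {
    bi <- b[1:split_idx]
    yi <- mag[1:split_idx]
    ic0 <- bi[which.min(abs(yi - (max(yi) + min(yi)) / 2))]
    if (ic0 <= 0) ic0 <- stats::median(bi[bi > 0])
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(yi ~ bot + (top - bot) / (1 + (bi / ic50)^h),
                        start = list(top = yi[1], bot = min(yi),
                                     ic50 = ic0, h = 1),
                        lower = c(top = -Inf, bot = -Inf, ic50 = 1e-12,
                                  h = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    ), error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      inhibition <- list(top_nA = unname(cf["top"]),
                         bottom_nA = unname(cf["bot"]),
                         IC50_mM = unname(cf["ic50"]), p = unname(cf["h"]),
                         converged = TRUE)
    } else {
      inhibition <- list(converged = FALSE)
    }
  }

  transport <- NULL
  if (interior && length(b) - split_idx >= 3) {
    # ascending limb: increments above the minimum, strictly past the split
    # (anchoring the Hill fit at the zero increment makes it degenerate)
    bt <- b[(split_idx + 1):length(b)]
    inc <- mag[(split_idx + 1):length(b)] - mag[split_idx]
    tab <- dose_response_table(bt, inc, unit = "mM")
    p_fix <- if (length(bt) >= 4) fix_transport_p else (fix_transport_p %||% 1)
    transport <- tryCatch(
      suppressMessages(fit_dose_response(tab, fix_p = p_fix)),
      error = function(e) NULL
    )
  }

  biphasic <- interior && enough
  structure(list(gaba_uM = gaba_uM, split_betaine_mM = split_b,
                 inhibition = inhibition, transport = transport,
                 biphasic = biphasic, reason = reason,
                 betaine_mM = b, mean_nA = y),
            class = "dual_effect_fit")
}

#' @export
print.dual_effect_fit <- function(x, ...) {
  cat(sprintf("Dual-effect analysis at GABA %g uM: %s\n", x$gaba_uM,
              if (x$biphasic) {
                sprintf("biphasic, split at betaine %g mM", x$split_betaine_mM)
              } else {
                paste("not biphasic -", x$reason)
              }))
  invisible(x)
}

#' Row currents normalized to the GABA-alone reference
#'
#' Divides every cell of one GABA row by the betaine-free mean of that row,
#' giving the fraction of the GABA-alone current remaining at each betaine
#' level (1 at betaine 0 by construction). Standard errors are propagated
#' by the delta method assuming independent cells.
#'
#' @param grid A [build_competition_grid()] result.
#' @param gaba_uM The GABA level of the row (uM).
#' @return `data.frame` with `betaine_mM`, `fraction`, `se`.
#' @export
normalized_inhibition <- function(grid, gaba_uM) {
  stopifnot(inherits(grid, "competition_grid"))
  i <- .grid_row(grid, gaba_uM)
  j0 <- which(grid$betaine_mM == 0)
  if (length(j0) != 1 || is.na(grid$mean_nA[i, j0])) {
    stop("GABA-alone (betaine 0) cell missing for this row", call. = FALSE)
  }
  ref <- grid$mean_nA[i, j0]
  if (ref == 0) {
    stop("GABA-alone current is zero; cannot normalize", call. = FALSE)
  }
  m <- grid$mean_nA[i, ]
  s <- grid$sem_nA[i, ]
  s0 <- grid$sem_nA[i, j0]
  frac <- m / ref
  se <- sqrt((s / ref)^2 + (m * s0 / ref^2)^2)
  data.frame(betaine_mM = grid$betaine_mM, fraction = unname(frac),
             se = unname(se))
}
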