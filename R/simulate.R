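#' Steady-state current of the two-substrate transport model
#'
#' Evaluates the generative steady-state transport current for substrate
#' concentrations `G` (uM) and `B` (mM) at potential `V`:
#' `I = factor(V) * (I_G*g*S + I_B*b) / (1 + g + b)` with `g = G/K_G`,
#' `b = B/K_B` and `S = (1+g)/(1+g+B/K_inh)` (see
#' [two_substrate_params()]). With the default `K_inh = Inf` this is the
#' plain single-site competitive scheme.
#'
#' @param G_uM Concentration of substrate G (uM, >= 0).
#' @param B_mM Concentration of substrate B (mM, >= 0).
#' @param params A [two_substrate_params()] object.
#' @param V_mV Membrane potential (mV).
#' @return Current in nA (inward negative). Vectorized over `G_uM`, `B_mM`
#'   and `V_mV` with the usual recycling rules.
#' @export
#' @examples
#' p <- two_substrate_params(voltage_scale = voltage_scale_unity())
#' steady_state_two_substrate(p$K_G_uM, 0, p, -60)  # I_G / 2
steady_state_two_substrate <- function(G_uM, B_mM, params, V_mV = -60) {
  stopifnot(inherits(params, "two_substrate_params"))
  if (any(G_uM < 0) || any(B_mM < 0)) {
    stop("substrate concentrations must be non-negative", call. = FALSE)
  }
  g <- G_uM / params$K_G_uM
  b <- B_mM / params$K_B_mM
  supp <- if (is.infinite(params$K_inh_mM)) {
    1
  } else {
    (1 + g) / (1 + g + B_mM / params$K_inh_mM)
  }
  fac <- evaluate_voltage_scale(params$voltage_scale, V_mV)
  fac * (params$I_G_nA * g * supp + params$I_B_nA * b) / (1 + g + b)
}

.local_rnorm <- function(n, sd, seed) {
  if (sd == 0) return(numeric(n))
  withr::with_seed(seed, stats::rnorm(n, mean = 0, sd = sd))
}

#' Simulate one voltage-step sweep
#'
#' Generates a current trace for a single test potential as the sum of a
#' capacitive transient, ohmic leak, the pre-steady-state (PSS) relaxation of
#' the two-state charge movement, a steady transport current during the step,
#' and optional white Gaussian noise. The PSS component at the test potential
#' `V` is `dQ(V)/tau(V) * exp(-(t - t_on)/tau(V))` with
#' `dQ(V) = Q_in(V) - Q_in(V_holding)` (see [charge_movement_theory()]); the
#' return to holding produces the mirror-image OFF relaxation with
#' `tau(V_holding)`.
#'
#' @param protocol A [voltage_step_protocol()].
#' @param test_V_mV One of the protocol's test potentials.
#' @param cm_params [charge_movement_params()] of the charge movement; `NULL`
#'   suppresses the PSS component (blocker-like condition).
#' @param cell [cell_params()] for capacitance and leak.
#' @param steady_current_nA Steady transport current during the step (nA).
#' @param noise A [noise_spec()]; a seed is required when its sd is > 0.
#' @param components If `TRUE`, attach an attribute `"components"` holding
#'   the separate leak/capacitive/pss/steady traces (useful for validation).
#' @return A [sweep_trace()].
#' @export
simulate_sweep <- function(protocol, test_V_mV, cm_params = NULL,
                           cell = cell_params(), steady_current_nA = 0,
                           noise = noise_spec(), components = FALSE) {
  stopifnot(inherits(protocol, "voltage_step_protocol"),
            inherits(cell, "cell_params"), inherits(noise, "noise_spec"))
  .require_seed(noise)
  if (!any(abs(protocol$test_potentials_mV - test_V_mV) < 1e-9)) {
    stop("test_V_mV = ", test_V_mV,
         " is not one of the protocol's test potentials", call. = FALSE)
  }
  t <- .protocol_sweep_times(protocol)
  t_on <- protocol$step_start_s
  t_off <- protocol$step_start_s + protocol$step_duration_s
  in_step <- t >= t_on & t < t_off
  post <- t >= t_off
  vh <- protocol$holding_mV
  v_of_t <- ifelse(in_step, test_V_mV, vh)
  dV <- test_V_mV - vh

  leak <- cell$g_leak_nA_per_mV * (v_of_t - cell$E_leak_mV)

  capac <- numeric(length(t))
  q_c <- cell$Cm_nF * dV / 1000  # nF * mV -> nC
  capac[in_step] <- (q_c / cell$tau_c_s) *
    exp(-(t[in_step] - t_on) / cell$tau_c_s)
  capac[post] <- (-q_c / cell$tau_c_s) *
    exp(-(t[post] - t_off) / cell$tau_c_s)

  pss <- numeric(length(t))
  if (!is.null(cm_params)) {
    th <- charge_movement_theory(cm_params)
    dq_on <- th$delta_Q_nC(test_V_mV, vh)
    tau_on <- th$tau_s(test_V_mV)
    tau_off <- th$tau_s(vh)
    pss[in_step] <- (dq_on / tau_on) * exp(-(t[in_step] - t_on) / tau_on)
    pss[post] <- (-dq_on / tau_off) * exp(-(t[post] - t_off) / tau_off)
  }

  steady <- ifelse(in_step, steady_current_nA, 0)
  eps <- .local_rnorm(length(t), noise$sd_current_nA, noise$seed)

  sw <- sweep_trace(test_V_mV, t, leak + capac + pss + steady + eps)
  if (components) {
    attr(sw, "components") <- list(leak = leak, capacitive = capac,
                                   pss = pss, steady = steady, noise = eps)
  }
  sw
}

.default_rate_scale <- c(gaba = 3.5, betaine = 0.35)

.condition_fields <- function(cond) {
  list(label = cond$label %||% stop("condition needs a label", call. = FALSE),
       gaba_uM = cond$gaba_uM %||% 0,
       betaine_mM = cond$betaine_mM %||% 0,
       blocker = isTRUE(cond$blocker),
       zero_transport = isTRUE(cond$zero_transport))
}

#' Simulate a family of recording sets across solution conditions
#'
#' Generates one [recording_set()] per solution condition over all protocol
#' potentials. A blocker condition (or a sodium-free `zero_transport`
#' condition) contains only the capacitive transient and leak; substrate
#' conditions add the PSS relaxation and the steady two-substrate transport
#' current. Substrates modulate the charge movement through the fractional
#' occupancy `occ = G/K_G + B/K_B`: the displaceable charge is scaled by
#' `1/(1 + occ)` and the rate scale `k0` by `(1 + c_G*G/K_G + c_B*B/K_B)`,
#' so that a saturating concentration of the high-affinity substrate makes
#' the transient both small and too fast to resolve within the analysis
#' window, while millimolar B only moderately shortens it.
#'
#' Per-sweep noise seeds are derived deterministically from the base seed as
#' `seed + 1000*i_condition + i_sweep`, so identical calls are bit-identical.
#'
#' @param protocol A [voltage_step_protocol()].
#' @param cm_params Baseline [charge_movement_params()] (substrate-free).
#' @param cell [cell_params()].
#' @param transport [two_substrate_params()] for the steady currents.
#' @param conditions List of condition descriptors, each a list with `label`
#'   and optional `gaba_uM`, `betaine_mM`, `blocker`, `zero_transport`.
#'   Must contain at least one blocker-type and one test condition; labels
#'   must be unique.
#' @param noise A [noise_spec()].
#' @param rate_scale Named numeric `c(gaba=, betaine=)` (or a single number
#'   applied to both) scaling the substrate acceleration of `k0`.
#' @return Named list of [recording_set()] objects (one per condition), with
#'   the scaled ground-truth parameters of each condition attached as the
#'   attribute `"truth"`.
#' @export
simulate_condition_set <- function(protocol, cm_params, cell, transport,
                                   conditions, noise = noise_spec(),
                                   rate_scale = c(gaba = 3.5, betaine = 0.35)) {
  stopifnot(inherits(protocol, "voltage_step_protocol"),
            inherits(cm_params, "charge_movement_params"),
            inherits(cell, "cell_params"),
            inherits(transport, "two_substrate_params"),
            is.list(conditions), length(conditions) >= 2)
  .require_seed(noise)
  if (length(rate_scale) == 1 && is.null(names(rate_scale))) {
    rate_scale <- c(gaba = unname(rate_scale), betaine = unname(rate_scale))
  }
  stopifnot(all(c("gaba", "betaine") %in% names(rate_scale)))
  conds <- lapply(conditions, .condition_fields)
  labels <- vapply(conds, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  is_blk <- vapply(conds, function(cc) cc$blocker || cc$zero_transport,
                   logical(1))
  if (!any(is_blk) || all(is_blk)) {
    stop("conditions must include at least one blocker and one test condition",
         call. = FALSE)
  }

  out <- vector("list", length(conds))
  names(out) <- labels
  for (i in seq_along(conds)) {
    cc <- conds[[i]]
    if (cc$blocker || cc$zero_transport) {
      cm_i <- NULL
      steady <- function(V) 0
      truth <- list(condition = cc, cm_params = NULL)
    } else {
      occ <- cc$gaba_uM / transport$K_G_uM + cc$betaine_mM / transport$K_B_mM
      acc <- 1 + rate_scale[["gaba"]] * cc$gaba_uM / transport$K_G_uM +
        rate_scale[["betaine"]] * cc$betaine_mM / transport$K_B_mM
      cm_i <- charge_movement_params(
        Qmax_nC = cm_params$Qmax_nC / (1 + occ),
        V_half_mV = cm_params$V_half_mV,
        z_eff = cm_params$z_eff,
        k0_per_s = cm_params$k0_per_s * acc,
        temperature_K = cm_params$temperature_K
      )
      steady <- function(V) {
        steady_state_two_substrate(cc$gaba_uM, cc$betaine_mM, transport, V)
      }
      truth <- list(condition = cc, cm_params = cm_i)
    }
    sweeps <- vector("list", length(protocol$test_potentials_mV))
    for (j in seq_along(protocol$test_potentials_mV)) {
      v <- protocol$test_potentials_mV[j]
      noise_ij <- if (noise$sd_current_nA > 0) {
        noise_spec(noise$sd_current_nA, noise$seed + 1000L * i + j)
      } else {
        noise
      }
      sweeps[[j]] <- simulate_sweep(protocol, v, cm_i, cell,
                                    steady_current_nA = steady(v),
                                    noise = noise_ij)
    }
    rs <- recording_set(cc$label,
                        solution = cc[c("gaba_uM", "betaine_mM", "blocker",
                                        "zero_transport")],
                        sweeps = sweeps, protocol = protocol)
    attr(rs, "truth") <- truth
    out[[i]] <- rs
  }
  out
}

#' Simulate a dose-response table
#'
#' Replicate currents at each concentration follow the Hill/logistic model
#' `I(S) = Imax * S^p / (S^p + K^p)` plus additive Gaussian noise; the table
#' reports the per-concentration mean, SEM and replicate count.
#'
#' @param Imax_nA Maximal current (nA; inward negative).
#' @param K_half Half-maximal concentration (> 0, in `unit`).
#' @param p Hill exponent (> 0).
#' @param concs Concentrations (> 0, in `unit`), strictly increasing.
#' @param n_replicates Replicates (cells) per concentration.
#' @param noise A [noise_spec()].
#' @param unit Concentration unit label recorded in the table.
#' @param n_batches Number of oocyte batches recorded in the table.
#' @return A [dose_response_table()] with the generating parameters attached
#'   as attribute `"truth"`.
#' @export
simulate_dose_response <- function(Imax_nA, K_half, p = 1, concs,
                                   n_replicates = 8, noise = noise_spec(),
                                   unit = "mM", n_batches = 3) {
  stopifnot(K_half > 0, all(concs > 0), n_replicates >= 1)
  if (p <= 0) stop("Hill exponent p must be > 0", call. = FALSE)
  .require_seed(noise)
  concs <- sort(concs)
  mu <- Imax_nA * concs^p / (concs^p + K_half^p)
  draws <- .local_rnorm(length(concs) * n_replicates, noise$sd_current_nA,
                        noise$seed %||% 0L)
  m <- matrix(draws, nrow = length(concs))
  reps <- mu + m
  mean_i <- rowMeans(reps)
  sem_i <- if (n_replicates > 1) {
    apply(reps, 1, stats::sd) / sqrt(n_replicates)
  } else {
    rep(NA_real_, length(concs))
  }
  tab <- dose_response_table(concs, mean_i, sem_i,
                             n_cells = rep(n_replicates, length(concs)),
                             n_batches = rep(n_batches, length(concs)),
                             unit = unit)
  attr(tab, "truth") <- list(Imax_nA = Imax_nA, K_half = K_half, p = p)
  tab
}

#' Simulate long-format competition measurements
#'
#' Draws `n_cells` replicate steady currents for every combination of the
#' given GABA and betaine levels (which should include the zero level on each
#' axis so the buffer-only reference cell exists) from
#' [steady_state_two_substrate()] plus additive noise.
#'
#' @param transport [two_substrate_params()].
#' @param gaba_uM_levels GABA levels (uM), usually including 0.
#' @param betaine_mM_levels Betaine levels (mM), usually including 0.
#' @param n_cells Replicates per condition.
#' @param noise [noise_spec()].
#' @param V_mV Holding potential of the measurement (mV).
#' @return Long-format `data.frame` with columns `gaba_uM`, `betaine_mM`,
#'   `current_nA`, `cell_id`, `batch_id`.
#' @export
simulate_competition_records <- function(transport, gaba_uM_levels,
                                         betaine_mM_levels, n_cells = 6,
                                         noise = noise_spec(), V_mV = -60) {
  stopifnot(inherits(transport, "two_substrate_params"), n_cells >= 1)
  .require_seed(noise)
  grid <- expand.grid(gaba_uM = sort(gaba_uM_levels),
                      betaine_mM = sort(betaine_mM_levels))
  mu <- steady_state_two_substrate(grid$gaba_uM, grid$betaine_mM, transport,
                                   V_mV)
  long <- grid[rep(seq_len(nrow(grid)), each = n_cells), ]
  long$current_nA <- rep(mu, each = n_cells) +
    .local_rnorm(nrow(long), noise$sd_current_nA, noise$seed %||% 0L)
  long$cell_id <- sprintf("cell%02d", rep(seq_len(n_cells), nrow(grid)))
  long$batch_id <- sprintf("batch%d",
                           1 + (rep(seq_len(n_cells), nrow(grid)) - 1) %/%
                             max(1, ceiling(n_cells / 2)))
  rownames(long) <- NULL
  long
}

#' Simulate a superfusion efflux time course
#'
#' `n_basal` drug-free fractions are followed by `n_drug` fractions in the
#' presence of the drug. Each fraction releases a percentage of the tracer
#' content remaining at its start: `2 * basal_rate` percent per (2-min)
#' fraction in the basal phase, ramping linearly over `rise_fractions` drug
#' fractions to the plateau
#' `2 * (basal_rate + mon * k_max * dose/(dose + K_half))` percent, where
#' `mon` is `monensin_factor` when monensin is present and 1 otherwise.
#' Optional multiplicative noise (`cv`) perturbs each fraction's released
#' counts.
#'
#' @param params [efflux_sim_params()].
#' @param dose Drug concentration (>= 0, units of `params$K_half`).
#' @param n_basal Number of basal fractions (>= 1).
#' @param n_drug Number of drug fractions (>= 1).
#' @param monensin Logical; monensin present?
#' @param cv Coefficient of variation of per-fraction released counts (>= 0).
#' @param seed Integer seed; required when `cv > 0`.
#' @param fraction_minutes Fraction length in minutes.
#' @return An [efflux_time_course()] with attribute `"truth"`.
#' @export
simulate_efflux <- function(params, dose, n_basal = 4, n_drug = 5,
                            monensin = FALSE, cv = 0, seed = NULL,
                            fraction_minutes = 2) {
  stopifnot(inherits(params, "efflux_sim_params"),
            n_basal >= 1, n_drug >= 1, cv >= 0, fraction_minutes > 0)
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  if (cv > 0 && is.null(seed)) {
    stop("noisy efflux simulation requires a seed", call. = FALSE)
  }
  mon <- if (monensin) params$monensin_factor else 1
  induced <- mon * params$k_max_pct_per_min * dose / (dose + params$K_half)
  rate_basal <- params$basal_rate_pct_per_min * fraction_minutes
  rate_plateau <- (params$basal_rate_pct_per_min + induced) * fraction_minutes
  ramp <- pmin(seq_len(n_drug) / params$rise_fractions, 1)
  rates <- c(rep(rate_basal, n_basal),
             rate_basal + ramp * (rate_plateau - rate_basal))
  mult <- if (cv > 0) {
    pmax(0, 1 + withr::with_seed(seed, stats::rnorm(length(rates), 0, cv)))
  } else {
    rep(1, length(rates))
  }
  remaining <- params$total_load_counts
  released <- numeric(length(rates))
  for (i in seq_along(rates)) {
    rel <- remaining * rates[i] / 100 * mult[i]
    rel <- min(rel, remaining)
    released[i] <- rel
    remaining <- remaining - rel
  }
  tc <- efflux_time_course(
    released_counts = released,
    remaining_counts = remaining,
    fraction_minutes = fraction_minutes,
    condition = list(drug = "drug", dose = dose, monensin = monensin),
    n_basal = n_basal
  )
  attr(tc, "truth") <- list(params = params, dose = dose, monensin = monensin,
                            rates_pct_per_fraction = rates)
  tc
}
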