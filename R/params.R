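#' Two-state charge-movement parameters
#'
#' Ground-truth parameters of the simulated pre-steady-state (PSS) charge
#' movement. The generator is a two-state Eyring scheme with a symmetric
#' barrier: charge occupies an outer or inner position within the membrane
#' electric field, and the voltage dependence enters each unidirectional rate
#' through half of the total energy drop. Its steady state is exactly the
#' Boltzmann sigmoid and its relaxation is mono-exponential, matching the
#' single-exponential fits used throughout the analysis pipeline.
#'
#' @param Qmax_nC Total displaceable charge (nC, magnitude; != 0).
#' @param V_half_mV Midpoint potential of the charge distribution (mV).
#' @param z_eff Effective valence of the moving charge (> 0).
#' @param k0_per_s Rate scale at `V = V_half_mV` (s^-1, > 0): both
#'   unidirectional rates equal `k0` there, so the relaxation time constant at
#'   the midpoint is `1/(2 k0)`.
#' @param temperature_K Absolute temperature (K).
#' @return An object of class `charge_movement_params`.
#' @seealso [charge_movement_theory()], [simulate_sweep()]
#' @export
charge_movement_params <- function(Qmax_nC = 12,
                                   V_half_mV = -32.87,
                                   z_eff = 1,
                                   k0_per_s = 10,
                                   temperature_K = 291.15) {
  stopifnot(is.numeric(Qmax_nC), length(Qmax_nC) == 1, Qmax_nC != 0,
            is.numeric(V_half_mV), length(V_half_mV) == 1, is.finite(V_half_mV),
            is.numeric(z_eff), length(z_eff) == 1, z_eff > 0,
            is.numeric(k0_per_s), length(k0_per_s) == 1, k0_per_s > 0,
            is.numeric(temperature_K), length(temperature_K) == 1,
            temperature_K > 0)
  sigma <- slope_factor_mV(z_eff, temperature_K)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("derived slope factor must be finite and positive", call. = FALSE)
  }
  structure(
    list(Qmax_nC = Qmax_nC, V_half_mV = V_half_mV, z_eff = z_eff,
         k0_per_s = k0_per_s, temperature_K = temperature_K,
         sigma_mV = sigma),
    class = "charge_movement_params"
  )
}

#' Closed-form theory of the two-state charge movement
#'
#' Returns the analytic functions implied by a [charge_movement_params()]
#' object. With `u = (V - V_half)/sigma` (equivalently
#' `z_eff F (V - V_half) / RT`):
#' * `fraction_in(V)  = 1 / (1 + exp(u))` - steady-state fraction of charge
#'   in the inner position (approaches 1 on hyperpolarization);
#' * `alpha_per_s(V) = k0 exp(+u/2)` - outward rate;
#' * `beta_per_s(V)  = k0 exp(-u/2)` - inward rate;
#' * `tau_s(V) = 1 / (alpha + beta)` - relaxation time constant;
#' * `Q_in(V) = Qmax * fraction_in(V)`; and
#' * `delta_Q_nC(V, holding_mV)` = `Q_in(V) - Q_in(holding)`, the charge moved
#'   by a step from the holding potential.
#'
#' These closed forms are the ground truth that the analysis pipeline must
#' recover from simulated sweeps.
#'
#' @param params A [charge_movement_params()] object.
#' @return A list of vectorized functions:
#'   `fraction_in`, `alpha_per_s`, `beta_per_s`, `tau_s`, `Q_in_nC`,
#'   `delta_Q_nC`.
#' @export
charge_movement_theory <- function(params) {
  stopifnot(inherits(params, "charge_movement_params"))
  sigma <- params$sigma_mV
  vh <- params$V_half_mV
  k0 <- params$k0_per_s
  qmax <- params$Qmax_nC
  u <- function(V) (V - vh) / sigma
  fraction_in <- function(V) 1 / (1 + exp(u(V)))
  alpha <- function(V) k0 * exp(u(V) / 2)
  beta <- function(V) k0 * exp(-u(V) / 2)
  tau <- function(V) 1 / (alpha(V) + beta(V))
  qin <- function(V) qmax * fraction_in(V)
  list(
    fraction_in = fraction_in,
    alpha_per_s = alpha,
    beta_per_s = beta,
    tau_s = tau,
    Q_in_nC = qin,
    delta_Q_nC = function(V, holding_mV) qin(V) - qin(holding_mV)
  )
}

#' Passive cell parameters for sweep simulation
#'
#' Linear membrane properties added to simulated sweeps: a single-exponential
#' capacitive transient at each voltage transition and an ohmic leak. Defaults
#' are typical for a stage-V/VI Xenopus oocyte under two-electrode voltage
#' clamp; they are generator plumbing, not estimates of any particular cell.
#'
#' @param Cm_nF Membrane capacitance (nF, >= 0).
#' @param tau_c_s Capacitive time constant (s, > 0). Default 1 ms, so the
#'   transient has decayed below 1 percent of its peak 5 ms after the step.
#' @param g_leak_nA_per_mV Leak conductance (nA/mV, >= 0).
#' @param E_leak_mV Leak reversal potential (mV).
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(Cm_nF = 220, tau_c_s = 0.001,
                        g_leak_nA_per_mV = 2, E_leak_mV = -20) {
  stopifnot(is.numeric(Cm_nF), Cm_nF >= 0,
            is.numeric(tau_c_s), tau_c_s > 0,
            is.numeric(g_leak_nA_per_mV), g_leak_nA_per_mV >= 0,
            is.numeric(E_leak_mV), is.finite(E_leak_mV))
  structure(list(Cm_nF = Cm_nF, tau_c_s = tau_c_s,
                 g_leak_nA_per_mV = g_leak_nA_per_mV, E_leak_mV = E_leak_mV),
            class = "cell_params")
}

#' Voltage-scale descriptors for the steady transport current
#'
#' The steady transport current of the simulator is the two-substrate current
#' at the reference driving force multiplied by a monotone factor of the
#' membrane potential, bounded in \[0, 1\]. `voltage_scale_logistic()` is a
#' logistic factor `1 / (1 + exp((V - v_mid)/v_slope))`, largest at
#' hyperpolarized potentials as expected for an inward sodium-coupled
#' transport current. `voltage_scale_unity()` disables the voltage dependence
#' (factor identically 1).
#'
#' @param v_mid_mV Midpoint of the logistic factor (mV).
#' @param v_slope_mV Slope of the logistic factor (mV, > 0).
#' @return A voltage-scale descriptor (class `voltage_scale`).
#' @export
voltage_scale_logistic <- function(v_mid_mV = -10, v_slope_mV = 25) {
  stopifnot(is.finite(v_mid_mV), v_slope_mV > 0)
  structure(list(type = "logistic", v_mid_mV = v_mid_mV,
                 v_slope_mV = v_slope_mV),
            class = "voltage_scale")
}

#' @rdname voltage_scale_logistic
#' @export
voltage_scale_unity <- function() {
  structure(list(type = "unity"), class = "voltage_scale")
}

#' @rdname voltage_scale_logistic
#' @param vs A voltage-scale descriptor.
#' @param V_mV Membrane potential(s) in mV.
#' @export
evaluate_voltage_scale <- function(vs, V_mV) {
  stopifnot(inherits(vs, "voltage_scale"))
  switch(vs$type,
    unity = rep(1, length(V_mV)),
    logistic = 1 / (1 + exp((V_mV - vs$v_mid_mV) / vs$v_slope_mV)),
    stop("unknown voltage_scale type: ", vs$type, call. = FALSE)
  )
}

#' Two-substrate transport parameters
#'
#' Parameters of the generative steady-state current model for two substrates
#' G (micromolar axis, e.g. GABA) and B (millimolar axis, e.g. betaine)
#' sharing one transporter:
#'
#' `I = factor(V) * (I_G * g * S + I_B * b) / (1 + g + b)`
#'
#' with `g = G/K_G`, `b = B/K_B`, and a modulatory suppression factor
#' `S = (1 + g) / (1 + g + B/K_inh)` on the G-borne current. With the default
#' `K_inh = Inf` the suppression is absent (`S = 1`) and the expression is the
#' plain single-site competitive scheme, in which the current is monotone in
#' B at fixed G. A finite `K_inh` adds a high-potency modulatory action of B
#' (slowing of the transport cycle) that is itself outcompeted by G; this is
#' what produces biphasic ("dual-effect") rows - inhibition of the G current
#' at low B followed by added transport at high B - that vanish when G is
#' saturating.
#'
#' @param I_G_nA Maximal current carried by substrate G (nA; inward negative).
#' @param K_G_uM Half-maximal concentration of G (uM, > 0).
#' @param I_B_nA Maximal current carried by substrate B (nA).
#' @param K_B_mM Half-maximal concentration of B (mM, > 0).
#' @param K_inh_mM Modulatory (cycle-slowing) constant of B (mM, > 0); `Inf`
#'   disables the modulatory site.
#' @param voltage_scale A descriptor from [voltage_scale_logistic()] or
#'   [voltage_scale_unity()].
#' @return An object of class `two_substrate_params`.
#' @seealso [steady_state_two_substrate()]
#' @export
two_substrate_params <- function(I_G_nA = -120, K_G_uM = 16,
                                 I_B_nA = -76.15, K_B_mM = 11.57,
                                 K_inh_mM = Inf,
                                 voltage_scale = voltage_scale_logistic()) {
  stopifnot(is.numeric(K_G_uM), K_G_uM > 0,
            is.numeric(K_B_mM), K_B_mM > 0,
            is.numeric(K_inh_mM), K_inh_mM > 0,
            is.numeric(I_G_nA), is.finite(I_G_nA),
            is.numeric(I_B_nA), is.finite(I_B_nA),
            inherits(voltage_scale, "voltage_scale"))
  structure(list(I_G_nA = I_G_nA, K_G_uM = K_G_uM, I_B_nA = I_B_nA,
                 K_B_mM = K_B_mM, K_inh_mM = K_inh_mM,
                 voltage_scale = voltage_scale),
            class = "two_substrate_params")
}

#' Additive recording-noise specification
#'
#' White Gaussian noise added to simulated traces after all deterministic
#' components; the acquisition low-pass filter is not simulated because the
#' generated components are band-limited by construction. A seed is mandatory
#' whenever `sd_current_nA > 0` so that every simulated dataset is exactly
#' reproducible.
#'
#' @param sd_current_nA Noise standard deviation (nA, >= 0).
#' @param seed Integer random seed; required when `sd_current_nA > 0`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd_current_nA = 0, seed = NULL) {
  stopifnot(is.numeric(sd_current_nA), length(sd_current_nA) == 1,
            sd_current_nA >= 0)
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    seed <- as.integer(seed)
  }
  structure(list(sd_current_nA = sd_current_nA, seed = seed),
            class = "noise_spec")
}

.require_seed <- function(noise) {
  if (noise$sd_current_nA > 0 && is.null(noise$seed)) {
    stop("noise_spec with sd_current_nA > 0 requires a seed ",
         "(reproducibility contract)", call. = FALSE)
  }
  invisible(noise)
}

#' Efflux-simulation parameters
#'
#' Ground truth for simulated superfusion release assays. Fractional release
#' is applied to the tracer content remaining at the start of each fraction
#' (superfusion physics), so the percent-of-total series declines slightly as
#' the cells deplete.
#'
#' @param basal_rate_pct_per_min Basal fractional release (% min^-1, >= 0).
#' @param k_max_pct_per_min Maximal drug-induced fractional release above
#'   basal (% min^-1, >= 0).
#' @param K_half Half-maximal drug concentration, in the units of the dose
#'   axis (> 0).
#' @param rise_fractions Number of drug fractions over which the induced rate
#'   ramps linearly to its plateau (integer >= 1).
#' @param monensin_factor Multiplicative scaling of the induced component when
#'   the sodium ionophore monensin is present (>= 0).
#' @param total_load_counts Initial tracer content (arbitrary counts, > 0).
#' @return An object of class `efflux_sim_params`.
#' @export
efflux_sim_params <- function(basal_rate_pct_per_min = 0.12,
                              k_max_pct_per_min = 1.0,
                              K_half = 6.73,
                              rise_fractions = 2,
                              monensin_factor = 1.5,
                              total_load_counts = 1e5) {
  stopifnot(basal_rate_pct_per_min >= 0, k_max_pct_per_min >= 0,
            K_half > 0, rise_fractions >= 1,
            rise_fractions == round(rise_fractions),
            monensin_factor >= 0, total_load_counts > 0)
  structure(list(basal_rate_pct_per_min = basal_rate_pct_per_min,
                 k_max_pct_per_min = k_max_pct_per_min,
                 K_half = K_half,
                 rise_fractions = as.integer(rise_fractions),
                 monensin_factor = monensin_factor,
                 total_load_counts = total_load_counts),
            class = "efflux_sim_params")
}

#' Study-condition generator defaults
#'
#' Bundles the published central estimates used as simulator ground truths:
#' the Q-V midpoints of the sodium buffer alone (-32.87 mV), of low betaine
#' (0.1 mM, -27.16 mV) and of low GABA (10 uM, -43.19 mV); the betaine
#' dose-response design (Imax -76.15 nA, K0.5 11.57 mM, concentrations
#' 0.1-50 mM at -60 mV holding); and the efflux concentration-response
#' designs (betaine K0.5 6.73 mM over 1-100 mM; GABA K0.5 36.28 uM over
#' 1-300 uM; basal efflux 0.12 % min^-1 in 2-min fractions).
#'
#' @return A nested list of parameter objects and design vectors.
#' @export
study_defaults <- function() {
  list(
    protocol = voltage_step_protocol(),
    cell = cell_params(),
    charge_movement = list(
      nd98 = charge_movement_params(V_half_mV = -32.87),
      betaine_0.1mM = charge_movement_params(V_half_mV = -27.16),
      gaba_10uM = charge_movement_params(V_half_mV = -43.19)
    ),
    transport = two_substrate_params(),
    dose = list(Imax_nA = -76.15, K_half_mM = 11.57, p = 1,
                concs_mM = c(0.1, 0.3, 1, 3, 10, 30, 50)),
    competition = list(
      gaba_uM = c(0, 1, 3, 10, 30, 100, 300),
      betaine_mM = c(0, 0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 50)
    ),
    efflux = list(
      betaine = list(params = efflux_sim_params(K_half = 6.73),
                     doses_mM = c(1, 3, 10, 30, 100)),
      gaba = list(params = efflux_sim_params(K_half = 36.28),
                  doses_uM = c(1, 3, 10, 30, 100, 300))
    )
  )
}
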