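test_that("two-substrate steady-state current matches its analytic values", {
  p_unity <- two_substrate_params(voltage_scale = voltage_scale_unity())
  # no substrate -> no transport current
  expect_identical(steady_state_two_substrate(0, 0, p_unity, -60), 0)
  # half-saturation of G alone
  expect_equal(steady_state_two_substrate(p_unity$K_G_uM, 0, p_unity, -60),
               p_unity$I_G_nA / 2)
  # a non-transported B at its K competitively dilutes G's current to I_G/3
  p_ib0 <- two_substrate_params(I_B_nA = 0,
                                voltage_scale = voltage_scale_unity())
  expect_equal(steady_state_two_substrate(p_ib0$K_G_uM, p_ib0$K_B_mM,
                                          p_ib0, -60),
               p_ib0$I_G_nA / 3)
  # vectorized evaluation agrees with the independently-coded model
  g <- c(0, 1, 10, 100, 300)
  b <- c(0, 0.1, 1, 10, 50)
  p_k <- two_substrate_params(I_B_nA = -12, K_inh_mM = 0.4,
                              voltage_scale = voltage_scale_unity())
  expect_equal(steady_state_two_substrate(g, b, p_k, -60),
               model_two_substrate(g, b, p_k))
  expect_error(steady_state_two_substrate(-1, 0, p_unity, -60),
               "non-negative")
})

test_that("voltage-scale factors stay within [0, 1] over the protocol range", {
  v <- seq(-140, 40, by = 1)
  f <- evaluate_voltage_scale(voltage_scale_logistic(), v)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) < 0))  # monotone, favouring inward transport
  expect_identical(evaluate_voltage_scale(voltage_scale_unity(), v),
                   rep(1, length(v)))
})

test_that("charge-movement theory has the cosh minimum at the midpoint", {
  cm <- h_cm(Qmax_nC = 10, V_half_mV = -40)
  th <- charge_movement_theory(cm)
  expect_equal(th$fraction_in(cm$V_half_mV), 0.5)
  expect_equal(th$tau_s(cm$V_half_mV), 1 / (2 * cm$k0_per_s))
  # tau is maximal at V_half (alpha + beta = 2 k0 cosh(u/2) is minimal there)
  v <- seq(-140, 40, by = 5)
  expect_true(all(th$tau_s(v) <= th$tau_s(cm$V_half_mV) + 1e-15))
})

test_that("simulated step charge matches explicit Euler integration of the
           two-state master equation", {
  cm <- h_cm(Qmax_nC = 10, V_half_mV = -40)
  th <- charge_movement_theory(cm)
  # integrate long enough for the slowest relaxation (tau ~ 50 ms) to settle
  oracle <- euler_two_state(cm, V = -40, holding_mV = -60, t_end = 0.8)
  # closed-form steady state of the generator vs the integrated ODE
  expect_equal(th$delta_Q_nC(-40, -60), oracle$delta_Q, tolerance = 1e-4)
  expect_equal(10 * (0.5 - th$fraction_in(-60)), oracle$delta_Q,
               tolerance = 1e-4)
})

test_that("isolated PSS component integrates to the displaced charge", {
  cm <- h_cm()
  proto <- h_protocol()
  th <- charge_movement_theory(cm)
  cell0 <- cell_params(Cm_nF = 0, g_leak_nA_per_mV = 0)
  t_on <- proto$step_start_s
  t_off <- t_on + proto$step_duration_s
  for (v in proto$test_potentials_mV) {
    if (v == proto$holding_mV) next
    sw <- simulate_sweep(proto, v, cm, cell0, steady_current_nA = 0)
    idx <- sw$time_s >= t_on & sw$time_s < t_off
    q_num <- trapezoid(sw$time_s[idx], sw$current_nA[idx])
    expect_equal(q_num, th$delta_Q_nC(v, proto$holding_mV),
                 tolerance = 1e-3)
  }
})

test_that("sweep simulation is seed-deterministic and demands a seed", {
  proto <- h_protocol()
  cm <- h_cm()
  s1 <- simulate_sweep(proto, -100, cm, noise = noise_spec(2, 42))
  s2 <- simulate_sweep(proto, -100, cm, noise = noise_spec(2, 42))
  s3 <- simulate_sweep(proto, -100, cm, noise = noise_spec(2, 43))
  expect_identical(s1$current_nA, s2$current_nA)
  expect_false(identical(s1$current_nA, s3$current_nA))
  expect_error(simulate_sweep(proto, -100, cm, noise = noise_spec(2)),
               "seed")
  expect_error(simulate_sweep(proto, -55, cm), "test potentials")
})

test_that("condition sets contain the advertised components", {
  sets <- h_pss_pair()
  blk <- sets$blocker
  proto <- blk$protocol
  cell <- h_cell()
  # blocker sweeps equal capacitive + leak exactly (noise-free construction)
  for (v in c(-140, -60, 40)) {
    ref <- simulate_sweep(proto, v, cm_params = NULL, cell = cell)
    expect_equal(get_sweep(blk, v)$current_nA, ref$current_nA)
  }
  # every set covers all protocol potentials
  expect_setequal(names(sets$test$sweeps),
                  as.character(proto$test_potentials_mV))
  expect_error(
    simulate_condition_set(proto, h_cm(), cell, two_substrate_params(),
                           list(list(label = "a", blocker = TRUE),
                                list(label = "a"))),
    "duplicate")
  expect_error(
    simulate_condition_set(proto, h_cm(), cell, two_substrate_params(),
                           list(list(label = "a"), list(label = "b"))),
    "blocker")
})

test_that("saturating GABA makes the PSS transient undetectable in the
           analysis window", {
  cm <- h_cm()
  tr <- two_substrate_params()
  proto <- h_protocol()
  sat <- 20 * tr$K_G_uM
  sets <- simulate_condition_set(
    proto, cm, h_cell(), tr,
    list(list(label = "blocker", blocker = TRUE),
         list(label = "nd98"),
         list(label = "sat_gaba", gaba_uM = sat)))
  cm_nd <- attr(sets$nd98, "truth")$cm_params
  cm_sat <- attr(sets$sat_gaba, "truth")$cm_params
  th_nd <- charge_movement_theory(cm_nd)
  th_sat <- charge_movement_theory(cm_sat)
  w0 <- 0.005  # default analysis-window offset from the step onset
  for (v in c(-120, -100, 0, 20)) {
    amp_nd <- abs(th_nd$delta_Q_nC(v, -60) / th_nd$tau_s(v)) *
      exp(-w0 / th_nd$tau_s(v))
    amp_sat <- abs(th_sat$delta_Q_nC(v, -60) / th_sat$tau_s(v)) *
      exp(-w0 / th_sat$tau_s(v))
    expect_lt(amp_sat, 0.01 * amp_nd)
  }
  # the displaced charge itself also collapses (scaled by 1/(1 + G/K_G))
  expect_equal(cm_sat$Qmax_nC, cm_nd$Qmax_nC / 21)
})

test_that("condition sets are bit-identical under identical seeds", {
  a <- h_pss_pair(noise_sd = 2, seed = 7)
  b <- h_pss_pair(noise_sd = 2, seed = 7)
  expect_identical(a, b)
})

test_that("dose-response simulation reproduces the closed-form means", {
  concs <- c(1, 3, 10, 30, 50)
  tab <- simulate_dose_response(-76.15, 11.57, 1, concs, n_replicates = 4)
  expect_equal(tab$mean_current_nA, hill_current(concs, -76.15, 11.57))
  # half-saturation and asymptotes when evaluated directly
  tab2 <- simulate_dose_response(-76.15, 11.57, 1, c(11.57, 1e-6, 1e6),
                                 n_replicates = 1)
  expect_equal(tab2$mean_current_nA[tab2$concentration == 11.57], -76.15 / 2)
  expect_equal(tab2$mean_current_nA[tab2$concentration == 1e-6], 0,
               tolerance = 1e-4)
  expect_equal(tab2$mean_current_nA[tab2$concentration == 1e6], -76.15,
               tolerance = 1e-4)
  expect_error(simulate_dose_response(-76, 11, 0, concs), "p must be > 0")
})

test_that("efflux simulation conserves tracer and honours the basal rate", {
  prm <- efflux_sim_params()
  tc <- simulate_efflux(prm, dose = 0)
  pct <- fractional_release(tc)
  expect_equal(sum(pct) + attr(pct, "remaining_percent"), 100,
               tolerance = 1e-9)
  # basal 0.12 %/min -> each 2-min fraction releases ~0.24% of total
  expect_equal(unname(pct[1]), 0.24, tolerance = 1e-6)
  expect_true(all(abs(pct - 0.24) < 0.005))  # depletion drift is tiny
  expect_error(simulate_efflux(prm, dose = -1), "non-negative")
  expect_error(simulate_efflux(prm, dose = 1, cv = 0.05), "seed")
})

test_that("drug fractions plateau at the programmed induced rate", {
  prm <- efflux_sim_params(basal_rate_pct_per_min = 0.12,
                           k_max_pct_per_min = 1, K_half = 6.73,
                           rise_fractions = 2)
  tc <- simulate_efflux(prm, dose = 6.73)  # half-maximal induction
  truth <- attr(tc, "truth")$rates_pct_per_fraction
  expect_equal(truth[length(truth)], 2 * (0.12 + 0.5), tolerance = 1e-12)
  # monensin scales only the induced component
  tcm <- simulate_efflux(prm, dose = 6.73, monensin = TRUE)
  tm <- attr(tcm, "truth")$rates_pct_per_fraction
  expect_equal(tm[length(tm)], 2 * (0.12 + prm$monensin_factor * 0.5),
               tolerance = 1e-12)
})
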