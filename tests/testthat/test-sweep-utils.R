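test_that("adjacent averaging matches the brute-force windowed mean", {
  sw <- sweep_trace(-60, (0:4) / 1000, c(0, 0, 3, 0, 0))
  expect_equal(smooth_adjacent_average(sw, 3)$current_nA, c(0, 1, 1, 1, 0))
  # constant trace unchanged, any window
  cw <- sweep_trace(-60, (0:19) / 1000, rep(-5, 20))
  expect_equal(smooth_adjacent_average(cw, 10)$current_nA, rep(-5, 20))
  # window 1 is the identity
  rnd <- sweep_trace(-60, (0:19) / 1000, sin(1:20))
  expect_identical(smooth_adjacent_average(rnd, 1), rnd)
  # general case vs a direct loop (even window widened to odd)
  y <- cos(1:15)
  sw2 <- sweep_trace(-60, (0:14) / 1000, y)
  got <- smooth_adjacent_average(sw2, 4)$current_nA
  want <- vapply(seq_along(y), function(i) {
    mean(y[max(1, i - 2):min(length(y), i + 2)])
  }, numeric(1))
  expect_equal(got, want)
  expect_error(smooth_adjacent_average(sw, 99), "exceeds")
})

test_that("blocker subtraction recovers the transporter component exactly", {
  sets <- h_pss_pair()
  sub <- subtract_blocker(sets$test, sets$blocker)
  proto <- sub$protocol
  cm <- attr(sets$test, "truth")$cm_params
  cell0 <- cell_params(Cm_nF = 0, g_leak_nA_per_mV = 0)
  for (v in c(-140, -100, 0, 40)) {
    ref <- simulate_sweep(proto, v, cm, cell0, steady_current_nA = 0)
    expect_equal(get_sweep(sub, v)$current_nA, ref$current_nA,
                 tolerance = 1e-12)
  }
  # identical sets subtract to zero
  zero <- subtract_blocker(sets$blocker, sets$blocker)
  expect_true(all(vapply(zero$sweeps,
                         function(s) all(s$current_nA == 0), logical(1))))
  expect_match(zero$condition_label, "blocker - blocker", fixed = TRUE)
})

test_that("protocol mismatches are rejected with the offending field named", {
  sets <- h_pss_pair()
  other <- h_pss_pair(protocol = h_protocol(holding_mV = -80))
  expect_error(subtract_blocker(sets$test, other$blocker), "holding_mV")
  shifted <- h_pss_pair(
    protocol = h_protocol(test_potentials_mV = seq(-120, 60, by = 20)))
  expect_error(subtract_blocker(sets$test, shifted$blocker),
               "test_potentials_mV")
})

test_that("subtraction is invariant to a common additive component", {
  sets <- h_pss_pair()
  extra <- simulate_sweep(h_protocol(), -100, h_cm(Qmax_nC = 3),
                          cell_params(Cm_nF = 50))
  add_to <- function(rs, k) {
    rs$sweeps <- lapply(rs$sweeps, function(s) {
      s$current_nA <- s$current_nA + k * extra$current_nA
      s
    })
    rs
  }
  base <- run_pss_pipeline(sets$test, sets$blocker)
  shifted <- run_pss_pipeline(add_to(sets$test, 2.5),
                              add_to(sets$blocker, 2.5))
  expect_equal(shifted$qv$Q_nC, base$qv$Q_nC, tolerance = 1e-9)
  expect_equal(shifted$boltzmann$V_half_mV, base$boltzmann$V_half_mV,
               tolerance = 1e-6)
})

test_that("steady-current measurement subtracts the holding baseline", {
  proto <- h_protocol()
  t <- (0:999) / 1000
  const <- sweep_trace(-100, t, rep(-7, 1000) + ifelse(t >= 0.1 & t < 0.9,
                                                       -43, 0))
  # constant -50 during the step, baseline -7 -> steady = -43
  expect_equal(measure_steady_current(const, proto), -43)
  # simulated sweep with a known steady current: relaxation fully decayed
  sw <- simulate_sweep(proto, -100, h_cm(), h_cell(),
                       steady_current_nA = -50)
  blk <- simulate_sweep(proto, -100, NULL, h_cell())
  diff_sw <- sweep_trace(-100, sw$time_s, sw$current_nA - blk$current_nA)
  expect_equal(measure_steady_current(diff_sw, proto), -50, tolerance = 0.5)
  expect_error(measure_steady_current(const, proto, tail_s = 2), "tail_s")
})

test_that("standard error of a noisy steady-current window scales as 1/sqrt(n)", {
  proto <- h_protocol()
  reps <- vapply(1:200, function(r) {
    sw <- simulate_sweep(proto, -100, NULL,
                         cell_params(Cm_nF = 0, g_leak_nA_per_mV = 0),
                         steady_current_nA = -50,
                         noise = noise_spec(1, 1000 + r))
    measure_steady_current(sw, proto)
  }, numeric(1))
  # tail window holds 100 samples at 1 kHz, but the baseline mean (100
  # pre-step samples) adds an equal variance contribution: SE = sqrt(2)/10
  expect_equal(sd(reps), sqrt(2) / 10, tolerance = 0.15)
})

test_that("plateau current over [4, 6] s matches direct recomputation", {
  t <- seq(0, 10, by = 0.01)
  flat <- list(time_s = t, current_nA = rep(-30, length(t)))
  got <- measure_plateau_current(flat)
  expect_equal(got$mean_nA, -30)
  expect_equal(got$sd_nA, 0)
  # linear ramp a + b t averages to its value at the window midpoint (5 s)
  ramp <- list(time_s = t, current_nA = 2 - 3 * t)
  expect_equal(measure_plateau_current(ramp)$mean_nA, 2 - 3 * 5)
  # noisy plateau equals brute-force mean/sd over the same index range
  y <- -30 + withr::with_seed(11, rnorm(length(t)))
  noisy <- list(time_s = t, current_nA = y)
  idx <- t >= 4 & t <= 6
  got2 <- measure_plateau_current(noisy)
  expect_equal(got2$mean_nA, mean(y[idx]))
  expect_equal(got2$sd_nA, sd(y[idx]))
  short <- list(time_s = t[t < 5], current_nA = y[t < 5])
  expect_error(measure_plateau_current(short), "cover")
})
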