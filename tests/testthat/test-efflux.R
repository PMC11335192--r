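test_that("fractional release is percent-of-total with exact conservation", {
  tc <- efflux_time_course(released_counts = c(100, 50), remaining_counts = 850,
                           n_basal = 2)
  pct <- fractional_release(tc)
  expect_equal(unname(pct[1]), 10)
  expect_equal(sum(pct) + attr(pct, "remaining_percent"), 100,
               tolerance = 1e-12)
  zero <- efflux_time_course(c(0, 0), 1000, n_basal = 2)
  expect_equal(as.vector(fractional_release(zero)), c(0, 0))
  bad <- efflux_time_course(c(0, 0), 0, n_basal = 2)
  expect_error(fractional_release(bad), "positive")
})

test_that("simulated percent series equals the generator's programmed rates", {
  prm <- efflux_sim_params()
  tc <- simulate_efflux(prm, dose = 10)
  pct <- fractional_release(tc)
  rates <- attr(tc, "truth")$rates_pct_per_fraction
  # reconstruct the depleting series independently
  remaining <- 100
  want <- numeric(length(rates))
  for (i in seq_along(rates)) {
    want[i] <- remaining * rates[i] / 100
    remaining <- remaining - want[i]
  }
  expect_equal(as.vector(pct), want, tolerance = 1e-9)
  # monotone depletion: released counts never exceed what remains
  expect_true(all(diff(cumsum(tc$released_counts)) >= 0))
  expect_gte(tc$remaining_counts, 0)
})

test_that("basal rate of 0.24 percent per 2-min fraction reads 0.12 %/min", {
  tc <- efflux_time_course(rep(2.4, 6), 1000 - 6 * 2.4, n_basal = 4)
  # each fraction releases 0.24% of the 1000-count total
  br <- basal_rate(tc)
  expect_equal(br$rate_pct_per_min, 0.12, tolerance = 1e-12)
  expect_equal(br$se, 0)
  expect_error(basal_rate(tc, n_basal = 1), "at least 2")
})

test_that("noisy basal-rate recovery is unbiased over 50 seeds", {
  prm <- efflux_sim_params()
  est <- vapply(1:50, function(r) {
    tc <- simulate_efflux(prm, dose = 0, cv = 0.1, seed = 900 + r)
    basal_rate(tc)$rate_pct_per_min
  }, numeric(1))
  expect_equal(mean(est), 0.12, tolerance = 2 * sd(est) / sqrt(50) / 0.12)
})

test_that("plateau detection follows the first-stable-fraction rule", {
  # drug-phase percents 0.5 0.9 1.0 1.0 1.0 -> plateau at fraction 3,
  # uncorrected induced = 1.0 / 2 min = 0.5 %/min
  total <- 1000
  basal <- rep(0.1 / 100 * total, 2)
  drug <- c(0.5, 0.9, 1.0, 1.0, 1.0) / 100 * total
  tc <- efflux_time_course(c(basal, drug),
                           total - sum(basal) - sum(drug), n_basal = 2)
  ind <- induced_efflux(tc)
  expect_equal(ind$plateau_fraction, 3)
  expect_equal(ind$uncorrected_pct_per_min, 0.5, tolerance = 0.01)
  expect_false(ind$no_plateau)

  # flat drug phase equal to basal -> corrected ~ 0
  flat <- efflux_time_course(rep(2, 7), 1000 - 14, n_basal = 4)
  ind_flat <- induced_efflux(flat)
  expect_equal(ind_flat$corrected_pct_per_min, 0, tolerance = 1e-9)

  # monotone rise with no plateau -> final fraction, flagged
  rise <- efflux_time_course(c(rep(2, 4), 3, 4, 5, 6, 7), 900, n_basal = 4)
  ind_rise <- induced_efflux(rise)
  expect_true(ind_rise$no_plateau)
  expect_equal(ind_rise$plateau_fraction, 5)
})

test_that("noise-free efflux concentration-response recovers K_half
           exactly", {
  doses <- c(1, 3, 10, 30, 100)
  induced <- hill_current(doses, 1.0, 6.73)
  fit <- fit_efflux_kinetics(doses, induced, fix_p = 1, unit = "mM")
  expect_true(fit$converged)
  expect_equal(fit$K_half, 6.73, tolerance = 1e-6)
  expect_equal(fit$max_induced, 1.0, tolerance = 1e-6)
  # induced at d = K_half is max/2
  expect_equal(hill_current(fit$K_half, fit$max_induced, fit$K_half, fit$p),
               fit$max_induced / 2)
})

test_that("an all-zero induced series (transport blocked) does not
           converge", {
  fit <- fit_efflux_kinetics(c(1, 3, 10, 30, 100), rep(0, 5))
  expect_false(fit$converged)
  expect_error(fit_efflux_kinetics(c(1, 3, 10), 1:3), ">= 4")
  expect_error(fit_efflux_kinetics(c(-1, 3, 10, 30), 1:4), "positive")
})

test_that("end-to-end efflux analysis recovers the simulated K_half", {
  prm <- efflux_sim_params()
  doses <- c(1, 3, 10, 30, 100)
  induced <- vapply(doses, function(d) {
    vals <- vapply(1:6, function(w) {
      tc <- simulate_efflux(prm, d, cv = 0.05, seed = 40000 + 100 * w + d)
      induced_efflux(tc)$corrected_pct_per_min
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  fit <- fit_efflux_kinetics(doses, induced, unit = "mM")
  expect_true(fit$converged)
  expect_equal(fit$K_half, 6.73, tolerance = 0.25)
})
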