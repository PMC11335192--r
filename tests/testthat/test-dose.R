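test_that("noise-free Hill points are recovered to 1e-6 relative", {
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 50)
  tab <- dose_response_table(concs, hill_current(concs, -76.15, 11.57),
                             unit = "mM")
  fit <- suppressMessages(fit_dose_response(tab))
  expect_true(fit$converged)
  expect_equal(fit$Imax_nA, -76.15, tolerance = 1e-6)
  expect_equal(fit$K_half, 11.57, tolerance = 1e-6)
  expect_equal(fit$p, 1, tolerance = 1e-6)
  # half-saturation identity of the fitted curve
  expect_equal(predict(fit, fit$K_half), fit$Imax_nA / 2, tolerance = 1e-9)
})

test_that("degenerate and invalid dose-response inputs are handled", {
  concs <- c(1, 3, 10, 30)
  zero <- dose_response_table(concs, rep(0, 4), unit = "mM")
  fit <- suppressMessages(fit_dose_response(zero))
  expect_false(fit$converged)
  expect_equal(fit$Imax_nA, 0)
  expect_error(dose_response_table(c(-1, 1, 2, 3), 1:4), "positive")
  expect_error(dose_response_table(c(3, 1, 2, 4), 1:4), "increasing")
  three <- dose_response_table(concs[1:3], hill_current(concs[1:3], -76, 11))
  expect_error(suppressMessages(fit_dose_response(three)), ">= 4")
  # but 3 points suffice with a fixed exponent
  fit3 <- suppressMessages(fit_dose_response(three, fix_p = 1))
  expect_true(fit3$converged)
  expect_equal(fit3$K_half, 11, tolerance = 1e-4)
})

test_that("weighted fits honour 1/sem^2 weights", {
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 50)
  y <- hill_current(concs, -76.15, 11.57)
  y_bad <- y
  y_bad[7] <- y[7] + 20  # corrupt the top point
  sem <- rep(0.5, 7)
  sem[7] <- 50           # ...but with a huge SEM, so it is down-weighted
  tab <- dose_response_table(concs, y_bad, sem_nA = sem, unit = "mM")
  fit_w <- fit_dose_response(tab)
  tab_u <- dose_response_table(concs, y_bad, unit = "mM")
  fit_u <- suppressMessages(fit_dose_response(tab_u))
  expect_lt(abs(fit_w$K_half - 11.57), abs(fit_u$K_half - 11.57))
  expect_lt(abs(fit_w$K_half - 11.57) / 11.57, 0.02)
})

test_that("transport efficiency reproduces Imax/K_half with a delta-method
           SE validated by Monte Carlo", {
  skip_if_not_installed("MASS")
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 50)
  y <- hill_current(concs, -76.15, 11.57) +
    withr::with_seed(21, rnorm(7, 0, 1.5))
  tab <- dose_response_table(concs, y, unit = "mM")
  fit <- suppressMessages(fit_dose_response(tab, fix_p = 1))
  eff <- transport_efficiency(fit)
  expect_equal(eff$efficiency, fit$Imax_nA / fit$K_half)
  expect_equal(eff$unit, "nA/mM")
  draws <- withr::with_seed(22, MASS::mvrnorm(
    10000, mu = c(fit$Imax_nA, fit$K_half),
    Sigma = fit$cov[c("Imax", "K"), c("Imax", "K")]))
  mc_se <- sd(draws[, 1] / draws[, 2])
  expect_equal(eff$se, mc_se, tolerance = 0.1)
})

test_that("efficiency is invariant under a consistent unit rescaling", {
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 50)
  y <- hill_current(concs, -76.15, 11.57)
  fit_mM <- suppressMessages(
    fit_dose_response(dose_response_table(concs, y, unit = "mM")))
  fit_uM <- suppressMessages(
    fit_dose_response(dose_response_table(concs * 1000, y, unit = "uM")))
  eff_mM <- transport_efficiency(fit_mM)$efficiency
  eff_uM <- transport_efficiency(fit_uM)$efficiency
  expect_equal(eff_uM * 1000, eff_mM, tolerance = 1e-6)
  expect_equal(sign(eff_mM), sign(fit_mM$Imax_nA))
})

test_that("K_half is recovered within 15 percent under 5 percent noise
           (median over 50 seeds)", {
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 50)
  sd_noise <- 0.05 * 76.15
  errs <- vapply(1:50, function(r) {
    tab <- simulate_dose_response(-76.15, 11.57, 1, concs, n_replicates = 8,
                                  noise = noise_spec(sd_noise, 7000 + r))
    fit <- suppressMessages(fit_dose_response(tab))
    abs(fit$K_half - 11.57) / 11.57
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})
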