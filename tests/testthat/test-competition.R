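# Transport parameters that make the dual effect visible: the millimolar
# substrate carries a small maximal current and has a high-potency
# modulatory (cycle-slowing) action on the GABA-borne current.
h_dual_params <- function() {
  two_substrate_params(I_G_nA = -120, K_G_uM = 16, I_B_nA = -12,
                       K_B_mM = 11.57, K_inh_mM = 0.4,
                       voltage_scale = voltage_scale_unity())
}

h_grid_levels <- function() {
  list(gaba = c(0, 1, 3, 10, 30, 100, 300),
       betaine = c(0, 0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 50))
}

test_that("the canonical composition yields 84 measured conditions", {
  lv <- h_grid_levels()
  rec <- h_competition_records(h_dual_params(), lv$gaba, lv$betaine)
  grid <- build_competition_grid(rec)
  expect_equal(grid$n_conditions, 84)
  expect_equal(length(grid$gaba_uM) * length(grid$betaine_mM), 84)
  # noise-free means equal the model values exactly
  for (g in c(1, 10, 300)) {
    i <- which(grid$gaba_uM == g)
    expect_equal(unname(grid$mean_nA[i, ]),
                 model_two_substrate(g, grid$betaine_mM, h_dual_params()),
                 tolerance = 1e-12)
  }
})

test_that("grid validation: reference cell, SEM of singletons, incomplete
           composition", {
  lv <- h_grid_levels()
  rec <- h_competition_records(h_dual_params(), lv$gaba, lv$betaine,
                               n_cells = 1)
  grid <- build_competition_grid(rec)
  expect_true(all(is.na(grid$sem_nA)))  # SEM undefined for n = 1
  no_ref <- rec[!(rec$gaba_uM == 0 & rec$betaine_mM == 0), ]
  expect_error(build_competition_grid(no_ref), "reference")
  holey <- rec[!(rec$gaba_uM == 3 & rec$betaine_mM == 1), ]
  expect_warning(build_competition_grid(holey), "incomplete")
  expect_error(build_competition_grid(data.frame(x = 1)), "columns")
})

test_that("dual-effect rows below K_G are biphasic with the split at the
           brute-force model minimizer", {
  lv <- h_grid_levels()
  prm <- h_dual_params()
  rec <- h_competition_records(prm, lv$gaba, lv$betaine)
  grid <- build_competition_grid(rec)
  for (g in c(1, 3, 10)) {  # all below K_G = 16 uM
    de <- analyze_dual_effect(grid, g)
    expect_true(de$biphasic)
    mags <- abs(model_two_substrate(g, lv$betaine, prm))
    expect_equal(de$split_betaine_mM, lv$betaine[which.min(mags)])
    expect_true(de$inhibition$converged)
  }
  # the ascending limb is fitted when >= 3 levels lie strictly above the
  # split (GABA 1 and 3 uM rows); the 10 uM row's minimum sits too high on
  # the betaine axis for a limb fit, but the row is still biphasic
  expect_true(analyze_dual_effect(grid, 1)$transport$converged)
  expect_true(analyze_dual_effect(grid, 3)$transport$converged)
})

test_that("the dual effect vanishes at GABA >= 10 K_G (monotone row)", {
  lv <- h_grid_levels()
  prm <- h_dual_params()
  rec <- h_competition_records(prm, lv$gaba, lv$betaine)
  grid <- build_competition_grid(rec)
  de <- analyze_dual_effect(grid, 300)  # 300 uM = 18.75 K_G
  expect_false(de$biphasic)
  expect_match(de$reason, "monoton")
})

test_that("a strictly increasing row is monotone with no inhibition
           branch", {
  # pure competitive scheme (no modulatory site), tiny G: |I| only grows
  prm <- two_substrate_params(I_G_nA = -1, K_G_uM = 16, I_B_nA = -76,
                              K_B_mM = 11.57,
                              voltage_scale = voltage_scale_unity())
  lv <- h_grid_levels()
  rec <- h_competition_records(prm, c(0, 1), lv$betaine)
  grid <- build_competition_grid(rec)
  de <- analyze_dual_effect(grid, 1)
  expect_false(de$biphasic)
  expect_null(de$inhibition)
})

test_that("normalized inhibition matches the direct model ratio", {
  lv <- h_grid_levels()
  prm <- h_dual_params()
  rec <- h_competition_records(prm, lv$gaba, lv$betaine)
  grid <- build_competition_grid(rec)
  ni <- normalized_inhibition(grid, 10)
  expect_equal(ni$fraction[ni$betaine_mM == 0], 1)
  want <- model_two_substrate(10, lv$betaine, prm) /
    model_two_substrate(10, 0, prm)
  expect_equal(ni$fraction, want, tolerance = 1e-12)
  # analytic spot check in the pure competitive scheme:
  # G = K_G with non-transported B at K_B -> (I_G/3)/(I_G/2) = 2/3
  prm2 <- two_substrate_params(I_B_nA = 0,
                               voltage_scale = voltage_scale_unity())
  rec2 <- h_competition_records(prm2, c(0, prm2$K_G_uM),
                                c(0, prm2$K_B_mM))
  grid2 <- build_competition_grid(rec2)
  ni2 <- normalized_inhibition(grid2, prm2$K_G_uM)
  expect_equal(ni2$fraction[ni2$betaine_mM == prm2$K_B_mM], 2 / 3,
               tolerance = 1e-12)
  # zero reference current is an error
  rec0 <- h_competition_records(prm2, c(0, 1), c(0, 1))
  rec0$current_nA[rec0$gaba_uM == 1 & rec0$betaine_mM == 0] <- 0
  grid0 <- build_competition_grid(rec0)
  expect_error(normalized_inhibition(grid0, 1), "zero")
})
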