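test_that("strong-acid media reproduce the nominal pH scale in ideal mode", {
  for (c_acid in c(1e-4, 1e-3, 1e-2, 0.1, 1)) {
    res <- compute_ph(medium(1, HCl = c_acid), mode = "ideal")
    # exact closed form including water autoionization
    h_exact <- (c_acid + sqrt(c_acid^2 + 4e-14)) / 2
    expect_equal(res$pH, -log10(h_exact), tolerance = 1e-9)
    # the nominal -log10(c) value, to which autoionization contributes
    # at most ~4e-7 pH units over this range
    expect_equal(res$pH, -log10(c_acid), tolerance = 1e-6)
  }
  expect_equal(compute_ph(medium(0.75, HCl = 0.1), mode = "ideal")$pH, 1.0,
               tolerance = 1e-9)
})

test_that("pure water is neutral", {
  expect_equal(compute_ph(medium(1), mode = "ideal")$pH, 7.0, tolerance = 1e-9)
})

test_that("the two-stage buffer mix reaches pH 6.8 only with activity correction", {
  usp <- mix_media(medium(0.750, HCl = 0.1), medium(0.250, Na3PO4 = 0.2))
  expect_equal(usp$volume_L, 1.0)
  expect_equal(unname(usp$totals[["HCl"]]), 0.075)
  expect_equal(unname(usp$totals[["Na3PO4"]]), 0.050)
  davies <- compute_ph(usp, mode = "davies")
  expect_equal(davies$pH, 6.8, tolerance = 0.1)
  # without the activity correction the mixture sits at phosphate pKa2
  ideal <- compute_ph(usp, mode = "ideal")
  expect_equal(ideal$pH, 7.198, tolerance = 0.01)
})

test_that("speciation closes the charge and phosphate mass balances", {
  usp <- mix_media(medium(0.750, HCl = 0.1), medium(0.250, Na3PO4 = 0.2))
  for (mode in c("ideal", "davies")) {
    res <- compute_ph(usp, mode = mode)
    expect_lt(abs(res$charge_residual), 1e-10)
    forms <- sum(res$speciation[c("H3PO4", "H2PO4-", "HPO4-2", "PO4-3")])
    expect_equal(forms, 0.050, tolerance = 1e-8)
  }
})

test_that("mixing conserves moles and is identity/idempotent in the limits", {
  m <- medium(0.4, HCl = 0.02, Na3PO4 = 0.01)
  # near-zero aliquot leaves concentrations unchanged
  almost_same <- mix_media(m, medium(1e-12))
  expect_equal(almost_same$totals, m$totals, tolerance = 1e-9)
  doubled <- mix_media(m, m)
  expect_equal(doubled$volume_L, 0.8)
  expect_equal(doubled$totals, m$totals)
  expect_error(mix_media(list()), class = "pbpk_data_error")
})

test_that("davies and ideal agree in the dilute limit", {
  set.seed(11)
  for (i in 1:10) {
    m <- medium(1, HCl = runif(1, 0, 1e-4), NaH2PO4 = runif(1, 0, 1e-4))
    d <- compute_ph(m, "davies")$pH
    id <- compute_ph(m, "ideal")$pH
    expect_lt(abs(d - id), 0.02)
  }
})

test_that("solver matches an independent grid+bisection oracle on random media", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    tot <- list(hcl = runif(1, 0, 0.2), naoh = runif(1, 0, 0.1),
                na3po4 = if (runif(1) < 0.5) runif(1, 0, 0.05) else 0,
                nah2po4 = if (runif(1) < 0.5) runif(1, 0, 0.05) else 0)
    m <- medium(1, HCl = tot$hcl, NaOH = tot$naoh, Na3PO4 = tot$na3po4,
                NaH2PO4 = tot$nah2po4)
    mode <- if (i %% 5 == 0) "davies" else "ideal"
    worst <- max(worst, abs(oracle_ph(tot, mode) - compute_ph(m, mode)$pH))
  }
  expect_lt(worst, 1e-6)
})

test_that("infeasible media are reported rather than silently mis-solved", {
  # 2 M NaOH puts the root outside the H+ bracket
  expect_error(compute_ph(medium(1, NaOH = 2), mode = "ideal"),
               class = "pbpk_infeasible_medium_error")
})

test_that("titration volume matches a 1-uL brute-force scan and is monotone", {
  vessel <- medium(0.5, HCl = 0.001)
  base <- medium(1, NaOH = 2)
  v <- titrant_volume_for_ph(vessel, base, 7.0, mode = "ideal")
  v_oracle <- oracle_titrant_volume(0.5, 0.001, 2, 7.0)
  expect_lt(abs(v - v_oracle), 2e-6)
  # zero volume when already at target
  ph0 <- compute_ph(vessel, "ideal")$pH
  expect_identical(titrant_volume_for_ph(vessel, base, ph0, "ideal"), 0)
  # more base for higher targets
  v_higher <- titrant_volume_for_ph(vessel, base, 9.0, mode = "ideal")
  expect_gt(v_higher, v)
  # wrong-direction request fails loudly
  expect_error(titrant_volume_for_ph(vessel, base, 2.0, "ideal"),
               class = "pbpk_titration_direction_error")
})

test_that("registry constraints are enforced", {
  expect_error(medium(1, Unobtainium = 0.1), class = "pbpk_data_error")
  expect_error(medium(0, HCl = 0.1), class = "pbpk_data_error")
  expect_error(medium(1, HCl = -0.1), class = "pbpk_data_error")
})
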