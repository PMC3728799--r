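test_that("noiseless self-fit reaches a near-zero objective", {
  study <- synthetic_study(seed = 1, sigma = 0)
  ds <- generate_plasma(study, "medium")
  cal <- calibrate_pbpk(ds, study$physiology, free = c("PA_si", "CL_hepatic"))
  expect_lt(cal$objective, 1e-10)
  est <- setNames(cal$fitted$value, cal$fitted$parameter)
  expect_equal(est[["PA_si"]], study$physiology[["PA_si"]], tolerance = 1e-4)
  expect_equal(est[["CL_hepatic"]], study$physiology[["CL_hepatic"]],
               tolerance = 1e-4)
})

test_that("identifiability and free-set guards fire before any fitting", {
  study <- synthetic_study(seed = 2, sigma = 0,
                           plasma_grid = c(1, 2, 4, 8, 12))
  ds <- generate_plasma(study, "medium")
  expect_error(
    calibrate_pbpk(ds, study$physiology,
                   free = c("PA_si", "CL_hepatic", "Q_tissues",
                            "F_unbound_factor", "CL_renal")),
    class = "pbpk_identifiability_error")
  expect_error(calibrate_pbpk(ds, study$physiology, free = character(0)),
               class = "pbpk_data_error")
  expect_error(calibrate_pbpk(ds, study$physiology, free = "Q_portal"),
               class = "pbpk_data_error")
  expect_error(calibrate_pbpk(ds, study$physiology, free = "not_a_param"),
               class = "pbpk_data_error")
})

test_that("prediction with frozen parameters reproduces the calibration curve", {
  study <- synthetic_study(seed = 3, sigma = 0)
  ds <- generate_plasma(study, "medium")
  cal <- calibrate_pbpk(ds, study$physiology, free = "PA_si")
  grid <- sort(unique(c(0, ds$time_h)))
  pred <- predict_formulation(cal, attr(ds, "dose"), grid)
  direct <- simulate_pbpk(cal$physiology, attr(ds, "dose"), grid)
  expect_equal(pred$trajectory$conc_plasma, direct$conc_plasma)
})

test_that("tampered calibrations are rejected at prediction time", {
  study <- synthetic_study(seed = 4, sigma = 0)
  ds <- generate_plasma(study, "medium")
  cal <- calibrate_pbpk(ds, study$physiology, free = "PA_si")
  tampered <- cal
  tampered$fitted$value <- tampered$fitted$value * 1.3
  expect_error(
    predict_formulation(tampered, attr(ds, "dose"), c(0, 1, 2, 4)),
    class = "pbpk_frozen_parameter_error")
  tampered2 <- cal
  p <- unclass(tampered2$physiology); p[["PA_si"]] <- p[["PA_si"]] * 2
  tampered2$physiology <- physiology_spec(p)
  expect_error(
    predict_formulation(tampered2, attr(ds, "dose"), c(0, 1, 2, 4)),
    class = "pbpk_frozen_parameter_error")
})

test_that("slower release never predicts a higher Cmax at equal dose", {
  study <- synthetic_study(seed = 5, sigma = 0)
  ds <- generate_plasma(study, "medium")
  cal <- calibrate_pbpk(ds, study$physiology, free = "PA_si")
  grid <- seq(0, 24, by = 0.25)
  cmax <- vapply(c(1.5, 3, 6, 12), function(tau) {
    d <- dose_event("oral", 100,
                    release_model = release_model("weibull", 100, tau, beta = 1.6))
    predict_formulation(cal, d, grid)$metrics$Cmax
  }, numeric(1))
  expect_true(all(diff(cmax) < 0))
})

test_that("calibration tidiers expose estimates, bounds and convergence", {
  study <- synthetic_study(seed = 6, sigma = 0)
  ds <- generate_plasma(study, "medium")
  cal <- calibrate_pbpk(ds, study$physiology, free = "PA_si")
  td <- tidy(cal)
  expect_identical(td$term, "PA_si")
  expect_true(td$lower < td$estimate && td$estimate < td$upper)
  gl <- glance(cal)
  expect_identical(gl$n_free, 1L)
  expect_identical(gl$n_obs, nrow(ds))
  # fitted + fixed cover the 22 parameters exactly once
  expect_setequal(c(cal$fitted$parameter, names(cal$fixed)),
                  physiology_parameter_names)
})
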