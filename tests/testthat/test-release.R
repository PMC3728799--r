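test_that("cumulative release has the right closed-form values and limits", {
  w <- release_model("weibull", M_inf = 100, tau = 2, beta = 1)
  expect_equal(evaluate_cumulative(w, 0), 0)
  expect_equal(evaluate_cumulative(w, 2), 100 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(evaluate_cumulative(w, 50 * 2), 100, tolerance = 1e-6)
  z <- release_model("zero_order_capped", M_inf = 100, tau = 4)
  expect_equal(evaluate_cumulative(z, 2), 50)
  expect_equal(evaluate_cumulative(z, 10), 100)
  lagged <- release_model("weibull", 100, 2, beta = 2, t_lag = 1)
  expect_equal(evaluate_cumulative(lagged, 0.5), 0)
  expect_error(evaluate_cumulative(w, -1), class = "pbpk_data_error")
})

test_that("release curves are continuous and non-decreasing", {
  models <- list(
    release_model("weibull", 100, 3, beta = 1.6),
    release_model("weibull", 80, 1.5, beta = 0.7, t_lag = 0.5),
    release_model("first_order", 100, 2),
    release_model("zero_order_capped", 100, 5, t_lag = 1)
  )
  tt <- seq(0, 40, by = 0.01)
  for (m in models) {
    y <- evaluate_cumulative(m, tt)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y <= m$M_inf + 1e-9))
    expect_lt(max(abs(diff(y))), m$M_inf * 0.05) # no jumps on a fine grid
  }
})

test_that("the analytic rate integrates back to the cumulative curve", {
  models <- list(
    release_model("weibull", 100, 3, beta = 1.6),
    release_model("first_order", 100, 2),
    release_model("zero_order_capped", 100, 5)
  )
  for (m in models) {
    q <- integrate(function(t) release_rate(m, t), 0, 50 * m$tau,
                   subdivisions = 2000, rel.tol = 1e-10)
    expect_equal(q$value, m$M_inf, tolerance = 1e-6)
    tt <- seq(0, 10 * m$tau, length.out = 500)
    expect_true(all(release_rate(m, tt) >= 0))
  }
  # initial-rate closed forms
  z <- release_model("zero_order_capped", 100, 4)
  expect_equal(release_rate(z, 1), 25)
  fo <- release_model("weibull", 100, 2, beta = 1)
  expect_equal(release_rate(fo, 0), 50)
})

test_that("noiseless profiles are recovered essentially exactly", {
  truth <- release_model("weibull", 100, 3, beta = 1.6)
  tt <- seq(0.5, 12, length.out = 12)
  prof <- dissolution_profile(tt, evaluate_cumulative(truth, tt))
  fit <- fit_release(prof, "weibull")
  expect_equal(fit$M_inf, 100, tolerance = 1e-4)
  expect_equal(fit$tau, 3, tolerance = 1e-4)
  expect_equal(fit$beta, 1.6, tolerance = 1e-4)
})

test_that("weibull nests first-order: beta is recovered near 1", {
  truth <- release_model("first_order", 100, 2.5)
  tt <- seq(0.25, 15, length.out = 14)
  prof <- dissolution_profile(tt, evaluate_cumulative(truth, tt))
  fit <- fit_release(prof, "weibull")
  expect_equal(fit$beta, 1, tolerance = 1e-3)
})

test_that("degenerate profiles raise fit errors instead of silent models", {
  tt <- seq(1, 8, by = 1)
  zeros <- dissolution_profile(tt, rep(0, length(tt)))
  expect_error(fit_release(zeros, "weibull"), class = "pbpk_fit_error")
  bouncy <- dissolution_profile(tt, c(10, 40, 20, 50, 60, 70, 80, 85))
  expect_error(fit_release(bouncy, "weibull"), class = "pbpk_fit_error")
  short <- dissolution_profile(c(1, 2, 3), c(10, 20, 30))
  expect_error(fit_release(short, "weibull"), class = "pbpk_fit_error")
})

test_that("model selection picks the generating form", {
  tt <- seq(0.5, 12, length.out = 12)
  wprof <- dissolution_profile(
    tt, evaluate_cumulative(release_model("weibull", 100, 3, beta = 2.2), tt))
  sel <- select_release_model(wprof, c("weibull", "zero_order_capped"))
  expect_identical(sel$form, "weibull")
  # a clean linear ramp: the 2-parameter capped form wins on parsimony
  ramp <- dissolution_profile(tt, pmin(100, 100 / 10 * tt))
  sel2 <- select_release_model(ramp, c("weibull", "zero_order_capped"))
  expect_identical(sel2$form, "zero_order_capped")
  # single candidate degenerates to fit_release
  one <- select_release_model(wprof, "weibull")
  expect_equal(one$tau, fit_release(wprof, "weibull")$tau)
})

test_that("tidy and glance expose release-fit parameters and diagnostics", {
  tt <- seq(0.5, 12, length.out = 12)
  prof <- dissolution_profile(
    tt, evaluate_cumulative(release_model("weibull", 100, 3, beta = 1.6), tt))
  fit <- fit_release(prof, "weibull")
  td <- tidy(fit)
  expect_setequal(td$term, c("M_inf", "tau", "beta"))
  gl <- glance(fit)
  expect_identical(gl$form, "weibull")
  expect_lt(gl$rss, 1e-6)
})
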