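test_that("the two-stage run reproduces the pharmacopoeial chemistry", {
  run <- run_usp_method_a(duration_buffer_h = 8)
  acid <- run[run$stage == "acid_stage", ]
  buf <- run[run$stage == "buffer_stage", ]
  expect_equal(unique(acid$pH), 1.0, tolerance = 1e-9)
  expect_equal(buf$pH[1], 6.8, tolerance = 0.1)
  expect_equal(unique(buf$volume_L), 1.0)
  expect_equal(unique(acid$volume_L), 0.75)
  expect_equal(max(acid$time_h), 2)
  # stage-1 chemistry shares the speciation code path exactly
  expect_identical(unique(acid$pH),
                   compute_ph(medium(0.75, HCl = 0.1), "ideal")$pH)
})

test_that("an enteric (pH-gated) tablet releases nothing in the acid stage", {
  tab <- tablet(release_model("weibull", 100, tau = 2, beta = 1.2),
                ph_threshold = 5.5)
  run <- run_usp_method_a(tab, duration_buffer_h = 8)
  expect_equal(max(run$released_mg[run$stage == "acid_stage"]), 0)
  expect_gt(max(run$released_mg[run$stage == "buffer_stage"]), 50)
})

test_that("a flat pH program doses at most one titrant quantum", {
  prog <- ph_program(c(0, 0.5), c(4.8, 4.8))
  run <- run_ph_program(prog)
  ctrl <- ph_controller()
  quantum <- ctrl$pump_max_L_per_h * ctrl$dt_s / 3600
  expect_lt(max(run$acid_added_L + run$base_added_L), quantum)
  expect_equal(run$pH[1], 4.8, tolerance = 1e-6)
})

test_that("a setpoint step settles within ten control intervals", {
  prog <- ph_program(c(0, 2, 2.0001, 3), c(4.8, 4.8, 6.8, 6.8))
  run <- run_ph_program(prog)
  # first control interval at which the controller sees the new setpoint
  i_step <- which(run$setpoint > 5.8)[1]
  expect_lt(abs(run$pH[i_step + 10] - 6.8), 0.05)
  expect_lt(abs(run$pH[nrow(run)] - 6.8), 0.05)
})

test_that("the fed-stomach program is tracked within 0.1 pH units on average", {
  run <- run_ph_program(fed_stomach_program())
  expect_lt(mean(abs(run$pH - run$setpoint)), 0.1)
  expect_false(attr(run, "unreachable"))
})

test_that("the controller respects pump physics and volume bookkeeping", {
  prog <- ph_program(c(0, 2, 2.0001, 3), c(4.8, 4.8, 6.8, 6.8))
  run <- run_ph_program(prog)
  d_acid <- diff(run$acid_added_L)
  d_base <- diff(run$base_added_L)
  # never dose acid and base in the same interval
  expect_false(any(d_acid > 0 & d_base > 0))
  # added volumes are non-decreasing and bounded by pump capacity
  ctrl <- ph_controller()
  quantum <- ctrl$pump_max_L_per_h * ctrl$dt_s / 3600
  expect_true(all(d_acid >= 0 & d_base >= 0))
  expect_true(all(d_acid <= quantum + 1e-15 & d_base <= quantum + 1e-15))
  # vessel volume = initial + everything the pumps added
  n <- nrow(run)
  expect_equal(run$volume_L[-1],
               run$volume_L[1] + run$acid_added_L[-n] + run$base_added_L[-n],
               tolerance = 1e-12)
})

test_that("release comparison reproduces the enteric-coat contrast", {
  gated <- tablet(release_model("weibull", 100, tau = 2, beta = 1.2),
                  ph_threshold = 5.5)
  usp <- run_usp_method_a(gated, duration_buffer_h = 2)
  fed <- run_ph_program(fed_stomach_program(), tab = gated)
  tbl <- compare_release(usp, fed, labels = c("usp", "fed"))
  expect_equal(tbl$released_mg[tbl$protocol == "usp" & tbl$stage == "acid_stage"], 0)
  expect_gt(sum(tbl$released_mg[tbl$protocol == "fed"]), 0)
  # identical runs give identical tables
  tbl_same <- compare_release(usp, usp)
  expect_equal(tbl_same$released_mg[tbl_same$protocol == "protocol_a"],
               tbl_same$released_mg[tbl_same$protocol == "protocol_b"])
})

test_that("pH-independent release depends only on elapsed time, not protocol", {
  free_tab <- tablet(release_model("weibull", 100, tau = 2, beta = 1.2))
  dur <- 4
  usp <- run_usp_method_a(free_tab, duration_buffer_h = dur - 2)
  prog <- run_ph_program(fed_stomach_program(duration_h = dur), tab = free_tab)
  expect_equal(max(usp$released_mg), max(prog$released_mg), tolerance = 1e-6)
  tbl <- compare_release(usp, prog)
  expect_equal(sum(tbl$released_mg[tbl$protocol == "protocol_a"]),
               sum(tbl$released_mg[tbl$protocol == "protocol_b"]),
               tolerance = 1e-4)
})

test_that("mismatched tablets cannot be compared", {
  a <- run_usp_method_a(tablet(release_model("weibull", 100, 2, beta = 1.2)),
                        duration_buffer_h = 1)
  b <- run_usp_method_a(tablet(release_model("weibull", 50, 2, beta = 1.2)),
                        duration_buffer_h = 1)
  expect_error(compare_release(a, b), class = "pbpk_data_error")
})
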