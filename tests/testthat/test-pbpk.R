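test_that("model structure: 7 compartment ODEs and 22 physiology parameters", {
  expect_length(pbpk_compartments, 7L)
  expect_length(physiology_parameter_names, 22L)
  phys <- default_physiology()
  expect_length(unclass(phys), 22L)
  # construction rejects incomplete or extended parameter sets
  p <- unclass(phys)
  expect_error(physiology_spec(p[-1]), class = "pbpk_data_error")
  expect_error(physiology_spec(c(p, extra = 1)), class = "pbpk_data_error")
  # flow balance is a construction invariant
  p2 <- p; p2[["Q_portal"]] <- p2[["Q_gics"]] * 2
  expect_error(physiology_spec(p2), class = "pbpk_data_error")
})

test_that("the RHS conserves mass identically for random states", {
  phys <- default_physiology()
  rel <- release_model("weibull", 100, tau = 3, beta = 1.6)
  dose <- dose_event("oral", 100, release_model = rel)
  nm <- c(pbpk_compartments, pbpkivivc:::pbpk_sinks)
  set.seed(5)
  for (i in 1:20) {
    st <- setNames(runif(length(nm), 0, 50), nm)
    loc <- sample(c("stomach", "si", "li", "exited"), 1)
    d <- pbpk_rhs(runif(1, 0, 10), st, phys, dose, location = loc)
    expect_lt(abs(sum(d)), 1e-12 * max(1, max(abs(d))))
  }
  # zero state, no dose flux: derivative identically zero
  zero <- setNames(numeric(length(nm)), nm)
  d0 <- pbpk_rhs(1, zero, phys, dose, location = "exited")
  expect_true(all(d0 == 0))
})

test_that("equal lumen and gut-circulation concentrations give zero wall flux", {
  phys <- default_physiology()
  dose <- dose_event("iv_bolus", 10)
  nm <- c(pbpk_compartments, pbpkivivc:::pbpk_sinks)
  st <- setNames(numeric(length(nm)), nm)
  c_eq <- 2 # mg/L on both sides of the SI wall
  st[["si_lumen"]] <- c_eq * phys[["V_lumen_si"]]
  st[["gics"]] <- c_eq * phys[["V_gics"]]
  d <- pbpk_rhs(0.5, st, phys, dose, location = "none")
  # SI lumen only loses mass by transit, not by diffusion
  expect_equal(unname(d[["si_lumen"]]),
               -phys[["k_si_transit"]] * st[["si_lumen"]], tolerance = 1e-12)
})

test_that("the fast solver RHS is flux-for-flux identical to the reference", {
  phys <- default_physiology()
  rel <- release_model("weibull", 100, tau = 3, beta = 1.6)
  dose <- dose_event("oral", 100, release_model = rel)
  nm <- c(pbpk_compartments, pbpkivivc:::pbpk_sinks)
  set.seed(9)
  for (loc in c("stomach", "si", "li", "exited")) {
    st <- setNames(runif(length(nm), 0, 30), nm)
    ref <- pbpk_rhs(2.5, st, phys, dose, location = loc)
    fast <- pbpkivivc:::make_fast_rhs(phys, dose, loc, 0)(2.5, unname(st), NULL)[[1]]
    expect_equal(unname(ref), fast, tolerance = 1e-12)
  }
})

test_that("IV bolus with decoupled compartments follows the mono-exponential", {
  p <- unclass(default_physiology())
  p[c("Q_gics", "Q_portal", "Q_hepatic_out", "Q_tissues", "PA_stomach",
      "PA_si", "PA_li", "CL_hepatic", "k_gastric", "k_si_transit",
      "k_li_transit")] <- 0
  p[["V_plasma"]] <- 5
  p[["CL_renal"]] <- 2.5
  phys <- physiology_spec(p)
  traj <- simulate_pbpk(phys, dose_event("iv_bolus", 100), seq(0, 10, by = 0.25))
  k <- 2.5 / 5
  expected <- (100 / 5) * exp(-k * traj$time_h)
  expect_equal(traj$conc_plasma, expected, tolerance = 1e-6)
})

test_that("with no gut-wall permeability an oral dose never reaches plasma", {
  p <- unclass(default_physiology())
  p[c("PA_stomach", "PA_si", "PA_li")] <- 0
  p[c("k_gastric", "k_si_transit", "k_li_transit")] <- c(3, 1, 1)
  phys <- physiology_spec(p)
  rel <- release_model("weibull", 100, tau = 1, beta = 1.6)
  traj <- simulate_pbpk(phys, dose_event("oral", 100, release_model = rel),
                        c(seq(0, 30, by = 0.5), seq(35, 120, by = 5)))
  expect_true(all(traj$plasma == 0))
  last <- traj[nrow(traj), ]
  expect_equal(last$excreted_fecal + last$unreleased, 100, tolerance = 1e-6)
})

test_that("mass is conserved along every simulated trajectory", {
  phys <- default_physiology()
  rel <- release_model("weibull", 100, tau = 3, beta = 1.6)
  cases <- list(
    dose_event("oral", 100, release_model = rel),
    dose_event("iv_bolus", 50),
    dose_event("iv_infusion", 80, start_h = 1, duration_h = 2)
  )
  for (dose in cases) {
    traj <- simulate_pbpk(phys, dose, seq(0, 36, by = 0.5))
    m <- mass_in_system(traj)
    after <- traj$time_h >= dose$start_h
    expect_lt(max(abs(m[after] - dose$amount_mg)) / dose$amount_mg, 1e-6)
    amounts <- as.matrix(as.data.frame(traj)[, pbpk_compartments])
    expect_gt(min(amounts), -1e-9)
  }
})

test_that("an infusion delivers its dose linearly over the window", {
  phys <- default_physiology()
  dose <- dose_event("iv_infusion", 60, start_h = 1, duration_h = 3)
  traj <- simulate_pbpk(phys, dose, seq(0, 8, by = 0.5))
  undelivered <- traj$undelivered_iv
  expect_equal(undelivered[traj$time_h == 1], 60)
  expect_equal(undelivered[traj$time_h == 2.5], 30, tolerance = 1e-6)
  expect_equal(undelivered[traj$time_h == 6], 0, tolerance = 1e-8)
})

test_that("dosage-form transit windows give the standard switch times", {
  phys <- default_physiology()
  sw <- dosage_form_transit_times(phys)
  expect_equal(unname(sw), c(2, 5, 29))
  expect_true(all(diff(sw) > 0))
  # zero SI residence: the form passes straight to the large intestine
  p <- unclass(phys); p[["t_form_si"]] <- 0
  sw0 <- dosage_form_transit_times(physiology_spec(p))
  expect_equal(unname(sw0[1:2]), c(2, 2))
  dose <- dose_event("oral", 100,
                     release_model = release_model("weibull", 100, 1, beta = 1.6))
  expect_identical(
    pbpkivivc:::dosage_form_location(2.5, dose, sw0), "li")
})

test_that("more intestinal permeability means more exposure while absorption-limited", {
  # monotone in the absorption-limited regime (up to the default PA_si);
  # far beyond it, back-secretion into the lumen and repeated portal passes
  # make AUC weakly non-monotone, which is a real property of the topology
  base <- unclass(default_physiology())
  rel <- release_model("weibull", 100, tau = 3, beta = 1.6)
  dose <- dose_event("oral", 100, release_model = rel)
  aucs <- vapply(c(0.1, 0.3, 0.8, 1.5, 2.5), function(pa) {
    p <- base; p[["PA_si"]] <- pa
    traj <- simulate_pbpk(physiology_spec(p), dose, seq(0, 36, by = 0.5))
    nca_metrics(traj$time_h, traj$conc_plasma)$AUC_0_last
  }, numeric(1))
  expect_true(all(diff(aucs) > -1e-9))
})

test_that("trajectory concentrations and the tidy writer are consistent", {
  phys <- default_physiology()
  traj <- simulate_pbpk(phys, dose_event("iv_bolus", 100), seq(0, 4, by = 0.5))
  expect_equal(traj$conc_plasma, traj$plasma / phys[["V_plasma"]])
  long <- tidy_trajectory(traj)
  expect_setequal(unique(long$compartment), pbpk_compartments)
  expect_equal(nrow(long), nrow(traj) * 7L)
})
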