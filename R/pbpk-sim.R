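pbpk_state_names <- function() c(pbpk_compartments, pbpk_sinks)

#' Mass-balance right-hand side of the PBPK model
#'
#' Derivatives of the 7 compartment amounts plus the bookkeeping states
#' (`unreleased` drug still in the dosage form, cumulative metabolic,
#' renal and fecal sinks, and the undelivered part of an infusion).
#' Every flux appears once with each sign, so the algebraic sum of all
#' returned derivatives is identically zero: whatever leaves a
#' compartment enters another one or a sink. Fluxes:
#'
#' * release of dissolved drug from the intact form into the lumen where
#'   the form currently resides, at the release model's analytic rate;
#' * first-order lumen-to-lumen transit of dissolved drug
#'   (stomach -> SI -> LI -> feces);
#' * passive diffusion across the gut wall, `PA_i * (C_lumen_i - C_gics)`;
#' * perfusion loop plasma -> gut circulation -> liver (portal) -> plasma;
#' * plasma <-> tissues exchange `Q_tissues * (C_plasma -
#'   C_tissues/F_unbound_factor)`;
#' * first-order hepatic metabolism and renal elimination;
#' * the intravenous inlet during a bolus/infusion.
#'
#' @param t Time, hours.
#' @param state Named state vector (mg); see [pbpk_compartments].
#' @param physiology A [physiology_spec()].
#' @param dose A [dose_event()].
#' @param location Location of the intact dosage form (`"stomach"`,
#'   `"si"`, `"li"`, `"exited"`, `"none"`). Computed from
#'   [dosage_form_transit_times()] with default residences when `NULL`.
#' @param iv_rate Current intravenous inflow, mg/h.
#' @param neg_tol Largest tolerated negative state excursion (mg) before
#'   an integrity error is raised.
#' @return Named derivative vector, mg/h.
#' @export
pbpk_rhs <- function(t, state, physiology, dose, location = NULL,
                     iv_rate = 0, neg_tol = 1e-6) {
  p <- physiology
  if (any(state < -neg_tol)) {
    stop_pbpk(sprintf("Negative compartment amount beyond tolerance at t = %g h.", t),
              "pbpk_integrity_error")
  }
  if (is.null(location)) {
    location <- dosage_form_location(t, dose, dosage_form_transit_times(p, start_h = dose$start_h))
  }
  conc <- function(a, v) if (v > 0) a / v else 0
  C_st <- conc(state[["stomach_lumen"]], p[["V_lumen_stomach"]])
  C_si <- conc(state[["si_lumen"]], p[["V_lumen_si"]])
  C_li <- conc(state[["li_lumen"]], p[["V_lumen_li"]])
  C_g <- conc(state[["gics"]], p[["V_gics"]])
  C_l <- conc(state[["liver"]], p[["V_liver"]])
  C_p <- state[["plasma"]] / p[["V_plasma"]]
  C_t <- conc(state[["tissues"]], p[["V_tissues"]])

  r <- 0
  if (dose$route == "oral" && location %in% c("stomach", "si", "li") &&
      t >= dose$start_h) {
    r <- release_rate(dose$release_model, t - dose$start_h)
  }
  r_st <- if (identical(location, "stomach")) r else 0
  r_si <- if (identical(location, "si")) r else 0
  r_li <- if (identical(location, "li")) r else 0

  J_st <- p[["PA_stomach"]] * (C_st - C_g)
  J_si <- p[["PA_si"]] * (C_si - C_g)
  J_li <- p[["PA_li"]] * (C_li - C_g)
  J_tis <- p[["Q_tissues"]] * (C_p - C_t / p[["F_unbound_factor"]])
  met <- p[["CL_hepatic"]] * C_l
  ren <- p[["CL_renal"]] * C_p
  fec <- p[["k_li_transit"]] * state[["li_lumen"]]

  d <- c(
    stomach_lumen = r_st - p[["k_gastric"]] * state[["stomach_lumen"]] - J_st,
    si_lumen = r_si + p[["k_gastric"]] * state[["stomach_lumen"]] -
      p[["k_si_transit"]] * state[["si_lumen"]] - J_si,
    li_lumen = r_li + p[["k_si_transit"]] * state[["si_lumen"]] - fec - J_li,
    gics = J_st + J_si + J_li + p[["Q_gics"]] * C_p - p[["Q_portal"]] * C_g,
    liver = p[["Q_portal"]] * C_g - p[["Q_hepatic_out"]] * C_l - met,
    plasma = p[["Q_hepatic_out"]] * C_l - p[["Q_gics"]] * C_p - J_tis -
      ren + iv_rate,
    tissues = J_tis,
    unreleased = -(r_st + r_si + r_li),
    eliminated_metabolic = met,
    eliminated_renal = ren,
    excreted_fecal = fec,
    undelivered_iv = -iv_rate
  )
  d
}

# Fast positional-index version of pbpk_rhs used inside the integrator.
# Captures all parameters as locals; must stay flux-for-flux identical to
# pbpk_rhs (asserted in the test suite).
make_fast_rhs <- function(physiology, dose, location, iv_rate) {
  p <- unclass(physiology)
  V_st <- p[["V_lumen_stomach"]]; V_si <- p[["V_lumen_si"]]; V_li <- p[["V_lumen_li"]]
  V_g <- p[["V_gics"]]; V_l <- p[["V_liver"]]; V_p <- p[["V_plasma"]]
  V_t <- p[["V_tissues"]]
  kg <- p[["k_gastric"]]; ksi <- p[["k_si_transit"]]; kli <- p[["k_li_transit"]]
  PA_st <- p[["PA_stomach"]]; PA_si <- p[["PA_si"]]; PA_li <- p[["PA_li"]]
  Qg <- p[["Q_gics"]]; Qp <- p[["Q_portal"]]; Qh <- p[["Q_hepatic_out"]]
  Qt <- p[["Q_tissues"]]; CLh <- p[["CL_hepatic"]]; CLr <- p[["CL_renal"]]
  Fu <- p[["F_unbound_factor"]]
  inv <- function(v) if (v > 0) 1 / v else 0
  iV_st <- inv(V_st); iV_si <- inv(V_si); iV_li <- inv(V_li)
  iV_g <- inv(V_g); iV_l <- inv(V_l); iV_t <- inv(V_t)
  releasing <- dose$route == "oral" && location %in% c("stomach", "si", "li")
  rel <- if (releasing) dose$release_model else NULL
  start_h <- dose$start_h
  loc_idx <- switch(location, stomach = 1L, si = 2L, li = 3L, 0L)
  function(t, y, parms) {
    C_st <- y[1] * iV_st; C_si <- y[2] * iV_si; C_li <- y[3] * iV_li
    C_g <- y[4] * iV_g; C_l <- y[5] * iV_l; C_p <- y[6] / V_p
    C_t <- y[7] * iV_t
    r <- if (releasing && t >= start_h) release_rate(rel, t - start_h) else 0
    J_st <- PA_st * (C_st - C_g); J_si <- PA_si * (C_si - C_g)
    J_li <- PA_li * (C_li - C_g)
    J_tis <- Qt * (C_p - C_t / Fu)
    met <- CLh * C_l; ren <- CLr * C_p; fec <- kli * y[3]
    d1 <- (if (loc_idx == 1L) r else 0) - kg * y[1] - J_st
    d2 <- (if (loc_idx == 2L) r else 0) + kg * y[1] - ksi * y[2] - J_si
    d3 <- (if (loc_idx == 3L) r else 0) + ksi * y[2] - fec - J_li
    d4 <- J_st + J_si + J_li + Qg * C_p - Qp * C_g
    d5 <- Qp * C_g - Qh * C_l - met
    d6 <- Qh * C_l - Qg * C_p - J_tis - ren + iv_rate
    d7 <- J_tis
    list(c(d1, d2, d3, d4, d5, d6, d7,
           -r, met, ren, fec, -iv_rate))
  }
}

#' Simulate the PBPK model
#'
#' Integrates the mass balances with a stiff-capable solver
#' (deSolve's lsoda, relative tolerance 1e-8, absolute tolerance
#' 1e-10 mg by default). The integration is split into smooth segments at
#' every derivative discontinuity - dose start, infusion end, and the
#' timed transitions of the intact dosage form between gut segments - so
#' the events cannot degrade solver accuracy.
#'
#' @param physiology A [physiology_spec()].
#' @param dose A [dose_event()].
#' @param t_grid Output times, hours, strictly increasing; must start at
#'   or before the dose start.
#' @param t_form_li_h Large-intestine residence of the intact form, hours.
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `pbpk_trajectory`: one row per output time
#'   with the amount (mg) in every compartment and sink and the
#'   concentration (mg/L) of every compartment; plasma concentration is
#'   `plasma / V_plasma`. The physiology and dose are carried as
#'   attributes.
#' @examples
#' phys <- default_physiology()
#' rel <- release_model("weibull", M_inf = 100, tau = 3, beta = 1.6)
#' traj <- simulate_pbpk(phys, dose_event("oral", 100, release_model = rel),
#'                       t_grid = seq(0, 24, by = 0.5))
#' @export
simulate_pbpk <- function(physiology, dose, t_grid, t_form_li_h = 24,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(physiology, "physiology_spec"),
            inherits(dose, "dose_event"))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0)) {
    stop_pbpk("`t_grid` must be strictly increasing with >= 2 points.",
              "pbpk_data_error")
  }
  if (t_grid[1] > dose$start_h) {
    stop_pbpk("`t_grid` must start at or before the dose start.", "pbpk_data_error")
  }
  t0 <- t_grid[1]
  t_end <- t_grid[length(t_grid)]
  switches <- dosage_form_transit_times(physiology, t_form_li_h = t_form_li_h,
                                        start_h = dose$start_h)
  bounds <- c(t0, t_end, dose$start_h)
  if (dose$route == "iv_infusion") {
    bounds <- c(bounds, dose$start_h + dose$duration_h)
  }
  if (dose$route == "oral") bounds <- c(bounds, unname(switches))
  bounds <- sort(unique(pmin(pmax(bounds, t0), t_end)))

  nm <- pbpk_state_names()
  state <- setNames(numeric(length(nm)), nm)
  rows <- list()
  record <- function(tt, st) rows[[length(rows) + 1L]] <<- c(time_h = tt, st)

  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    # discrete dose events at the segment start
    if (isTRUE(all.equal(a, dose$start_h, tolerance = 1e-12))) {
      if (dose$route == "iv_bolus") state[["plasma"]] <- state[["plasma"]] + dose$amount_mg
      if (dose$route == "oral") state[["unreleased"]] <- state[["unreleased"]] + dose$amount_mg
      if (dose$route == "iv_infusion") {
        state[["undelivered_iv"]] <- state[["undelivered_iv"]] + dose$amount_mg
      }
    }
    tm <- (a + b) / 2
    location <- dosage_form_location(tm, dose, switches)
    iv_rate <- 0
    if (dose$route == "iv_infusion" && tm >= dose$start_h &&
        tm < dose$start_h + dose$duration_h) {
      iv_rate <- dose$amount_mg / dose$duration_h
    }
    times <- sort(unique(c(a, t_grid[t_grid > a & t_grid < b], b)))
    sol <- deSolve::ode(
      y = state, times = times,
      func = make_fast_rhs(physiology, dose, location, iv_rate),
      parms = NULL, method = "lsoda", rtol = rtol, atol = atol,
      maxsteps = 50000
    )
    if (attr(sol, "istate")[1] < 0) {
      stop_pbpk(sprintf("ODE integration failed in segment [%g, %g] h.", a, b),
                "pbpk_solver_error")
    }
    for (j in seq_len(nrow(sol))) {
      tt <- sol[j, 1]
      if (tt %in% t_grid || j == nrow(sol)) record(unname(tt), sol[j, -1])
    }
    state <- sol[nrow(sol), -1]
  }

  df <- tibble::as_tibble(do.call(rbind, rows))
  # duplicated times at segment boundaries: keep the latest (post-event) row
  df <- df[!duplicated(df$time_h, fromLast = TRUE), ]
  df <- df[df$time_h %in% t_grid, ]
  vols <- c(stomach_lumen = physiology[["V_lumen_stomach"]],
            si_lumen = physiology[["V_lumen_si"]],
            li_lumen = physiology[["V_lumen_li"]],
            gics = physiology[["V_gics"]], liver = physiology[["V_liver"]],
            plasma = physiology[["V_plasma"]], tissues = physiology[["V_tissues"]])
  for (comp in pbpk_compartments) {
    df[[paste0("conc_", comp)]] <-
      if (vols[[comp]] > 0) df[[comp]] / vols[[comp]] else NA_real_
  }
  attr(df, "physiology") <- physiology
  attr(df, "dose") <- dose
  attr(df, "t_form_li_h") <- t_form_li_h
  class(df) <- c("pbpk_trajectory", class(df))
  df
}

#' Total drug accounted for at each trajectory time
#'
#' Sums compartments, the unreleased reservoir and all cumulative sinks;
#' equals the administered dose at every time after administration (the
#' model's primary correctness property).
#'
#' @param traj A `pbpk_trajectory`.
#' @return Numeric vector, mg.
#' @export
mass_in_system <- function(traj) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  rowSums(as.data.frame(traj)[, pbpk_state_names()])
}
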