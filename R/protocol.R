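#' pH program for the simulated dissolution vessel
#'
#' A setpoint schedule for the feedback-controlled vessel: breakpoints of
#' (time, pH) interpolated either stepwise or linearly.
#'
#' @param time_h Breakpoint times, hours, non-decreasing, starting at 0.
#' @param pH Setpoints, each in (0, 14).
#' @param interpolation `"linear"` or `"step"`.
#' @return A tibble of class `ph_program`.
#' @export
ph_program <- function(time_h, pH, interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  if (length(time_h) != length(pH) || length(time_h) < 1L) {
    stop_pbpk("Need matching non-empty time/pH breakpoints.", "pbpk_data_error")
  }
  if (any(diff(time_h) < 0)) {
    stop_pbpk("Breakpoint times must be non-decreasing.", "pbpk_data_error")
  }
  if (any(pH <= 0) || any(pH >= 14)) {
    stop_pbpk("Setpoints must lie strictly between 0 and 14.", "pbpk_data_error")
  }
  out <- tibble::tibble(time_h = as.numeric(time_h), pH = as.numeric(pH))
  attr(out, "interpolation") <- interpolation
  class(out) <- c("ph_program", class(out))
  out
}

#' Setpoint of a pH program at time t
#' @param program A [ph_program()].
#' @param t Time(s), hours.
#' @return pH setpoint(s).
#' @export
setpoint_at <- function(program, t) {
  stopifnot(inherits(program, "ph_program"))
  method <- if (attr(program, "interpolation") == "step") "constant" else "linear"
  stats::approx(program$time_h, program$pH, xout = t, method = method,
                rule = 2, ties = "ordered")$y
}

#' The synthetic fed-stomach pH program
#'
#' A parameterized stand-in for a postprandial gastric pH history: the pH
#' starts near 4.8 right after a meal, declines slowly (barely reaching 2
#' within two hours as re-acidification proceeds), then rises toward the
#' intestinal setpoint of 6.8 at the gastric-emptying time. This fixture
#' is synthetic - it emulates the shape of published in-vivo recordings,
#' not any specific subject.
#'
#' @param t_empty_h Gastric-emptying time, hours.
#' @param duration_h Total program duration, hours.
#' @return A [ph_program()].
#' @export
fed_stomach_program <- function(t_empty_h = 2, duration_h = 4) {
  ph_program(
    time_h = c(0, 0.25 * t_empty_h, 0.5 * t_empty_h, 0.75 * t_empty_h,
               t_empty_h, t_empty_h + 0.1, duration_h),
    pH = c(4.8, 4.3, 3.5, 2.6, 2.0, 6.8, 6.8),
    interpolation = "linear"
  )
}

#' Tablet model for protocol simulations
#'
#' Couples a parametric release model to the vessel chemistry through an
#' optional pH gate: an enteric-coated tablet releases only while the
#' medium pH is at or above `ph_threshold`, and the release clock only
#' advances during those periods (the coat is treated as intact below the
#' threshold). `ph_threshold = NULL` gives pH-independent release.
#'
#' @param release A [release_model()].
#' @param ph_threshold Optional pH below which no release occurs.
#' @return An object of class `tablet`.
#' @export
tablet <- function(release, ph_threshold = NULL) {
  stopifnot(inherits(release, "release_model"))
  if (!is.null(ph_threshold)) {
    assert_scalar_number(ph_threshold, "ph_threshold", lower = 0, upper = 14)
  }
  structure(list(release = release, ph_threshold = ph_threshold),
            class = "tablet")
}

tablet_active <- function(tab, pH) {
  is.null(tab$ph_threshold) || pH >= tab$ph_threshold
}

#' Solution buffer titrated to a target pH
#'
#' Builds a phosphate medium whose Davies-mode pH equals the target, by
#' solving for the net strong-base content mixed with a dilute
#' dihydrogen-phosphate solution. The default emulates the 500 mL fed-state
#' starting medium of the pH-programmed test (initial pH 4.8); its exact
#' composition is an assumption (a dilute phosphate buffer), since only
#' the pH of the physical medium is specified by the protocol.
#'
#' @param target_pH Target pH.
#' @param volume_L Volume, liters.
#' @param phosphate_M Total phosphate, mol/L.
#' @param mode pH convention.
#' @return A [medium()].
#' @export
make_buffer_at_ph <- function(target_pH, volume_L = 0.5, phosphate_M = 0.05,
                              mode = "davies") {
  f <- function(b) {
    m <- medium(volume_L, NaH2PO4 = phosphate_M,
                NaOH = max(b, 0), HCl = max(-b, 0))
    compute_ph(m, mode)$pH - target_pH
  }
  r <- uniroot(f, lower = -2 * phosphate_M - 0.01, upper = 3 * phosphate_M + 0.01,
               tol = 1e-12)
  b <- r$root
  medium(volume_L, NaH2PO4 = phosphate_M, NaOH = max(b, 0), HCl = max(-b, 0))
}

new_protocol_run <- function(df, tab, vessel_final) {
  attr(df, "tablet") <- tab
  attr(df, "vessel_final") <- vessel_final
  class(df) <- c("protocol_run", class(df))
  df
}

# advance the pH-gated release clock and return released mass over a step
step_release <- function(tab, clock, pH, dt) {
  if (is.null(tab)) return(list(clock = clock, released = NA_real_))
  if (tablet_active(tab, pH)) clock <- clock + dt
  list(clock = clock, released = evaluate_cumulative(tab$release, clock))
}

#' Simulate the USP two-stage enteric test (Method A)
#'
#' Stage 1 (acid stage): the dosage form sits for two hours in 750 mL of
#' 0.1 M HCl - nominal pH 1.0 (ideal convention). Stage transition: 250 mL
#' of 0.2 M tribasic sodium phosphate is added, raising the pH to 6.8
#' (Davies convention, reflecting a measured value at buffer ionic
#' strength). Stage 2 (buffer stage) runs for `duration_buffer_h`.
#' Release accrues per stage through the tablet's pH gate.
#'
#' @param tab A [tablet()], or `NULL` to run the protocol without release
#'   accounting.
#' @param duration_buffer_h Buffer-stage duration, hours.
#' @param dt_h Reporting interval, hours.
#' @param duration_acid_h Acid-stage duration, hours (the pharmacopoeial
#'   test uses 2).
#' @return A tibble of class `protocol_run`: `time_h`, `pH`, `stage`,
#'   `volume_L`, `acid_added_L`, `base_added_L`, `released_mg`.
#' @export
run_usp_method_a <- function(tab = NULL, duration_buffer_h = 8, dt_h = 0.05,
                             duration_acid_h = 2) {
  acid <- medium(0.750, HCl = 0.1)
  ph_acid <- compute_ph(acid, mode = "ideal")$pH
  buffer <- mix_media(acid, medium(0.250, Na3PO4 = 0.2))
  ph_buffer <- compute_ph(buffer, mode = "davies")$pH

  t1 <- seq(0, duration_acid_h, by = dt_h)
  t2 <- seq(duration_acid_h, duration_acid_h + duration_buffer_h, by = dt_h)[-1]
  times <- c(t1, t2)
  stage <- c(rep("acid_stage", length(t1)), rep("buffer_stage", length(t2)))
  pH <- c(rep(ph_acid, length(t1)), rep(ph_buffer, length(t2)))
  volume <- c(rep(acid$volume_L, length(t1)), rep(buffer$volume_L, length(t2)))

  released <- rep(NA_real_, length(times))
  clock <- 0
  if (!is.null(tab)) {
    stopifnot(inherits(tab, "tablet"))
    released[1] <- if (tablet_active(tab, pH[1])) evaluate_cumulative(tab$release, 0) else 0
    for (i in 2:length(times)) {
      st <- step_release(tab, clock, pH[i], times[i] - times[i - 1])
      clock <- st$clock
      released[i] <- st$released
    }
  }
  df <- tibble::tibble(
    time_h = times, pH = pH, stage = stage, volume_L = volume,
    acid_added_L = 0, base_added_L = 0, released_mg = released
  )
  new_protocol_run(df, tab, buffer)
}

#' PI controller settings for the pH-programmed vessel
#'
#' Discrete proportional-integral control of the dosing pumps: every
#' `dt_s` seconds the vessel pH is computed (Davies mode), the error
#' against the program setpoint is formed, and a volume of 2 M titrant -
#' base for positive error, acid for negative - is dosed, clipped to the
#' pump capacity. Integral action is frozen while the pump saturates
#' (anti-windup). Defaults are tuned so a 4.8 -> 6.8 setpoint step in the
#' standard 500 mL buffer settles within a few control intervals.
#'
#' @param kp Proportional gain, liters of titrant per pH unit.
#' @param ki Integral gain, liters per (pH unit * hour).
#' @param dt_s Control interval, seconds.
#' @param pump_max_L_per_h Pump capacity, liters/hour.
#' @param titrant_M Titrant concentration, mol/L (2 M HCl / 2 M NaOH).
#' @param saturation_warn_fraction Fraction of saturated intervals above
#'   which the run is flagged as an unreachable program.
#' @return A list of class `ph_controller`.
#' @export
ph_controller <- function(kp = 3e-4, ki = 1e-2, dt_s = 30,
                          pump_max_L_per_h = 0.12, titrant_M = 2,
                          saturation_warn_fraction = 0.5) {
  structure(list(kp = kp, ki = ki, dt_s = dt_s,
                 pump_max_L_per_h = pump_max_L_per_h, titrant_M = titrant_M,
                 saturation_warn_fraction = saturation_warn_fraction),
            class = "ph_controller")
}

#' Simulate the pH-programmed dissolution test
#'
#' Discrete-time simulation of the feedback-controlled vessel: at each
#' control interval the pH is measured (computed from the full charge
#' balance, Davies mode), the PI controller doses 2 M HCl or 2 M NaOH
#' through the simulated pumps, the vessel is re-mixed (volume and moles
#' exactly conserved), and tablet release advances through its pH gate.
#'
#' @param program A [ph_program()].
#' @param tab Optional [tablet()].
#' @param controller A [ph_controller()].
#' @param initial_medium Starting vessel content; default is the 500 mL
#'   fed-state buffer at pH 4.8 from [make_buffer_at_ph()].
#' @param duration_h Run length, hours; defaults to the last program
#'   breakpoint.
#' @return A `protocol_run` tibble (`time_h`, `pH`, `setpoint`, `stage`,
#'   `volume_L`, `acid_added_L`, `base_added_L`, `released_mg`) with
#'   attributes `saturation_fraction` and `unreachable` (flag set when
#'   the pumps saturated for more than the configured fraction of the
#'   run).
#' @export
run_ph_program <- function(program, tab = NULL, controller = ph_controller(),
                           initial_medium = NULL, duration_h = NULL) {
  stopifnot(inherits(program, "ph_program"))
  if (!is.null(tab)) stopifnot(inherits(tab, "tablet"))
  vessel <- initial_medium %||% make_buffer_at_ph(4.8)
  duration_h <- duration_h %||% max(program$time_h)
  dt <- controller$dt_s / 3600
  n <- ceiling(duration_h / dt) + 1L
  times <- (seq_len(n) - 1L) * dt

  reg <- vessel$registry
  acid_stock <- medium(1, HCl = controller$titrant_M, registry = reg)
  base_stock <- medium(1, NaOH = controller$titrant_M, registry = reg)
  v_int_max <- controller$pump_max_L_per_h * dt

  pH <- numeric(n); sp <- numeric(n)
  acid_cum <- numeric(n); base_cum <- numeric(n); vol <- numeric(n)
  released <- rep(NA_real_, n)
  integral <- 0
  prev_err <- 0
  clock <- 0
  saturated <- 0L

  for (i in seq_len(n)) {
    t <- times[i]
    pH[i] <- compute_ph(vessel, mode = "davies")$pH
    sp[i] <- setpoint_at(program, t)
    vol[i] <- vessel$volume_L
    if (!is.null(tab)) {
      if (i == 1L) {
        released[i] <- if (tablet_active(tab, pH[i])) evaluate_cumulative(tab$release, 0) else 0
      } else {
        st <- step_release(tab, clock, pH[i], dt)
        clock <- st$clock
        released[i] <- st$released
      }
    }
    if (i == n) {
      if (i > 1L) { acid_cum[i] <- acid_cum[i - 1L]; base_cum[i] <- base_cum[i - 1L] }
      break
    }
    err <- sp[i] - pH[i]
    # integrator reset on zero crossing: once the pH passes the setpoint the
    # accumulated history argues for the wrong direction, so drop it
    if (i > 1L && sign(err) != 0 && sign(err) != sign(prev_err) &&
        prev_err != 0) {
      integral <- 0
    }
    prev_err <- err
    u <- controller$kp * err + controller$ki * integral
    v_dose <- min(abs(u), v_int_max)
    if (v_dose >= v_int_max - 1e-15) saturated <- saturated + 1L
    else integral <- integral + err * dt  # anti-windup: freeze while saturated
    prev_acid <- if (i > 1L) acid_cum[i - 1L] else 0
    prev_base <- if (i > 1L) base_cum[i - 1L] else 0
    if (v_dose > 0) {
      stock <- if (u > 0) base_stock else acid_stock
      shot <- stock
      shot$volume_L <- v_dose
      vessel <- mix_media(vessel, shot)
    }
    acid_cum[i] <- prev_acid + if (v_dose > 0 && u < 0) v_dose else 0
    base_cum[i] <- prev_base + if (v_dose > 0 && u > 0) v_dose else 0
  }

  sat_frac <- saturated / (n - 1L)
  unreachable <- sat_frac > controller$saturation_warn_fraction
  if (unreachable) {
    rlang::warn("Pump saturated for most of the run: pH program may be unreachable.",
                class = "pbpk_unreachable_program_warning")
  }
  df <- tibble::tibble(
    time_h = times, pH = pH, setpoint = sp, stage = "program",
    volume_L = vol, acid_added_L = acid_cum, base_added_L = base_cum,
    released_mg = released
  )
  out <- new_protocol_run(df, tab, vessel)
  attr(out, "saturation_fraction") <- sat_frac
  attr(out, "unreachable") <- unreachable
  out
}

#' Compare drug release between two protocol runs
#'
#' Tabulates released mass per stage and the time to 80% release for each
#' protocol - the quantitative form of the comparison between the
#' pharmacopoeial two-stage test and a physiological pH program. Both
#' runs must carry release accounting for tablets of equal drug content.
#'
#' @param a,b `protocol_run` objects with tablets.
#' @param labels Length-2 character labels for the two protocols.
#' @return A tibble with one row per protocol x stage: `protocol`,
#'   `stage`, `released_mg` (mass released during that stage),
#'   `t80_h` (time to 80% of the releasable content, `NA` if not
#'   reached).
#' @export
compare_release <- function(a, b, labels = c("protocol_a", "protocol_b")) {
  stopifnot(inherits(a, "protocol_run"), inherits(b, "protocol_run"))
  ta <- attr(a, "tablet"); tb <- attr(b, "tablet")
  if (is.null(ta) || is.null(tb)) {
    stop_pbpk("Both runs must carry release accounting (a tablet).", "pbpk_data_error")
  }
  if (abs(ta$release$M_inf - tb$release$M_inf) > 1e-9 * ta$release$M_inf) {
    stop_pbpk("Mismatched drug content between the two runs.", "pbpk_data_error")
  }
  one <- function(run, lab) {
    m_inf <- attr(run, "tablet")$release$M_inf
    idx80 <- which(run$released_mg >= 0.8 * m_inf)[1]
    t80 <- if (is.na(idx80)) NA_real_ else run$time_h[idx80]
    r <- rle(run$stage)
    ends <- cumsum(r$lengths)
    baseline <- c(run$released_mg[1], run$released_mg[ends[-length(ends)]])
    tibble::tibble(
      protocol = lab, stage = r$values,
      released_mg = run$released_mg[ends] - baseline,
      t80_h = t80
    )
  }
  dplyr::bind_rows(one(a, labels[1]), one(b, labels[2]))
}
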