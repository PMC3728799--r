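#' Names of the seven PBPK compartments
#'
#' The body is represented by seven perfectly mixed compartments (the CSTR
#' assumption): the three gastrointestinal lumens (stomach, small
#' intestine, large intestine), the gastrointestinal circulatory system
#' ("gics", the splanchnic blood draining the gut wall), the liver, the
#' plasma (blood plus richly perfused organs) and the scarcely perfused
#' tissues. One mass-balance ODE per compartment.
#'
#' @export
pbpk_compartments <- c("stomach_lumen", "si_lumen", "li_lumen",
                       "gics", "liver", "plasma", "tissues")

# bookkeeping states integrated alongside the 7 compartments so the mass
# balance closes exactly
pbpk_sinks <- c("unreleased", "eliminated_metabolic", "eliminated_renal",
                "excreted_fecal", "undelivered_iv")

#' Names of the 22 physiological/drug parameters
#'
#' @format Character vector of length 22.
#' @export
physiology_parameter_names <- c(
  "V_gics", "V_liver", "V_plasma", "V_tissues",
  "V_lumen_stomach", "V_lumen_si", "V_lumen_li",
  "Q_gics", "Q_portal", "Q_hepatic_out", "Q_tissues",
  "k_gastric", "k_si_transit", "k_li_transit",
  "PA_stomach", "PA_si", "PA_li",
  "CL_hepatic", "CL_renal",
  "F_unbound_factor",
  "t_form_gastric", "t_form_si"
)

#' Physiology and drug parameter set
#'
#' The 22 scalar parameters the seven-compartment model needs. Units are
#' fixed throughout the package: volumes in L, flows/permeability-area
#' products/clearances in L/h, rate constants in 1/h, times in h,
#' concentrations in mg/L.
#'
#' * `V_gics`, `V_liver`, `V_plasma`, `V_tissues`: distribution volumes of
#'   the perfused compartments.
#' * `V_lumen_stomach`, `V_lumen_si`, `V_lumen_li`: lumen fluid volumes.
#' * `Q_gics`: plasma -> gut-wall circulation perfusion flow; `Q_portal`:
#'   gut circulation -> liver (portal) flow; `Q_hepatic_out`: liver ->
#'   plasma flow. Constant compartment volumes require
#'   `Q_gics = Q_portal = Q_hepatic_out` (inflow = outflow), checked at
#'   construction.
#' * `Q_tissues`: plasma <-> tissues exchange flow.
#' * `k_gastric`, `k_si_transit`, `k_li_transit`: first-order emptying
#'   rate constants moving *dissolved* drug down the lumen chain (the
#'   large-intestine outflow is fecal excretion).
#' * `PA_stomach`, `PA_si`, `PA_li`: permeability-area products for
#'   passive diffusion across the gut wall (lumen <-> gut circulation).
#' * `CL_hepatic`: first-order metabolic clearance in the liver;
#'   `CL_renal`: first-order elimination clearance from plasma.
#' * `F_unbound_factor`: lumped tissue partition/binding factor; at
#'   distribution equilibrium `C_tissues = F_unbound_factor * C_plasma`.
#' * `t_form_gastric`, `t_form_si`: residence times of the *intact dosage
#'   form* in stomach and small intestine (see
#'   [dosage_form_transit_times()]); dissolved drug always moves by the
#'   first-order `k`'s, the monolithic tablet moves at these fixed times.
#'
#' @param ... Exactly the 22 named scalars listed in
#'   [physiology_parameter_names], all >= 0, `V_plasma > 0`.
#' @return A named numeric vector of class `physiology_spec`.
#' @seealso [default_physiology()] for a realistic complete set.
#' @export
physiology_spec <- function(...) {
  p <- c(...)
  if (!is_named_numeric(p)) {
    stop_pbpk("Physiology parameters must be named numbers.", "pbpk_data_error")
  }
  missing <- setdiff(physiology_parameter_names, names(p))
  extra <- setdiff(names(p), physiology_parameter_names)
  if (length(missing) || length(extra)) {
    msg <- c(
      if (length(missing)) paste0("missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("unknown: ", paste(extra, collapse = ", "))
    )
    stop_pbpk(paste0("Physiology must contain exactly the 22 named parameters (",
                     paste(msg, collapse = "; "), ")."), "pbpk_data_error")
  }
  p <- p[physiology_parameter_names]
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_pbpk("All physiology parameters must be finite and >= 0.", "pbpk_data_error")
  }
  if (p[["V_plasma"]] <= 0) {
    stop_pbpk("V_plasma must be > 0.", "pbpk_data_error")
  }
  if (abs(p[["Q_portal"]] - p[["Q_gics"]]) > 1e-9 * max(1, p[["Q_gics"]]) ||
      abs(p[["Q_hepatic_out"]] - p[["Q_portal"]]) > 1e-9 * max(1, p[["Q_portal"]])) {
    stop_pbpk(paste0("Flow balance violated: constant gics/liver volumes need ",
                     "Q_gics = Q_portal = Q_hepatic_out."), "pbpk_data_error")
  }
  structure(p, class = "physiology_spec")
}

#' @export
print.physiology_spec <- function(x, ...) {
  cat("<physiology_spec> 22 parameters (L, L/h, 1/h, h)\n")
  print(unclass(x))
  invisible(x)
}

#' Default synthetic physiology
#'
#' A complete, realistic adult parameter set used as the ground truth of
#' the synthetic study and as the template for calibration examples. The
#' drug disposition side (high hepatic clearance, moderate renal
#' clearance, tissue partition ~3) emulates a well-absorbed,
#' high-first-pass oral drug such as a calcium-channel blocker.
#'
#' @return A [physiology_spec()].
#' @export
default_physiology <- function() {
  physiology_spec(
    V_gics = 1.0, V_liver = 1.8, V_plasma = 10, V_tissues = 35,
    V_lumen_stomach = 0.25, V_lumen_si = 0.4, V_lumen_li = 0.3,
    Q_gics = 60, Q_portal = 60, Q_hepatic_out = 60, Q_tissues = 20,
    k_gastric = 2.8, k_si_transit = 0.25, k_li_transit = 0.05,
    PA_stomach = 0.02, PA_si = 2.5, PA_li = 0.3,
    CL_hepatic = 40, CL_renal = 2,
    F_unbound_factor = 3,
    t_form_gastric = 2, t_form_si = 3
  )
}

#' Dosing event
#'
#' Route decides which inlet of the model is active: an intravenous dose
#' enters the plasma compartment directly; an oral dose enters whichever
#' lumen the intact dosage form currently resides in, at the rate given by
#' its release model.
#'
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"oral"`.
#' @param amount_mg Dose, mg (> 0).
#' @param start_h Administration time, hours.
#' @param duration_h Infusion duration, hours (`iv_infusion` only).
#' @param release_model A [release_model()] (`oral` only); its `M_inf`
#'   may not exceed the dose.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(route, amount_mg, start_h = 0, duration_h = NULL,
                       release_model = NULL) {
  route <- match.arg(route, c("iv_bolus", "iv_infusion", "oral"))
  assert_scalar_number(amount_mg, "amount_mg", lower = 0, strict_lower = TRUE)
  assert_scalar_number(start_h, "start_h")
  if (route == "iv_infusion") {
    if (is.null(duration_h)) stop_pbpk("Infusion needs `duration_h`.", "pbpk_data_error")
    assert_scalar_number(duration_h, "duration_h", lower = 0, strict_lower = TRUE)
  }
  if (route == "oral") {
    if (!inherits(release_model, "release_model")) {
      stop_pbpk("Oral dose needs a release_model.", "pbpk_data_error")
    }
    if (release_model$M_inf > amount_mg * (1 + 1e-9)) {
      stop_pbpk("Release model M_inf exceeds the administered amount.",
                "pbpk_data_error")
    }
  }
  structure(
    list(route = route, amount_mg = amount_mg, start_h = start_h,
         duration_h = duration_h, release_model = release_model),
    class = "dose_event"
  )
}

#' Transit times of the intact dosage form
#'
#' A monolithic tablet does not move like dissolved lumen contents: it is
#' carried between gut segments at discrete times (timed-window mode).
#' From ingestion it sits in the stomach for `t_form_gastric` hours
#' (default 2 h, the gastric-emptying window of the two-stage enteric
#' protocol), then in the small intestine for `t_form_si` hours (default
#' 3 h), then in the large intestine for `t_form_li_h` hours (default
#' 24 h) before exiting. Only the intact form follows these windows;
#' dissolved drug always moves by the first-order transit constants.
#'
#' @param physiology A [physiology_spec()].
#' @param t_form_li_h Large-intestine residence of the form, hours.
#' @param start_h Ingestion time, hours.
#' @return Named numeric: absolute switch times `t_gastric_empty`,
#'   `t_si_empty`, `t_li_empty` (hours). With the defaults: 2, 5, 29 h.
#' @export
dosage_form_transit_times <- function(physiology, t_form_li_h = 24,
                                      start_h = 0) {
  stopifnot(inherits(physiology, "physiology_spec"))
  t1 <- start_h + physiology[["t_form_gastric"]]
  t2 <- t1 + physiology[["t_form_si"]]
  t3 <- t2 + t_form_li_h
  c(t_gastric_empty = t1, t_si_empty = t2, t_li_empty = t3)
}

# Where the intact form is at time t (vectorized over nothing; scalar t)
dosage_form_location <- function(t, dose, switches) {
  if (dose$route != "oral" || t < dose$start_h) return("none")
  if (t < switches[["t_gastric_empty"]]) "stomach"
  else if (t < switches[["t_si_empty"]]) "si"
  else if (t < switches[["t_li_empty"]]) "li"
  else "exited"
}
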