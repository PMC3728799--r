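#' In-vivo plasma concentration dataset
#'
#' Observed plasma concentrations for one formulation, together with the
#' dose event that produced them (route, amount and - for oral dosing -
#' the fitted in-vitro release model, which is how the in-vitro
#' information enters the in-vivo prediction).
#'
#' @param time_h Sampling times, hours, strictly increasing; >= 5 points
#'   are required for calibration use.
#' @param conc_mg_per_L Concentrations, mg/L, >= 0.
#' @param dose A [dose_event()].
#' @param label Formulation label.
#' @return A tibble of class `plasma_dataset`.
#' @export
plasma_dataset <- function(time_h, conc_mg_per_L, dose, label = "dataset") {
  stopifnot(inherits(dose, "dose_event"))
  if (length(time_h) != length(conc_mg_per_L)) {
    stop_pbpk("Times and concentrations must have equal length.", "pbpk_data_error")
  }
  if (any(diff(time_h) <= 0)) {
    stop_pbpk("Plasma sampling times must be strictly increasing.", "pbpk_data_error")
  }
  if (any(!is.finite(conc_mg_per_L)) || any(conc_mg_per_L < 0)) {
    stop_pbpk("Concentrations must be finite and >= 0.", "pbpk_data_error")
  }
  out <- tibble::tibble(time_h = as.numeric(time_h),
                        conc_mg_per_L = as.numeric(conc_mg_per_L))
  attr(out, "dose") <- dose
  attr(out, "label") <- label
  class(out) <- c("plasma_dataset", class(out))
  out
}

# parameters that may never be freed individually: they are tied to Q_gics
# by the flow-balance constraint of the constant-volume compartments
flow_balance_derived <- c("Q_portal", "Q_hepatic_out")

# build a physiology_spec from a template and a named vector of overrides,
# propagating the flow-balance constraint when Q_gics moves
physiology_with <- function(template, values) {
  p <- unclass(template)
  p[names(values)] <- values
  if ("Q_gics" %in% names(values)) {
    p[["Q_portal"]] <- p[["Q_gics"]]
    p[["Q_hepatic_out"]] <- p[["Q_gics"]]
  }
  physiology_spec(p)
}

calibration_fingerprint <- function(fitted, fixed) {
  paste(signif(c(fitted, fixed), 15), collapse = "|")
}

#' Calibrate the PBPK model against one plasma dataset
#'
#' Bounded weighted least squares of the simulated plasma curve against
#' the observations: the objective is `sum(w_i * (C_model(t_i) -
#' C_obs(t_i))^2)` with relative weights `w_i = 1 / max(C_obs_i, floor)^2`
#' and `floor` equal to 1% of the observed Cmax, so that a plasma curve
#' spanning an order of magnitude is fitted evenly on the relative scale
#' without division blow-ups near zero.
#'
#' Optimization is a deterministic multi-start Levenberg-Marquardt in
#' log-parameter space: 5 log-spaced candidate starts per free dimension
#' (full factorial, thinned evenly to at most 32), every candidate
#' screened by its initial objective, and the most promising refined to
#' convergence; the best refined fit wins. No randomness is involved.
#'
#' Only parameters that can move independently may be freed: `Q_portal`
#' and `Q_hepatic_out` are derived from `Q_gics` by the flow balance, so
#' free `Q_gics` to move the perfusion loop.
#'
#' @param dataset A [plasma_dataset()] (>= 5 points).
#' @param physiology_template A [physiology_spec()] supplying every fixed
#'   parameter and the centre of each free parameter's search range.
#' @param free Names of the parameters to fit (non-empty subset of
#'   [physiology_parameter_names]). Default: the four
#'   absorption/disposition parameters least constrained by physiology.
#' @param bound_factor Multiplicative half-width of each free parameter's
#'   box: bounds are `template/bound_factor` to `template*bound_factor`.
#' @param n_refine How many screened starts are polished to convergence.
#' @param t_form_li_h,rtol,atol Passed to [simulate_pbpk()].
#' @return An object of class `pbpk_calibration`: list with `fitted`
#'   (tibble of name/value/lower/upper), `fixed` (named vector of the
#'   remaining parameters), `physiology` (the calibrated
#'   [physiology_spec()]), `objective`, `convergence` (iterations,
#'   termination message, starts screened/refined) and the calibration
#'   dataset.
#' @export
calibrate_pbpk <- function(dataset, physiology_template,
                           free = c("PA_si", "CL_hepatic", "Q_tissues",
                                    "F_unbound_factor"),
                           bound_factor = 10, n_refine = 8,
                           t_form_li_h = 24, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(dataset, "plasma_dataset"),
            inherits(physiology_template, "physiology_spec"))
  if (nrow(dataset) < 5L) {
    stop_pbpk("Calibration needs at least 5 plasma points.", "pbpk_data_error")
  }
  if (length(free) < 1L) stop_pbpk("Free parameter set is empty.", "pbpk_data_error")
  bad <- setdiff(free, physiology_parameter_names)
  if (length(bad)) {
    stop_pbpk(paste0("Unknown free parameter(s): ", paste(bad, collapse = ", ")),
              "pbpk_data_error")
  }
  tied <- intersect(free, flow_balance_derived)
  if (length(tied)) {
    stop_pbpk(paste0(paste(tied, collapse = ", "),
                     " are derived from Q_gics by the flow balance; free Q_gics instead."),
              "pbpk_data_error")
  }
  if (length(free) >= nrow(dataset)) {
    stop_pbpk("More free parameters than data points: not identifiable.",
              "pbpk_identifiability_error")
  }
  dose <- attr(dataset, "dose")
  obs <- dataset$conc_mg_per_L
  floor_c <- 0.01 * max(obs)
  if (floor_c <= 0) stop_pbpk("All observations are zero.", "pbpk_data_error")
  w <- 1 / pmax(obs, floor_c)

  centre <- unclass(physiology_template)[free]
  if (any(centre <= 0)) {
    stop_pbpk("Template values of free parameters must be > 0.", "pbpk_data_error")
  }
  lower <- centre / bound_factor
  upper <- centre * bound_factor

  t_grid <- sort(unique(c(min(dataset$time_h, dose$start_h), dataset$time_h)))
  sim_conc <- function(theta_log) {
    vals <- setNames(exp(theta_log), free)
    phys <- physiology_with(physiology_template, vals)
    traj <- simulate_pbpk(phys, dose, t_grid, t_form_li_h = t_form_li_h,
                          rtol = rtol, atol = atol)
    traj$conc_plasma[match(dataset$time_h, traj$time_h)]
  }
  resid_fn <- function(theta_log) {
    cm <- tryCatch(sim_conc(theta_log), error = function(e) NULL)
    if (is.null(cm) || any(!is.finite(cm))) return(rep(1e6, length(obs)))
    w * (cm - obs)
  }

  # deterministic multi-start grid in log space
  axes <- purrr::map2(lower, upper, function(lo, hi) {
    log(exp(seq(log(lo), log(hi), length.out = 5)))
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  if (nrow(grid) > 32L) {
    grid <- grid[round(seq(1, nrow(grid), length.out = 32L)), , drop = FALSE]
  }
  scr <- apply(grid, 1L, function(th) sum(resid_fn(th)^2))
  ord <- order(scr)
  n_refine <- min(n_refine, nrow(grid))

  best <- NULL
  for (i in ord[seq_len(n_refine)]) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = grid[i, ], lower = log(lower), upper = log(upper),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 120, ftol = 1e-12,
                                             ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop_pbpk("Calibration did not converge from any start.",
              "pbpk_convergence_error")
  }
  fitted_vals <- setNames(exp(best$fit$par), free)
  phys <- physiology_with(physiology_template, fitted_vals)
  fixed <- unclass(phys)[setdiff(physiology_parameter_names, free)]
  fitted_tbl <- tibble::tibble(parameter = free, value = unname(fitted_vals),
                               lower = unname(lower), upper = unname(upper))
  out <- structure(
    list(
      fitted = fitted_tbl,
      fixed = fixed,
      physiology = phys,
      objective = best$rss,
      convergence = list(iterations = best$fit$niter,
                         message = best$fit$message,
                         starts_screened = nrow(grid),
                         starts_refined = n_refine),
      dataset = dataset,
      t_form_li_h = t_form_li_h,
      rtol = rtol, atol = atol
    ),
    class = "pbpk_calibration"
  )
  out$fingerprint <- calibration_fingerprint(fitted_vals, fixed)
  out
}

#' @export
print.pbpk_calibration <- function(x, ...) {
  cat(sprintf("<pbpk_calibration> %d free parameter(s), objective %.4g\n",
              nrow(x$fitted), x$objective))
  print(x$fitted)
  invisible(x)
}

#' Predict a new formulation with frozen calibrated parameters
#'
#' The point of the workflow: once the model is calibrated on one
#' formulation, any other formulation of the same drug is simulated with
#' *no further optimization* - only the dose event (and through it the
#' in-vitro release model) changes. The calibrated parameter set is
#' fingerprinted at calibration time and re-verified here: any mutation
#' between calibrate and predict is rejected.
#'
#' @param calibration A [calibrate_pbpk()] result.
#' @param new_dose A [dose_event()] for the formulation to predict.
#' @param t_grid Output times, hours.
#' @param observed Optional [plasma_dataset()]; when supplied the percent
#'   prediction errors of Cmax and AUC (predicted vs observed NCA) are
#'   reported.
#' @param extrapolate_auc Use AUC to infinity for the prediction-error
#'   comparison (default uses AUC to the last common time).
#' @return A list of class `pbpk_prediction`: `trajectory`
#'   (a `pbpk_trajectory`), `metrics` (a `pk_metrics` tibble with
#'   prediction-error columns when `observed` is given).
#' @export
predict_formulation <- function(calibration, new_dose, t_grid,
                                observed = NULL, extrapolate_auc = FALSE) {
  stopifnot(inherits(calibration, "pbpk_calibration"),
            inherits(new_dose, "dose_event"))
  fitted_vals <- setNames(calibration$fitted$value, calibration$fitted$parameter)
  fp <- calibration_fingerprint(fitted_vals, calibration$fixed)
  if (!identical(fp, calibration$fingerprint) ||
      !identical(unname(unclass(calibration$physiology)[calibration$fitted$parameter]),
                 unname(fitted_vals))) {
    stop_pbpk("Calibrated parameters were modified after calibration: prediction refused.",
              "pbpk_frozen_parameter_error")
  }
  traj <- simulate_pbpk(calibration$physiology, new_dose, t_grid,
                        t_form_li_h = calibration$t_form_li_h,
                        rtol = calibration$rtol, atol = calibration$atol)
  metrics <- nca_metrics(traj$time_h, traj$conc_plasma,
                         extrapolate = extrapolate_auc)
  if (!is.null(observed)) {
    stopifnot(inherits(observed, "plasma_dataset"))
    obs_metrics <- nca_metrics(observed$time_h, observed$conc_mg_per_L,
                               extrapolate = extrapolate_auc)
    auc_col <- if (extrapolate_auc) "AUC_0_inf" else "AUC_0_last"
    metrics$prediction_error_Cmax <-
      100 * (metrics$Cmax - obs_metrics$Cmax) / obs_metrics$Cmax
    metrics$prediction_error_AUC <-
      100 * (metrics[[auc_col]] - obs_metrics[[auc_col]]) / obs_metrics[[auc_col]]
    attr(metrics, "observed_metrics") <- obs_metrics
  }
  structure(list(trajectory = traj, metrics = metrics, dose = new_dose),
            class = "pbpk_prediction")
}

#' @export
print.pbpk_prediction <- function(x, ...) {
  cat("<pbpk_prediction>\n")
  print(x$metrics)
  invisible(x)
}
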