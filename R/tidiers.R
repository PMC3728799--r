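#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.release_model <- function(x, ...) {
  pars <- c(M_inf = x$M_inf, tau = x$tau,
            if (x$form == "weibull") c(beta = x$beta),
            if (x$t_lag > 0) c(t_lag = x$t_lag))
  tibble::tibble(term = names(pars), estimate = unname(pars),
                 unit = c("mg", "h",
                          if (x$form == "weibull") "1",
                          if (x$t_lag > 0) "h"))
}

#' @export
glance.release_model <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(form = x$form,
                 rss = d$rss %||% NA_real_,
                 aicc = d$aicc %||% NA_real_,
                 n = d$n %||% NA_integer_,
                 n_params = d$n_params %||% NA_integer_)
}

#' @export
tidy.pbpk_calibration <- function(x, ...) {
  dplyr::rename(x$fitted, term = "parameter", estimate = "value")
}

#' @export
glance.pbpk_calibration <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 n_free = nrow(x$fitted),
                 n_obs = nrow(x$dataset),
                 iterations = x$convergence$iterations,
                 message = x$convergence$message)
}

#' @export
tidy.physiology_spec <- function(x, ...) {
  tibble::tibble(parameter = names(unclass(x)), value = unname(unclass(x)),
                 unit = unname(c(V_gics = "L", V_liver = "L", V_plasma = "L",
                          V_tissues = "L", V_lumen_stomach = "L",
                          V_lumen_si = "L", V_lumen_li = "L",
                          Q_gics = "L/h", Q_portal = "L/h",
                          Q_hepatic_out = "L/h", Q_tissues = "L/h",
                          k_gastric = "1/h", k_si_transit = "1/h",
                          k_li_transit = "1/h", PA_stomach = "L/h",
                          PA_si = "L/h", PA_li = "L/h", CL_hepatic = "L/h",
                          CL_renal = "L/h", F_unbound_factor = "1",
                          t_form_gastric = "h", t_form_si = "h")[names(unclass(x))]))
}

#' @export
tidy.ph_result <- function(x, ...) {
  tibble::tibble(form = names(x$speciation),
                 concentration_mol_per_L = unname(x$speciation))
}

#' @export
glance.ph_result <- function(x, ...) {
  tibble::tibble(pH = x$pH, mode = x$mode, ionic_strength = x$ionic_strength,
                 charge_residual = x$charge_residual)
}
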