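#' Non-compartmental analysis of a concentration-time curve
#'
#' Cmax and Tmax from the discrete maximum; AUC to the last sample by the
#' linear-up/log-down trapezoid rule; AUC to infinity by adding
#' `C_last / lambda_z`, with the terminal slope `lambda_z` estimated by
#' log-linear regression on the final run of (at least 3) strictly
#' descending positive points. When the extrapolated fraction of
#' AUC_0_inf exceeds 20% the extrapolation is refused and flagged, since
#' the terminal phase is then too poorly characterized to trust the
#' bioavailability estimate.
#'
#' @param time_h Sampling times, hours, strictly increasing.
#' @param conc Concentrations, mg/L, >= 0; at least 3 points.
#' @param extrapolate Extrapolate AUC to infinity? When `FALSE`,
#'   `AUC_0_inf` equals `AUC_0_last`.
#' @param auc_method `"lin_up_log_down"` (default) or `"linear"`.
#' @return A one-row tibble of class `pk_metrics`: `Cmax` (mg/L), `Tmax`
#'   (h), `AUC_0_last`, `AUC_0_inf` (mg*h/L), `lambda_z` (1/h),
#'   `extrap_fraction`, `extrapolation_ok`.
#' @examples
#' t <- seq(0, 24, by = 0.25)
#' nca_metrics(t, 2 * exp(-0.3 * t), extrapolate = TRUE)
#' @export
nca_metrics <- function(time_h, conc, extrapolate = FALSE,
                        auc_method = c("lin_up_log_down", "linear")) {
  auc_method <- match.arg(auc_method)
  if (length(time_h) < 3L || length(conc) != length(time_h)) {
    stop_pbpk("NCA needs >= 3 matching time/concentration points.", "pbpk_data_error")
  }
  if (any(diff(time_h) <= 0)) {
    stop_pbpk("NCA times must be strictly increasing.", "pbpk_data_error")
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_pbpk("Concentrations must be finite and >= 0.", "pbpk_data_error")
  }
  imax <- which.max(conc)
  cmax <- conc[imax]
  tmax <- time_h[imax]

  auc_last <- 0
  for (i in seq_len(length(conc) - 1L)) {
    dt <- time_h[i + 1L] - time_h[i]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    seg <- if (auc_method == "lin_up_log_down" && c2 < c1 && c2 > 0) {
      (c1 - c2) / log(c1 / c2) * dt
    } else {
      (c1 + c2) / 2 * dt
    }
    auc_last <- auc_last + seg
  }

  # terminal run of strictly descending positive points
  lambda_z <- NA_real_
  n <- length(conc)
  run_start <- n
  while (run_start > 1L && conc[run_start - 1L] > conc[run_start] &&
         conc[run_start] > 0) {
    run_start <- run_start - 1L
  }
  has_terminal <- (n - run_start + 1L) >= 3L && all(conc[run_start:n] > 0) &&
    run_start >= imax
  if (has_terminal) {
    fitlm <- lm(log(conc[run_start:n]) ~ time_h[run_start:n])
    lambda_z <- -unname(coef(fitlm)[2])
    if (!is.finite(lambda_z) || lambda_z <= 0) {
      lambda_z <- NA_real_
      has_terminal <- FALSE
    }
  }

  extrap_ok <- TRUE
  auc_inf <- auc_last
  extrap_fraction <- 0
  if (extrapolate) {
    if (!has_terminal) {
      if (cmax == 0) {
        extrap_ok <- FALSE   # all-zero curve: nothing to extrapolate
      } else {
        stop_pbpk("No descending terminal phase: cannot extrapolate AUC.",
                  "pbpk_data_error")
      }
    } else {
      tail_auc <- conc[n] / lambda_z
      auc_inf <- auc_last + tail_auc
      extrap_fraction <- tail_auc / auc_inf
      if (extrap_fraction > 0.20) extrap_ok <- FALSE
    }
  }

  out <- tibble::tibble(
    Cmax = cmax, Tmax = tmax,
    AUC_0_last = auc_last, AUC_0_inf = auc_inf,
    lambda_z = lambda_z, extrap_fraction = extrap_fraction,
    extrapolation_ok = extrap_ok
  )
  class(out) <- c("pk_metrics", class(out))
  out
}
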