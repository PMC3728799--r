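#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a PBPK trajectory
#'
#' Concentration-time curves, one panel per compartment (or a single
#' plasma panel).
#'
#' @param object A `pbpk_trajectory`.
#' @param compartments Compartments to show; default all seven.
#' @param ... Ignored.
#' @export
autoplot.pbpk_trajectory <- function(object,
                                     compartments = pbpk_compartments, ...) {
  long <- tidy_trajectory(object)
  long <- long[long$compartment %in% compartments, ]
  ggplot(long, aes(x = .data$time_h, y = .data$concentration_mg_per_L)) +
    geom_line() +
    facet_wrap(~compartment, scales = "free_y") +
    labs(x = "time (h)", y = "concentration (mg/L)") +
    theme_minimal()
}

#' Plot a dissolution profile with an optional fitted model
#'
#' @param object A `dissolution_profile`.
#' @param model Optional fitted [release_model()] overlaid as a curve.
#' @param ... Ignored.
#' @export
autoplot.dissolution_profile <- function(object, model = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time_h, y = .data$released_mg)) +
    geom_point() +
    labs(x = "time (h)", y = "cumulative released (mg)",
         title = attr(object, "label")) +
    theme_minimal()
  if (!is.null(model)) {
    tt <- seq(0, max(object$time_h), length.out = 200)
    fit <- tibble::tibble(time_h = tt,
                          released_mg = evaluate_cumulative(model, tt))
    p <- p + geom_line(data = fit)
  }
  p
}

#' Plot a protocol run's pH trace and release
#'
#' pH (and setpoint, when present) against time; release overlaid on a
#' second panel when the run carries a tablet.
#'
#' @param object A `protocol_run`.
#' @param ... Ignored.
#' @export
autoplot.protocol_run <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$time_h, y = .data$pH)) +
    geom_line() +
    labs(x = "time (h)", y = "pH") +
    theme_minimal()
  if ("setpoint" %in% names(object)) {
    p <- p + geom_step(aes(y = .data$setpoint), linetype = "dashed")
  }
  p
}

#' Plot a plasma dataset
#'
#' @param object A `plasma_dataset`.
#' @param ... Ignored.
#' @export
autoplot.plasma_dataset <- function(object, ...) {
  ggplot(object, aes(x = .data$time_h, y = .data$conc_mg_per_L)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    labs(x = "time (h)", y = "plasma concentration (mg/L)",
         title = attr(object, "label")) +
    theme_minimal()
}
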