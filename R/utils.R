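#' @importFrom rlang abort warn %||%
#' @importFrom stats uniroot coef lm median quantile rnorm setNames
#' @importFrom utils head tail modifyList
NULL

# error constructor with a subclass so callers can distinguish data errors
# from convergence errors (the CLI maps these onto exit codes)
stop_pbpk <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "pbpkivivc_error"), ...)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pbpk(sprintf("`%s` must be a single finite number.", name),
              "pbpk_data_error")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop_pbpk(sprintf("`%s` = %g is outside its allowed range.", name, x),
              "pbpk_data_error")
  }
  invisible(x)
}

is_named_numeric <- function(x) {
  is.numeric(x) && !is.null(names(x)) && all(nzchar(names(x)))
}
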