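#' Specification of a synthetic in-vitro/in-vivo study
#'
#' Defines a complete study with known ground truth, emulating the design
#' of the worked modified-release example: three tablets of equal drug
#' content whose release rates decrease from "fast" to "medium" to
#' "slow" (sigmoid Weibull profiles reaching a 100 mg plateau), a single
#' ground-truth physiology generating single-peak plasma curves for each,
#' and multiplicative log-normal measurement noise. Every random draw
#' comes from the mandatory seed - no hidden entropy - so generated
#' fixtures are bit-reproducible.
#'
#' @param seed Integer seed (mandatory).
#' @param physiology Ground-truth [physiology_spec()].
#' @param release Named list of three [release_model()]s, labels `fast`,
#'   `medium`, `slow`, strictly ordered by time-to-50%-release.
#' @param sigma Multiplicative log-normal noise sd (default 0.05, i.e.
#'   roughly 5% relative measurement error).
#' @param dissolution_grid Sampling times for dissolution profiles, hours.
#' @param plasma_grid Sampling times for plasma curves, hours.
#' @param dose_mg Tablet drug content, mg.
#' @return An object of class `synthetic_study`.
#' @export
synthetic_study <- function(seed,
                            physiology = default_physiology(),
                            release = list(
                              fast = release_model("weibull", 100, tau = 1.5, beta = 1.6),
                              medium = release_model("weibull", 100, tau = 3, beta = 1.6),
                              slow = release_model("weibull", 100, tau = 6, beta = 1.6)
                            ),
                            sigma = 0.05,
                            dissolution_grid = seq(0.5, 12, length.out = 12),
                            plasma_grid = c(0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6,
                                            8, 10, 12, 16, 20, 24),
                            dose_mg = 100) {
  if (missing(seed)) stop_pbpk("`seed` is mandatory.", "pbpk_data_error")
  assert_scalar_number(seed, "seed")
  stopifnot(inherits(physiology, "physiology_spec"))
  if (!identical(sort(names(release)), c("fast", "medium", "slow"))) {
    stop_pbpk("`release` must be a named list: fast, medium, slow.", "pbpk_data_error")
  }
  t50 <- vapply(release[c("fast", "medium", "slow")], function(m) {
    m$t_lag + m$tau * switch(m$form,
      weibull = log(2)^(1 / m$beta),
      first_order = log(2),
      zero_order_capped = 0.5)
  }, numeric(1))
  if (any(diff(t50) <= 0)) {
    stop_pbpk("fast/medium/slow must be strictly ordered by time-to-50%-release.",
              "pbpk_data_error")
  }
  assert_scalar_number(sigma, "sigma", lower = 0)
  structure(
    list(seed = as.integer(seed), physiology = physiology, release = release,
         sigma = sigma, dissolution_grid = dissolution_grid,
         plasma_grid = plasma_grid, dose_mg = dose_mg),
    class = "synthetic_study"
  )
}

# run fn under a deterministic task-specific RNG state, restoring on exit
with_task_seed <- function(seed, task_offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + task_offset) %% .Machine$integer.max)
  fn()
}

multiplicative_noise <- function(x, sigma) {
  if (sigma == 0) return(x)
  x * exp(rnorm(length(x), mean = 0, sd = sigma))
}

#' Generate the synthetic dissolution triplet
#'
#' Samples each ground-truth release model on the dissolution grid,
#' applies multiplicative log-normal noise, clips to
#' `[0, 1.05 * M_inf]`, and enforces monotonicity by cumulative maximum
#' (cumulative release cannot decrease; apparent decreases are
#' measurement error).
#'
#' @param study A [synthetic_study()].
#' @return Named list of three [dissolution_profile()]s
#'   (`fast`, `medium`, `slow`).
#' @export
generate_dissolution <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  labs <- c("fast", "medium", "slow")
  out <- purrr::imap(setNames(labs, labs), function(lab, nm) {
    offset <- match(lab, labs)
    with_task_seed(study$seed, offset, function() {
      truth <- evaluate_cumulative(study$release[[lab]], study$dissolution_grid)
      y <- multiplicative_noise(truth, study$sigma)
      y <- pmin(pmax(y, 0), 1.05 * study$release[[lab]]$M_inf)
      y <- cummax(y)
      dissolution_profile(study$dissolution_grid, y, label = lab,
                          dose_content_mg = study$dose_mg)
    })
  })
  out
}

#' Generate a synthetic plasma dataset
#'
#' Simulates the ground-truth physiology with an oral dose of the chosen
#' formulation, samples the plasma concentration on the plasma grid and
#' applies multiplicative log-normal noise. The generating dose event
#' (with the *true* release model) is stored on the dataset.
#'
#' @param study A [synthetic_study()].
#' @param formulation_label `"fast"`, `"medium"` or `"slow"`.
#' @return A [plasma_dataset()].
#' @export
generate_plasma <- function(study, formulation_label) {
  stopifnot(inherits(study, "synthetic_study"))
  formulation_label <- match.arg(formulation_label, c("fast", "medium", "slow"))
  dose <- dose_event("oral", study$dose_mg,
                     release_model = study$release[[formulation_label]])
  t_grid <- sort(unique(c(0, study$plasma_grid)))
  traj <- simulate_pbpk(study$physiology, dose, t_grid)
  truth <- traj$conc_plasma[match(study$plasma_grid, traj$time_h)]
  offset <- 10L + match(formulation_label, c("fast", "medium", "slow"))
  conc <- with_task_seed(study$seed, offset, function() {
    pmax(multiplicative_noise(truth, study$sigma), 0)
  })
  plasma_dataset(study$plasma_grid, conc, dose = dose,
                 label = formulation_label)
}
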