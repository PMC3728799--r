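timeseries_dialects <- list(
  dissolution = c("time_h", "released_mg"),
  plasma = c("time_h", "conc_mg_per_L"),
  ph_program = c("time_h", "pH")
)

#' Read a time-series CSV
#'
#' Strict readers for the three CSV dialects the package exchanges:
#' dissolution profiles (`time_h, released_mg`), plasma curves
#' (`time_h, conc_mg_per_L`) and pH programs (`time_h, pH`). The header
#' must match exactly; rows are normalized to time order; duplicate
#' times and non-numeric cells are rejected with row-numbered messages.
#'
#' @param path CSV file path.
#' @param kind `"dissolution"`, `"plasma"` or `"ph_program"`.
#' @param ... Passed to the typed constructor: for `dissolution`,
#'   `label` and `dose_content_mg`; for `plasma`, `dose` and `label`;
#'   for `ph_program`, `interpolation`.
#' @return A [dissolution_profile()], [plasma_dataset()] or
#'   [ph_program()].
#' @export
read_timeseries_csv <- function(path, kind = c("dissolution", "plasma",
                                               "ph_program"), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop_pbpk(paste0("File not found: ", path), "pbpk_data_error")
  }
  cols <- timeseries_dialects[[kind]]
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!identical(names(df), cols)) {
    stop_pbpk(sprintf("Expected header '%s' in %s, found '%s'.",
                      paste(cols, collapse = ","), path,
                      paste(names(df), collapse = ",")), "pbpk_data_error")
  }
  num <- purrr::map(df, function(x) suppressWarnings(as.numeric(x)))
  for (cn in cols) {
    bad <- which(is.na(num[[cn]]) & !is.na(df[[cn]]))
    if (length(bad)) {
      stop_pbpk(sprintf("Non-numeric value in column '%s', row %d of %s.",
                        cn, bad[1] + 1L, path), "pbpk_data_error")
    }
    if (anyNA(num[[cn]])) {
      stop_pbpk(sprintf("Missing value in column '%s', row %d of %s.",
                        cn, which(is.na(num[[cn]]))[1] + 1L, path),
                "pbpk_data_error")
    }
  }
  tt <- num$time_h
  dup <- which(duplicated(tt))
  if (length(dup)) {
    stop_pbpk(sprintf("Duplicated time %g at row %d of %s.",
                      tt[dup[1]], dup[1] + 1L, path), "pbpk_data_error")
  }
  ord <- order(tt)
  switch(kind,
    dissolution = dissolution_profile(tt[ord], num$released_mg[ord], ...),
    plasma = plasma_dataset(tt[ord], num$conc_mg_per_L[ord], ...),
    ph_program = ph_program(tt[ord], num$pH[ord], ...)
  )
}

#' Write a time-series CSV
#'
#' Writers matched to the readers: the output of
#' `write_timeseries_csv()` is always accepted by
#' [read_timeseries_csv()] with the corresponding kind.
#'
#' @param x A `dissolution_profile`, `plasma_dataset` or `ph_program`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path) {
  cols <- if (inherits(x, "dissolution_profile")) timeseries_dialects$dissolution
  else if (inherits(x, "plasma_dataset")) timeseries_dialects$plasma
  else if (inherits(x, "ph_program")) timeseries_dialects$ph_program
  else stop_pbpk("Unsupported object for write_timeseries_csv().", "pbpk_data_error")
  readr::write_csv(tibble::as_tibble(x)[, cols], path)
  invisible(path)
}

#' Write a PBPK trajectory as tidy CSV
#'
#' Long format: one row per time x compartment with both amount and
#' concentration.
#'
#' @param traj A `pbpk_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  long <- tidy_trajectory(traj)
  readr::write_csv(long, path)
  invisible(path)
}

#' Tidy long form of a trajectory
#'
#' @param traj A `pbpk_trajectory`.
#' @return Tibble with columns `time_h`, `compartment`, `amount_mg`,
#'   `concentration_mg_per_L`.
#' @export
tidy_trajectory <- function(traj) {
  stopifnot(inherits(traj, "pbpk_trajectory"))
  df <- tibble::as_tibble(traj)
  amounts <- df |>
    dplyr::select("time_h", dplyr::all_of(pbpk_compartments)) |>
    tidyr::pivot_longer(-"time_h", names_to = "compartment",
                        values_to = "amount_mg")
  concs <- df |>
    dplyr::select("time_h", dplyr::starts_with("conc_")) |>
    tidyr::pivot_longer(-"time_h", names_to = "compartment",
                        values_to = "concentration_mg_per_L") |>
    dplyr::mutate(compartment = sub("^conc_", "", .data$compartment))
  dplyr::left_join(amounts, concs, by = c("time_h", "compartment"))
}

config_unit_suffix <- c(
  V_gics = "_L", V_liver = "_L", V_plasma = "_L", V_tissues = "_L",
  V_lumen_stomach = "_L", V_lumen_si = "_L", V_lumen_li = "_L",
  Q_gics = "_L_per_h", Q_portal = "_L_per_h", Q_hepatic_out = "_L_per_h",
  Q_tissues = "_L_per_h",
  k_gastric = "_per_h", k_si_transit = "_per_h", k_li_transit = "_per_h",
  PA_stomach = "_L_per_h", PA_si = "_L_per_h", PA_li = "_L_per_h",
  CL_hepatic = "_L_per_h", CL_renal = "_L_per_h",
  F_unbound_factor = "",
  t_form_gastric = "_h", t_form_si = "_h"
)

#' Expected physiology keys in configuration files
#'
#' Configuration files embed units in the key names (e.g.
#' `Q_portal_L_per_h`); this returns the full set of 22 expected keys.
#'
#' @return Character vector of length 22.
#' @export
physiology_config_keys <- function() {
  unname(paste0(names(config_unit_suffix), config_unit_suffix))
}

parse_physiology_block <- function(block, where = "physiology") {
  expected <- physiology_config_keys()
  got <- names(block)
  missing <- setdiff(expected, got)
  extra <- setdiff(got, expected)
  if (length(missing) || length(extra)) {
    msg <- c(
      if (length(missing)) paste0("missing keys: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("unknown keys: ", paste(extra, collapse = ", "))
    )
    stop_pbpk(paste0("Invalid ", where, " block (", paste(msg, collapse = "; "), ")."),
              "pbpk_config_error")
  }
  vals <- setNames(vapply(expected, function(k) as.numeric(block[[k]]), numeric(1)),
                   names(config_unit_suffix))
  physiology_spec(vals)
}

run_config_sections <- c("physiology", "dose", "free_parameters", "paths",
                         "protocol", "seed", "output_dir", "log_level")

#' Load and validate a run configuration
#'
#' YAML configuration with a strict schema: unknown top-level sections or
#' physiology keys are rejected (a silently defaulted physiology would
#' corrupt a calibration), and the physiology block must contain exactly
#' the 22 unit-suffixed parameter keys of [physiology_config_keys()].
#'
#' @param path YAML file.
#' @return A list of class `run_config` with a parsed
#'   `physiology` ([physiology_spec()]), `dose` (list as given),
#'   `free_parameters`, `paths`, `protocol`, `seed`, `output_dir`,
#'   `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_pbpk(paste0("Config not found: ", path), "pbpk_config_error")
  }
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), run_config_sections)
  if (length(extra)) {
    stop_pbpk(paste0("Unknown config section(s): ", paste(extra, collapse = ", ")),
              "pbpk_config_error")
  }
  if (is.null(raw$physiology)) {
    stop_pbpk("Config must contain a `physiology` section.", "pbpk_config_error")
  }
  phys <- parse_physiology_block(raw$physiology)
  free <- raw$free_parameters %||% c("PA_si", "CL_hepatic", "Q_tissues",
                                     "F_unbound_factor")
  bad <- setdiff(free, physiology_parameter_names)
  if (length(bad)) {
    stop_pbpk(paste0("Unknown free parameter(s) in config: ",
                     paste(bad, collapse = ", ")), "pbpk_config_error")
  }
  structure(
    list(physiology = phys, dose = raw$dose, free_parameters = free,
         paths = raw$paths, protocol = raw$protocol,
         seed = raw$seed %||% 1L, output_dir = raw$output_dir %||% ".",
         log_level = raw$log_level %||% "info"),
    class = "run_config"
  )
}
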