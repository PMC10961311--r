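#' Default model configuration
#'
#' Returns the full nested configuration consumed by [build_parameters()] and
#' the simulation layer. The allometric constants follow the classic
#' bioenergetic food-web parameterisation: rates scale with body mass to the
#' -1/4 power, maximum consumption is a fixed multiple of metabolic rate, and
#' assimilation efficiency depends on whether the resource is plant or animal
#' tissue. All rate constants are expressed per day here; the model runs per
#' hour after [convert_daily_to_hourly()].
#'
#' Sections:
#' \describe{
#'   \item{allometry}{`a_r` (producer intrinsic growth at reference mass,
#'     1/d), `a_x` (consumer metabolic constant, 1/d), `y` (maximum
#'     consumption rate as a dimensionless multiple of metabolic rate),
#'     `mass_exponent` (default -0.25), `reference_mass_g`.}
#'   \item{efficiencies}{`e_plant` (0.45), `e_animal` (0.85); the baseline
#'     detritus node uses the plant value.}
#'   \item{functional_response}{`q` (Holling shape exponent, 1.2 — between
#'     Type II and Type III), `B0` (half-saturation density g/m2), `d`
#'     (intraspecific interference, dimensionless).}
#'   \item{scenario}{`k_mixing_grid` (pelagic-intertidal exchange rates, 1/h),
#'     `baseline_biomass` (g/m2), `extinction_threshold` (g/m2),
#'     `equilibration_years`, `f_a`, `f_m` (assimilation and
#'     maintenance coefficients of the consumer equation; 1 recovers the
#'     standard bioenergetic model).}
#' }
#'
#' @param ... Named overrides applied on top of the defaults, e.g.
#'   `atn_default_config(functional_response = list(q = 2))` replaces only
#'   the keys given.
#' @return A nested named list with class `atn_config`.
#' @export
atn_default_config <- function(...) {
  cfg <- list(
    allometry = list(
      a_r = 1.0,            # 1/d at reference mass
      a_x = 0.314,          # 1/d, invertebrate metabolic constant
      y = 8,                # max consumption, multiple of x_i
      mass_exponent = -0.25,
      reference_mass_g = 1.0
    ),
    efficiencies = list(
      e_plant = 0.45,
      e_animal = 0.85
    ),
    functional_response = list(
      q = 1.2,
      B0 = 1500,            # g/m2 half-saturation
      d = 0.01              # intraspecific interference; bounds consumer
                            # growth on the constant detritus pool. The
                            # natural scale is B0^(q-2) ~ 0.003 (interference
                            # comparable to resource saturation when consumer
                            # biomass is near B0); 0.01 is moderate.
    ),
    scenario = list(
      k_mixing_grid = c(0.1, 1.0, 10.0),  # 1/h
      baseline_biomass = 3750,            # g/m2
      extinction_threshold = 1e-6,        # g/m2
      equilibration_years = 10,
      f_a = 1,
      f_m = 1
    )
  )
  overrides <- list(...)
  for (section in names(overrides)) {
    if (!section %in% names(cfg)) {
      stop("unknown config section: ", section, call. = FALSE)
    }
    for (key in names(overrides[[section]])) {
      if (!key %in% names(cfg[[section]])) {
        stop("unknown config key: ", section, "$", key, call. = FALSE)
      }
      cfg[[section]][[key]] <- overrides[[section]][[key]]
    }
  }
  structure(cfg, class = c("atn_config", "list"))
}

#' @export
print.atn_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Read a configuration file
#'
#' Loads a YAML configuration and overlays it on the defaults, so a file only
#' needs to state the keys it changes.
#'
#' @param path Path to a YAML file with any subset of the sections of
#'   [atn_default_config()].
#' @return An `atn_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(atn_default_config, raw)
}
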