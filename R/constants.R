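#' Physical constants and unit factors
#'
#' The internal unit system is micrometer (length), millisecond (time),
#' millimolar (concentration), millivolt (voltage) and mA/cm^2 (membrane
#' current density) -- the conventional system of compartmental dendrite
#' models. All unit conversions are funneled through this one table so a
#' single dimensional-analysis test can pin them down.
#'
#' Entries:
#' * `FARADAY`: Faraday constant, C/mol.
#' * `GAS_CONSTANT`: molar gas constant, J/(mol K).
#' * `FLUX_TO_CONC`: converts a membrane calcium current density (mA/cm^2,
#'   inward negative) into a concentration source: for a shell of depth
#'   `d` um, `dCa/dt (mM/ms) = -I * FLUX_TO_CONC / (z * d)`. The factor is
#'   `1e4 / FARADAY`: 1 mA/cm^2 equals 10 A/m^2; dividing by (z F) and a depth
#'   in meters gives mol m^-3 s^-1 = mM/s, and collecting the um and ms
#'   conversions leaves 1e4/F in (mM um / ms) per (mA/cm^2).
#' * `PUMP_DENSITY_TO_CONC`: converts a membrane pump density in mol/cm^2
#'   times an area/volume ratio in um^-1 into mM: 1 mol/cm^2 is 1e-8 mol/um^2,
#'   dividing by a depth in um gives 1e-8 mol/um^3 = 1e7 mol/L, i.e. 1e10 mM.
#'
#' @format A named list.
#' @export
dca_constants <- list(
  FARADAY       = 96485.33212,
  GAS_CONSTANT  = 8.314462618,
  FLUX_TO_CONC  = 1e4 / 96485.33212,
  PUMP_DENSITY_TO_CONC = 1e10
)

# Default resting free calcium, mM (45 nM).
CA_REST_DEFAULT <- 45e-6

# invalid-geometry condition used across the geometry-facing functions
stop_invalid_geometry <- function(...) {
  msg <- paste0(...)
  stop(errorCondition(msg, class = c("dendroca_invalid_geometry", "error")))
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid_geometry(name, " must be a positive finite scalar, got ",
                          deparse(substitute(x)), " = ", format(x))
  }
  invisible(x)
}
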