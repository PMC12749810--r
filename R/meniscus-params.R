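#' Fluid parameters for the interface solver
#'
#' Density and surface tension drive the quasi-static Young-Laplace balance;
#' viscosity is carried as metadata only (a quasi-static model has no flow).
#'
#' @param density liquid density, kg m^-3.
#' @param surface_tension liquid-air surface tension, N m^-1.
#' @param viscosity dynamic viscosity, Pa s (metadata, unused by the solver).
#' @param gravity gravitational acceleration, m s^-2.
#' @return An object of class `fluid_params`.
#' @export
fluid_params <- function(density = 1000, surface_tension = 0.05,
                         viscosity = 0.05, gravity = 9.81) {
  gp_validate(is.numeric(density) && density > 0, "density must be > 0")
  gp_validate(is.numeric(surface_tension) && surface_tension > 0,
              "surface_tension must be > 0")
  gp_validate(is.numeric(gravity) && gravity >= 0, "gravity must be >= 0")
  structure(list(density = density, surface_tension = surface_tension,
                 viscosity = viscosity, gravity = gravity),
            class = "fluid_params")
}

#' Cylindrical well geometry
#'
#' @param radius well radius, m.
#' @param height well height, m.
#' @param format_label free-text plate format label.
#' @return An object of class `well_geometry`.
#' @export
well_geometry <- function(radius = 3.2e-3, height = 11e-3,
                          format_label = "96-well") {
  gp_validate(is.numeric(radius) && radius > 0, "well radius must be > 0")
  gp_validate(is.numeric(height) && height > 0, "well height must be > 0")
  structure(list(radius = radius, height = height,
                 format_label = format_label), class = "well_geometry")
}

#' Contact-angle hysteresis parameters
#'
#' Advancing and receding angles apply to the contact line on the well bottom;
#' `theta_wall` is the static contact angle on the sidewall once it is wetted.
#' Defaults describe a protein-rich (gelatin) precursor on polystyrene:
#' moderate advancing angle, near-zero receding angle (adsorbed protein pins
#' the receding line), see the methods vignette for the calibration.
#'
#' @param theta_advancing advancing contact angle on the bottom, degrees.
#' @param theta_receding receding contact angle on the bottom, degrees.
#' @param theta_wall sidewall contact angle, degrees.
#' @return An object of class `wetting_params`.
#' @export
wetting_params <- function(theta_advancing = 50, theta_receding = 2,
                           theta_wall = 60) {
  gp_validate(is.numeric(theta_receding) && theta_receding > 0 &&
                theta_receding <= theta_advancing && theta_advancing < 180,
              "need 0 < theta_receding <= theta_advancing < 180")
  gp_validate(is.numeric(theta_wall) && theta_wall > 0 && theta_wall < 180,
              "need 0 < theta_wall < 180")
  structure(list(theta_advancing = theta_advancing,
                 theta_receding = theta_receding,
                 theta_wall = theta_wall), class = "wetting_params")
}

#' Dispense / aspirate protocol
#'
#' @param steps a data.frame with columns `action` ("dispense"/"aspirate") and
#'   `volume` (m^3), or a list of `list(action=, volume=)` entries.
#' @param residual_volume liquid left behind after the final aspiration, m^3.
#'   `NULL` derives it at run time from `film_um` in [simulate_protocol()]
#'   (mean residual film thickness over the pinned footprint).
#' @return An object of class `dispense_protocol`.
#' @export
dispense_protocol <- function(steps, residual_volume = NULL) {
  if (is.list(steps) && !is.data.frame(steps)) {
    steps <- data.frame(
      action = vapply(steps, function(s) as.character(s$action), ""),
      volume = vapply(steps, function(s) as.numeric(s$volume), 0))
  }
  gp_validate(is.data.frame(steps) &&
                all(c("action", "volume") %in% names(steps)),
              "steps needs columns action, volume")
  gp_validate(all(steps$action %in% c("dispense", "aspirate")),
              "actions must be dispense or aspirate")
  gp_validate(all(steps$volume > 0), "every step volume must be > 0")
  if (!is.null(residual_volume))
    gp_validate(residual_volume >= 0, "residual_volume must be >= 0")
  structure(list(steps = steps, residual_volume = residual_volume),
            class = "dispense_protocol")
}

#' Default parameter set
#'
#' The parameter set used throughout the package for a 96-well gelatin
#' precursor system.  The well and fluid values are conventional (3.2 mm well
#' radius, water-like density, 0.05 N m^-1 surface tension for a gelatin
#' solution); the advancing angle is calibrated so the simulated dispensing
#' regime matches the reported volume thresholds, and the receding angle is
#' near zero so the contact line stays pinned during re-aspiration (see the
#' methods vignette).
#'
#' @return A list with elements `well`, `fluid`, `wetting`.
#' @export
default_params <- function() {
  list(well = well_geometry(), fluid = fluid_params(),
       wetting = wetting_params())
}
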