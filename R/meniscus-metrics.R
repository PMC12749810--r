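#' Flatness metric of an interface profile
#'
#' Percentage of the well radius over which the air-liquid interface is
#' "planar", i.e. its local inclination to the horizontal stays within
#' `tolerance_deg` (default 3 degrees, the 90 +/- 3 degree rule stated
#' relative to the vertical dispensing axis).  The planar length is measured
#' as radial projection; for near-flat regions this differs from arc length
#' by under `tan(3 deg)^2` (~0.3%).
#'
#' @param profile an `interface_profile`.
#' @param well a [well_geometry()].
#' @param tolerance_deg planarity tolerance, degrees (> 0).
#' @return flatness in percent, clamped to `[0, 100]`.
#' @export
flatness_metric <- function(profile, well = well_geometry(),
                            tolerance_deg = 3) {
  gp_validate(tolerance_deg > 0, "tolerance_deg must be > 0")
  gp_validate(length(profile$r) >= 3, "profile needs at least 3 points")
  r <- profile$r; z <- profile$z
  dr <- diff(r); dz <- diff(z)
  keep <- dr > 0
  slope <- abs(dz[keep] / dr[keep])
  planar <- slope <= tan(deg2rad(tolerance_deg))
  min(100, max(0, 100 * sum(dr[keep][planar]) / well$radius))
}

#' Radial coverage metric
#'
#' Gel footprint radius as a percentage of the well radius.
#'
#' @inheritParams flatness_metric
#' @return coverage in percent.
#' @export
coverage_metric <- function(profile, well = well_geometry()) {
  gp_validate(profile$contact_radius <= well$radius * (1 + 1e-9),
              "contact radius exceeds the well radius")
  100 * min(profile$contact_radius, well$radius) / well$radius
}
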