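#' Spherical-cap closed form (zero-gravity oracle)
#'
#' For a drop pinned at contact radius `rc` with no gravity the equilibrium
#' shape is a spherical cap with apex height `h` satisfying
#' `V = (pi h / 6) (3 rc^2 + h^2)` and contact angle `theta = 2 atan(h / rc)`.
#' Restricted to sub-hemispherical caps (`theta <= 90` degrees); used as the
#' independent closed-form reference for the numerical solver.
#'
#' @param volume drop volume, m^3 (>= 0).
#' @param contact_radius pinned contact-line radius, m.
#' @return list with `height` (m) and `apparent_angle` (degrees).
#' @export
spherical_cap_oracle <- function(volume, contact_radius) {
  gp_validate(is.numeric(volume) && volume >= 0, "volume must be >= 0")
  gp_validate(is.numeric(contact_radius) && contact_radius > 0,
              "contact_radius must be > 0")
  if (volume == 0) return(list(height = 0, apparent_angle = 0))
  rc <- contact_radius
  # monotone cubic (pi/6) h^3 + (pi/2) rc^2 h - V = 0, single real root
  f <- function(h) pi * h * (3 * rc^2 + h^2) / 6 - volume
  h <- uniroot(f, c(0, max(10 * rc, (6 * volume / pi)^(1 / 3))),
               tol = 1e-15 * rc)$root
  if (h > rc * (1 + 1e-9))
    gp_stop("volume implies a contact angle above 90 degrees",
            "gelplate_out_of_range")
  list(height = h, apparent_angle = rad2deg(2 * atan(h / rc)))
}

# --- internal shooting machinery --------------------------------------------

# volume of a pinned cap at apex curvature b; mode 2 (theta<=90) / 3 (>90)
cap_try <- function(b, c_grav, rc, mode, ds_max) {
  res <- yl_cap_integrate(b, c_grav, mode, rc, ds_max, 500000L)
  if (!res$hit) return(NULL)
  res
}

# find apex curvature so the pinned cap at rc encloses `volume`;
# returns the integration result (r, depth z, phi, volume)
cap_solve_pinned <- function(volume, rc, c_grav, rel_tol = 1e-4) {
  ds_max <- rc / 600
  # upper end of the theta<=90 branch: largest b whose profile still reaches
  # rc while phi < 90 deg; located by bisection on the hit condition
  b <- 1 / rc  # exact branch end at zero gravity, good anchor otherwise
  res_b <- cap_try(b, c_grav, rc, 2L, ds_max)
  if (is.null(res_b)) {
    b_no <- b
    while (is.null(res_b) && b > 1e-9 / rc) {
      b <- b * 0.8
      res_b <- cap_try(b, c_grav, rc, 2L, ds_max)
    }
  } else {
    b_no <- b
    for (i in 1:40) {
      b_no <- b_no * 1.3
      if (is.null(cap_try(b_no, c_grav, rc, 2L, ds_max))) break
    }
  }
  lo_hit <- b; hi_no <- b_no
  for (i in 1:50) {  # refine the branch end
    mid <- sqrt(lo_hit * hi_no)
    cand <- cap_try(mid, c_grav, rc, 2L, ds_max)
    if (is.null(cand)) hi_no <- mid else { lo_hit <- mid; res_b <- cand }
  }
  hi <- lo_hit
  res_hi <- res_b
  if (!is.null(res_hi) && res_hi$volume >= volume) {
    lo <- hi * 1e-8
    # V(b) increasing on this branch
    for (i in 1:100) {
      mid <- sqrt(lo * hi)
      res <- cap_try(mid, c_grav, rc, 2L, ds_max)
      v <- if (is.null(res)) Inf else res$volume
      if (!is.null(res) && abs(v - volume) <= rel_tol * volume)
        return(res)
      if (v > volume) hi <- mid else lo <- mid
    }
    res <- cap_try(sqrt(lo * hi), c_grav, rc, 2L, ds_max)
    if (!is.null(res) && abs(res$volume - volume) <= 10 * rel_tol * volume)
      return(res)
    gp_stop(sprintf("no convergent cap shape (last residual %.3g)",
                    if (is.null(res)) NA_real_ else res$volume - volume),
            "gelplate_solver")
  }
  # theta > 90 branch: V(b) decreasing in b
  hi_b <- hi
  lo_b <- hi * 1e-4
  for (i in 1:100) {
    mid <- sqrt(lo_b * hi_b)
    res <- cap_try(mid, c_grav, rc, 3L, ds_max)
    v <- if (is.null(res)) -Inf else res$volume
    if (!is.null(res) && abs(v - volume) <= rel_tol * volume) return(res)
    if (v < volume) hi_b <- mid else lo_b <- mid
  }
  gp_stop("no convergent cap shape on the steep branch", "gelplate_solver")
}

# find apex curvature so the cap meeting the bottom at `theta_deg` encloses
# `volume`; V(b) is decreasing in b on this family
cap_solve_at_angle <- function(volume, theta_deg, c_grav, rel_tol = 1e-4) {
  th <- deg2rad(theta_deg)
  L <- (6 * volume / pi)^(1 / 3) * 4
  ds_max <- L / 600
  lo <- 1e-3 / L
  hi <- 1e5 / L
  for (i in 1:110) {
    mid <- sqrt(lo * hi)
    res <- yl_cap_integrate(mid, c_grav, 1L, th, ds_max, 500000L)
    v <- if (res$hit) res$volume else -Inf
    if (res$hit && abs(v - volume) <= rel_tol * volume) return(res)
    if (is.finite(v) && v < volume) hi <- mid else lo <- mid
  }
  gp_stop("no convergent cap shape at the prescribed angle",
          "gelplate_solver")
}

cap_profile_from_res <- function(res, volume) {
  n <- length(res$r)
  h <- res$z[n]
  structure(list(r = res$r, z = h - res$z, contact_radius = res$r[n],
                 volume = volume, wall_contact = FALSE,
                 apparent_angle = rad2deg(res$phi[n])),
            class = "interface_profile")
}

#' Solve the pinned sessile-drop interface
#'
#' Axisymmetric Young-Laplace shape of a drop pinned at `contact_radius`,
#' including the hydrostatic pressure gradient.  The apex curvature is found
#' by bisection on the enclosed-volume residual (relative tolerance 1e-4,
#' tighter than the 0.1% contract).
#'
#' @param volume drop volume, m^3.
#' @param contact_radius pinned footprint radius, m.
#' @param fluid a [fluid_params()] object.
#' @return An `interface_profile`: radial grid `r` (m, 0 to contact radius),
#'   heights `z` (m), `contact_radius`, `volume`, `wall_contact = FALSE` and
#'   `apparent_angle` (degrees, at the contact line).
#' @export
solve_cap_profile <- function(volume, contact_radius, fluid = fluid_params()) {
  gp_validate(is.numeric(volume) && is.finite(volume) && volume > 0,
              "volume must be finite and > 0")
  gp_validate(is.numeric(contact_radius) && is.finite(contact_radius) &&
                contact_radius > 0, "contact_radius must be finite and > 0")
  c_grav <- fluid$density * fluid$gravity / fluid$surface_tension
  res <- cap_solve_pinned(volume, contact_radius, c_grav)
  prof <- cap_profile_from_res(res, volume)
  if (prof$apparent_angle > 150)
    gp_stop("apparent angle beyond ~150 degrees; no pinned solution",
            "gelplate_solver")
  prof
}

#' Solve the wall-wetted meniscus
#'
#' Interface spanning the whole well, meeting the sidewall at the prescribed
#' contact angle and the axis with zero slope.  The centre curvature is found
#' by shooting on the wall inclination; the vertical offset then matches the
#' volume exactly (the shape itself is volume-independent up to a shift).
#'
#' @param volume liquid volume, m^3.
#' @param well a [well_geometry()].
#' @param fluid a [fluid_params()].
#' @param theta_wall sidewall contact angle, degrees.
#' @return An `interface_profile` with `wall_contact = TRUE`; the
#'   `apparent_angle` field reports the wall contact angle.
#' @export
solve_wall_meniscus <- function(volume, well = well_geometry(),
                                fluid = fluid_params(), theta_wall = 60) {
  gp_validate(is.numeric(volume) && is.finite(volume) && volume > 0,
              "volume must be finite and > 0")
  gp_validate(theta_wall > 0 && theta_wall < 180,
              "theta_wall must be in (0, 180)")
  Rw <- well$radius
  c_grav <- fluid$density * fluid$gravity / fluid$surface_tension
  target <- deg2rad(90 - theta_wall)
  ds_max <- Rw / 600
  shoot <- function(A) {
    res <- yl_wall_integrate(A, c_grav, Rw, ds_max, 500000L)
    if (res$hit) res else NULL
  }
  phi_end <- function(A) {
    res <- shoot(A)
    if (is.null(res)) {  # inclination blew up before the wall
      res2 <- yl_wall_integrate(A, c_grav, Rw, ds_max, 500000L)
      return(sign(res2$phi[length(res2$phi)]) * 10)
    }
    res$phi[length(res$phi)]
  }
  lo <- -5e4; hi <- 5e4
  for (i in 1:90) {
    mid <- (lo + hi) / 2
    f <- phi_end(mid) - target
    if (abs(f) < 1e-9) break
    if (f < 0) lo <- mid else hi <- mid
  }
  res <- shoot(mid)
  if (is.null(res))
    gp_stop("wall meniscus shooting failed to reach the wall",
            "gelplate_solver")
  r <- res$r; zeta <- res$z
  v_shape <- shell_volume(r, zeta)
  z0 <- (volume - v_shape) / (pi * Rw^2)
  z <- z0 + zeta
  if (min(z) < -1e-12 * max(1, abs(max(z))))
    gp_stop("volume too small for a wall-wetted configuration",
            "gelplate_infeasible")
  structure(list(r = r, z = pmax(z, 0), contact_radius = Rw,
                 volume = volume, wall_contact = TRUE,
                 apparent_angle = theta_wall),
            class = "interface_profile")
}

# solid-of-revolution volume under z(r) by cylindrical shells (trapezoid)
shell_volume <- function(r, z) {
  n <- length(r)
  if (n < 2) return(0)
  dr <- diff(r)
  sum(pi * (r[-n] * z[-n] + r[-1] * z[-1]) * dr)
}

#' Recompute the solid-of-revolution volume of a profile
#'
#' @param profile an `interface_profile`.
#' @return volume in m^3 from cylindrical-shell integration of `z(r)`.
#' @export
profile_volume <- function(profile) {
  shell_volume(profile$r, profile$z)
}

#' @export
print.interface_profile <- function(x, ...) {
  cat(sprintf(
    "<interface_profile> rc = %.3f mm, V = %.3f uL, angle = %.2f deg, %s\n",
    x$contact_radius * 1e3, x$volume * 1e9, x$apparent_angle,
    if (x$wall_contact) "wall-wetted" else "pinned cap"))
  invisible(x)
}
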