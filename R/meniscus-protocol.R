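#' Simulate a dispense / re-aspirate protocol with contact-angle hysteresis
#'
#' Steps the liquid volume quasi-statically through the protocol, applying the
#' contact-line rules: while dispensing the line is pinned until the apparent
#' angle reaches the advancing angle, then advances at constant advancing
#' angle; if the footprint reaches the well radius the state switches to the
#' wall-wetted regime.  While aspirating the line is pinned until the angle
#' falls to the receding angle, then recedes at constant receding angle.
#' Aspiration stops at the residual volume (a thin boundary layer; by default
#' the volume of a `film_um` mean film over the pinned footprint).
#'
#' @param protocol a [dispense_protocol()].
#' @param well a [well_geometry()].
#' @param fluid a [fluid_params()].
#' @param wetting a [wetting_params()].
#' @param volume_step quasi-static volume increment, m^3; default 1% of the
#'   largest protocol step.  Must be smaller than every protocol step.
#' @param film_um residual mean film thickness used when the protocol does
#'   not fix `residual_volume`, micrometres.
#' @return A `simulation_result`: `trajectory` (data.frame of volume, contact
#'   radius, apparent angle, pinned flag, regime), `final_profile`,
#'   `flatness`, `coverage`, `wall_contact_ever`, `residual_volume`, `empty`.
#' @export
simulate_protocol <- function(protocol, well = well_geometry(),
                              fluid = fluid_params(),
                              wetting = wetting_params(),
                              volume_step = NULL, film_um = 30) {
  gp_validate(inherits(protocol, "dispense_protocol"),
              "protocol must be a dispense_protocol")
  steps <- protocol$steps
  if (nrow(steps) == 0) {
    return(structure(list(
      trajectory = data.frame(volume = numeric(), contact_radius = numeric(),
                              apparent_angle = numeric(), pinned = logical(),
                              regime = character()),
      final_profile = NULL, flatness = 0, coverage = 0,
      wall_contact_ever = FALSE, residual_volume = 0, empty = TRUE),
      class = "simulation_result"))
  }
  if (is.null(volume_step)) volume_step <- 0.01 * max(steps$volume)
  gp_validate(volume_step > 0, "volume_step must be > 0")
  gp_validate(volume_step < min(steps$volume),
              "volume_step must be smaller than every protocol step")

  Rw <- well$radius
  c_grav <- fluid$density * fluid$gravity / fluid$surface_tension
  th_adv <- wetting$theta_advancing
  th_rec <- wetting$theta_receding
  ds_pin <- Rw / 600

  # lean pinned-cap angle solver (theta <= 90 branch), warm-started
  b_hint <- NULL
  pinned_state <- function(V, rc) {
    vol_at <- function(b) {
      res <- yl_cap_integrate(b, c_grav, 2L, rc, ds_pin, 500000L)
      if (res$hit) res$volume else NA_real_
    }
    lo <- NULL
    if (!is.null(b_hint)) {
      l <- b_hint / 2; h <- b_hint * 2
      vl <- vol_at(l); vh <- vol_at(h)
      if (!is.na(vl) && !is.na(vh) && vl <= V && vh >= V) { lo <- l; hi <- h }
    }
    if (is.null(lo)) {
      hi <- 1 / rc
      while (is.na(vol_at(hi)) && hi > 1e-9 / rc) hi <- hi * 0.85
      lo <- hi * 1e-9
    }
    for (i in 1:100) {
      mid <- sqrt(lo * hi)
      res <- yl_cap_integrate(mid, c_grav, 2L, rc, ds_pin, 500000L)
      v <- if (res$hit) res$volume else Inf
      if (res$hit && abs(v - V) <= 1e-3 * V) break
      if (v > V) hi <- mid else lo <- mid
    }
    b_hint <<- mid
    rad2deg(res$phi[length(res$phi)])
  }
  # footprint of a cap meeting the bottom at theta, warm-started
  a_hint <- NULL
  angle_state <- function(V, theta) {
    th <- deg2rad(theta)
    L <- (6 * V / pi)^(1 / 3) * 4
    ds <- L / 600
    vol_at <- function(b) {
      res <- yl_cap_integrate(b, c_grav, 1L, th, ds, 500000L)
      if (res$hit) res$volume else NA_real_
    }
    lo <- NULL
    if (!is.null(a_hint)) {
      l <- a_hint / 2; h <- a_hint * 2
      vl <- vol_at(l); vh <- vol_at(h)
      if (!is.na(vl) && !is.na(vh) && vh <= V && vl >= V) { lo <- l; hi <- h }
    }
    if (is.null(lo)) { lo <- 1e-3 / L; hi <- 1e5 / L }
    for (i in 1:110) {
      mid <- sqrt(lo * hi)
      res <- yl_cap_integrate(mid, c_grav, 1L, th, ds, 500000L)
      v <- if (res$hit) res$volume else -Inf
      if (res$hit && abs(v - V) <= 1e-3 * V) break
      if (is.finite(v) && v < V) hi <- mid else lo <- mid
    }
    a_hint <<- mid
    res$r[length(res$r)]
  }
  # minimal feasible volume of the wall-wetted configuration (z0 >= 0)
  wall_vmin <- local({
    val <- NULL
    function() {
      if (is.null(val)) {
        prof <- solve_wall_meniscus(pi * Rw^2 * well$height, well, fluid,
                                    wetting$theta_wall)
        val <<- profile_volume(prof) - pi * Rw^2 * min(prof$z)
      }
      val
    }
  })

  regime <- "empty"; V <- 0; rc <- 0
  wall_ever <- FALSE
  residual <- protocol$residual_volume
  tv <- c(); trc <- c(); tang <- c(); tpin <- c(); treg <- c()
  rec <- function(v, r, a, p, g) {
    tv <<- c(tv, v); trc <<- c(trc, r); tang <<- c(tang, a)
    tpin <<- c(tpin, p); treg <<- c(treg, g)
  }

  dispense_to <- function(Vn) {
    if (regime == "wall") { V <<- Vn; rec(Vn, Rw, wetting$theta_wall, FALSE, "wall"); return() }
    if (regime == "cap") {
      ang <- pinned_state(Vn, rc)
      if (ang < th_adv - 1e-7) {
        V <<- Vn; rec(Vn, rc, ang, TRUE, "cap"); return()
      }
    }
    rc_new <- angle_state(Vn, th_adv)
    if (rc_new >= Rw) {
      regime <<- "wall"; wall_ever <<- TRUE; rc <<- Rw; V <<- Vn
      rec(Vn, Rw, wetting$theta_wall, FALSE, "wall")
    } else {
      regime <<- "cap"; rc <<- rc_new; V <<- Vn
      rec(Vn, rc_new, th_adv, FALSE, "cap")
    }
  }
  aspirate_to <- function(Vn) {
    if (regime == "wall") {
      if (Vn >= wall_vmin()) {
        V <<- Vn; rec(Vn, Rw, wetting$theta_wall, FALSE, "wall"); return()
      }
      regime <<- "cap"; rc <<- Rw; b_hint <<- NULL
    }
    if (regime != "cap") return()
    ang <- pinned_state(Vn, rc)
    if (ang > th_rec + 1e-9) {
      V <<- Vn; rec(Vn, rc, ang, TRUE, "cap")
    } else {
      rc_new <- angle_state(Vn, th_rec)
      rc <<- rc_new; V <<- Vn; b_hint <<- NULL
      rec(Vn, rc_new, th_rec, FALSE, "cap")
    }
  }

  for (k in seq_len(nrow(steps))) {
    act <- steps$action[k]; vol <- steps$volume[k]
    if (act == "dispense") {
      targets <- seq_vol(V, V + vol, volume_step)
      for (Vn in targets) dispense_to(Vn)
    } else {
      if (is.null(residual))
        residual <- pi * rc^2 * film_um * 1e-6
      Vend <- max(V - vol, residual, 0)
      if (Vend < V) {
        targets <- sort(unique(c(Vend, seq_vol(Vend, V - volume_step / 2,
                                               volume_step))),
                        decreasing = TRUE)
        for (Vn in targets) if (Vn < V) aspirate_to(Vn)
      }
    }
  }

  final <- switch(regime,
    empty = NULL,
    cap = solve_cap_profile(V, rc, fluid),
    wall = solve_wall_meniscus(V, well, fluid, wetting$theta_wall))
  structure(list(
    trajectory = data.frame(volume = tv, contact_radius = trc,
                            apparent_angle = tang, pinned = tpin,
                            regime = treg),
    final_profile = final,
    flatness = if (is.null(final)) 0 else flatness_metric(final, well),
    coverage = if (is.null(final)) 0 else coverage_metric(final, well),
    wall_contact_ever = wall_ever,
    residual_volume = if (is.null(residual)) 0 else residual,
    empty = is.null(final)),
    class = "simulation_result")
}

# volume targets from a (exclusive) to b (inclusive) in steps of dv
seq_vol <- function(a, b, dv) {
  if (b <= a) return(numeric())
  out <- seq(a + dv, b, by = dv)
  if (length(out) == 0 || tail(out, 1) < b - 1e-15 * b) out <- c(out, b)
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> final V = %.3f uL, coverage = %.1f%%, flatness = %.1f%%, wall contact: %s\n",
    if (x$empty) 0 else x$final_profile$volume * 1e9, x$coverage, x$flatness,
    x$wall_contact_ever))
  invisible(x)
}

#' Robustness sweep over dispensed volume and well radius tolerances
#'
#' Re-runs the dispense/re-aspirate simulation for every combination of the
#' candidate volumes, a relative volume perturbation (-dV, 0, +dV) and a set
#' of well-radius offsets (plate tolerance / robot calibration), and tables
#' wall contact, flatness and coverage.
#'
#' @param volumes candidate dispensed volumes, m^3.
#' @param dV_fraction relative volume perturbation in `[0, 1)`.
#' @param dR_offsets well-radius offsets, m (e.g. `c(-100e-6, -200e-6)`).
#' @param well,fluid,wetting as in [simulate_protocol()].
#' @param volume_step,film_um forwarded to [simulate_protocol()].
#' @return data.frame with one row per combination: `volume_nominal_ul`,
#'   `dv`, `dr_um`, `volume_ul`, `wall_contact`, `flatness`, `coverage`.
#' @export
robustness_sweep <- function(volumes, dV_fraction = 0.2,
                             dR_offsets = c(-100e-6, -200e-6),
                             well = well_geometry(), fluid = fluid_params(),
                             wetting = wetting_params(),
                             volume_step = NULL, film_um = 30) {
  gp_validate(length(volumes) > 0, "volumes must be non-empty")
  gp_validate(dV_fraction >= 0 && dV_fraction < 1,
              "dV_fraction must be in [0, 1)")
  dvs <- if (dV_fraction > 0) c(-dV_fraction, 0, dV_fraction) else 0
  drs <- unique(c(0, dR_offsets))
  grid <- expand.grid(volume = volumes, dv = dvs, dr = drs,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$volume[i] * (1 + grid$dv[i])
    w <- well_geometry(radius = well$radius + grid$dr[i],
                       height = well$height, format_label = well$format_label)
    prot <- dispense_protocol(data.frame(
      action = c("dispense", "aspirate"), volume = c(v, v)))
    sim <- simulate_protocol(prot, w, fluid, wetting,
                             volume_step = volume_step, film_um = film_um)
    data.frame(volume_nominal_ul = grid$volume[i] * 1e9, dv = grid$dv[i],
               dr_um = grid$dr[i] * 1e6, volume_ul = v * 1e9,
               wall_contact = sim$wall_contact_ever,
               flatness = sim$flatness, coverage = sim$coverage)
  })
  do.call(rbind, rows)
}
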