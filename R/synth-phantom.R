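#' Specification of a synthetic well phantom
#'
#' Describes a two-channel confocal z-stack of one well: a bright sidewall
#' ring ("wall" channel) and a bead-speckled gel volume ("gel" channel).
#' Shape classes: `planar` (flat slab), `concave` (slab with a central
#' parabolic sag), `meniscus` (footprint spanning the well, rising at the
#' wall to the top of the stack) and `empty` (noise only).
#'
#' @param shape_class one of `planar`, `concave`, `meniscus`, `empty`.
#' @param well_radius_px well radius in pixels.
#' @param gel_footprint_fraction gel footprint radius / well radius; forced
#'   to 1 for the meniscus class.
#' @param gel_height_um nominal gel height, micrometres.
#' @param sag_depth_um central sag of the concave class, micrometres.
#' @param bead_density fluorescent bead density, beads per cubic micrometre.
#' @param pixel_size_um,z_step_um lateral / axial calibration, micrometres.
#' @param n_slices number of z slices.
#' @param noise named vector `c(gaussian_sd=, poisson_scale=)`; Gaussian read
#'   noise on the 16-bit scale and photon count per unit intensity
#'   (`poisson_scale = 0` disables shot noise).
#' @param center_offset_px integer (dy, dx) offset of the well centre.
#' @param seed RNG seed for bead placement and noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_class = "planar", well_radius_px = 44,
                         gel_footprint_fraction = 0.8, gel_height_um = 60,
                         sag_depth_um = 55, bead_density = 1.2e-4,
                         pixel_size_um = 30, z_step_um = 30, n_slices = 8,
                         noise = c(gaussian_sd = 5, poisson_scale = 80),
                         center_offset_px = c(0, 0), seed = 1) {
  gp_validate(shape_class %in% c("planar", "concave", "meniscus", "empty"),
              "unknown shape_class")
  if (shape_class == "meniscus") gel_footprint_fraction <- 1
  gp_validate(gel_footprint_fraction > 0 && gel_footprint_fraction <= 1,
              "gel_footprint_fraction must be in (0, 1]")
  gp_validate(well_radius_px > 0 && gel_height_um > 0 && pixel_size_um > 0 &&
                z_step_um > 0 && n_slices >= 2, "all sizes must be > 0")
  if (shape_class != "meniscus" &&
      gel_height_um > n_slices * z_step_um)
    gp_stop("gel is taller than the stack extent", "gelplate_validation")
  gp_validate(shape_class != "concave" || sag_depth_um < gel_height_um,
              "sag_depth_um must be below gel_height_um")
  structure(list(shape_class = shape_class, well_radius_px = well_radius_px,
                 gel_footprint_fraction = gel_footprint_fraction,
                 gel_height_um = gel_height_um, sag_depth_um = sag_depth_um,
                 bead_density = bead_density, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, n_slices = n_slices, noise = noise,
                 center_offset_px = center_offset_px, seed = seed),
            class = "phantom_spec")
}

#' Generate a two-channel well phantom z-stack with ground truth
#'
#' Beads are placed by a Poisson point process inside the gel volume, blurred
#' with an isotropic Gaussian PSF per slice (sigma 1.2 px), then degraded
#' with Poisson (photon) and Gaussian (read) noise.  Equal seeds give
#' bit-identical stacks.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` (an [image_stack()], axes z,c,y,x, channels
#'   wall/gel) and `truth` (class, centre, radii, per-pixel height map in
#'   micrometres, bead count).
#' @export
generate_well_phantom <- function(spec) {
  gp_validate(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  # odd side: the well centre falls on a pixel, keeping projections aligned
  side <- 2L * as.integer(ceiling(1.3 * spec$well_radius_px +
                                    max(abs(spec$center_offset_px)))) + 1L
  cy <- (side + 1) / 2 + spec$center_offset_px[1]
  cx <- (side + 1) / 2 + spec$center_offset_px[2]
  yy <- matrix(seq_len(side), side, side)
  xx <- matrix(seq_len(side), side, side, byrow = TRUE)
  rr <- sqrt((yy - cy)^2 + (xx - cx)^2)

  zmax <- spec$n_slices * spec$z_step_um
  rfoot <- spec$gel_footprint_fraction * spec$well_radius_px
  hmap <- matrix(0, side, side)
  inside <- rr <= rfoot
  H <- spec$gel_height_um
  hmap[inside] <- switch(spec$shape_class,
    planar = H,
    concave = H - spec$sag_depth_um * (1 - (rr[inside] / rfoot)^2),
    meniscus = H + (zmax - H) * (rr[inside] / spec$well_radius_px)^6,
    empty = 0)
  if (spec$shape_class == "empty") hmap[] <- 0

  # plate walls are thick relative to the pixel grid at QC magnification
  wall <- 0.9 * (rr >= spec$well_radius_px - 6 &
                   rr <= spec$well_radius_px + 6)
  px <- array(0, c(spec$n_slices, 2L, side, side))

  with_seed(spec$seed, {
    lam <- spec$bead_density * spec$pixel_size_um^2 * hmap
    nb <- rpois(1, sum(lam))
    if (nb > 0) {
      pix <- sample.int(side * side, nb, replace = TRUE, prob = as.vector(lam))
      bz <- runif(nb, 0, hmap[pix])
      by <- yy[pix]; bx <- xx[pix]
    }
    gk <- gauss_kernel(1.2)
    for (k in seq_len(spec$n_slices)) {
      imp <- matrix(0, side, side)
      if (nb > 0) {
        sel <- bz >= (k - 1) * spec$z_step_um & bz < k * spec$z_step_um
        if (any(sel)) {
          ii <- cbind(by[sel], bx[sel])
          for (j in seq_len(nrow(ii)))
            imp[ii[j, 1], ii[j, 2]] <- imp[ii[j, 1], ii[j, 2]] + 0.7
        }
      }
      gel <- as.matrix(EBImage::filter2(EBImage::Image(imp), gk))
      px[k, 1, , ] <- wall
      px[k, 2, , ] <- pmin(pmax(gel, 0), 1)
    }
    gs <- spec$noise[["gaussian_sd"]] / 65535
    ps <- spec$noise[["poisson_scale"]]
    if (ps > 0)
      px[] <- rpois(length(px), as.vector(px) * ps) / ps
    if (gs > 0)
      px[] <- px + rnorm(length(px), 0, gs)
  })
  px <- pmax(px, 0)

  stack <- image_stack(px, c("z", "c", "y", "x"),
                       channel_names = c("wall", "gel"),
                       pixel_size_um = spec$pixel_size_um,
                       z_step_um = spec$z_step_um)
  truth <- list(class = spec$shape_class, center = c(cy, cx),
                well_radius_px = spec$well_radius_px, footprint_px = rfoot,
                height_map_um = hmap,
                n_beads = if (spec$shape_class == "empty") 0L else nb)
  list(stack = stack, truth = truth)
}

gauss_kernel <- function(sigma) {
  n <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  x <- seq_len(n) - (n + 1) / 2
  k <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Generate a synthetic multiwell plate
#'
#' Class counts follow largest-remainder allocation of the composition
#' fractions; classes are assigned to wells in a seeded random order, and
#' each well gets its own derived seed.
#'
#' @param n_wells number of wells (> 0).
#' @param composition named fractions over `planar`, `bad`, `concave`,
#'   `empty` summing to 1 (`bad` renders the meniscus/wall-contact phantom).
#' @param seed master seed.
#' @param ... overrides forwarded to [phantom_spec()].
#' @return list of `list(well_id, stack, truth)`.
#' @export
generate_plate <- function(n_wells,
                           composition = c(planar = 0.91, bad = 0.06,
                                           concave = 0.03),
                           seed = 1, ...) {
  gp_validate(n_wells > 0, "n_wells must be > 0")
  gp_validate(abs(sum(composition) - 1) < 1e-6, "composition must sum to 1")
  counts <- largest_remainder(composition, n_wells)
  classes <- rep(names(counts), counts)
  shape_of <- c(planar = "planar", bad = "meniscus", concave = "concave",
                empty = "empty")
  gp_validate(all(names(counts) %in% names(shape_of)),
              "unknown class in composition")
  seeds <- derive_seeds(seed, n_wells + 1)
  classes <- with_seed(seeds[1], sample(classes))
  ncol_plate <- 12L
  lapply(seq_len(n_wells), function(i) {
    wid <- sprintf("%s%02d", LETTERS[(i - 1) %/% ncol_plate + 1],
                   (i - 1) %% ncol_plate + 1)
    sp <- phantom_spec(shape_class = shape_of[[classes[i]]],
                       seed = seeds[i + 1], ...)
    ph <- generate_well_phantom(sp)
    list(well_id = wid, stack = ph$stack, truth = ph$truth)
  })
}

# integer allocation of n items by fractions (largest remainder, ties by
# position)
largest_remainder <- function(fractions, n) {
  exact <- fractions * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}
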