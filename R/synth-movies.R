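#' Generate a synthetic confluency time-lapse with logistic growth
#'
#' The true covered-area fraction follows discrete logistic growth
#' `C[t+1] = C[t] + r(dose) C[t] (1 - C[t])` with the per-frame growth rate
#' suppressed by a Hill function of the drug dose,
#' `r(dose) = r0 / (1 + (dose / ic50_true)^hill)`.  Frames render cells as
#' textured disks placed (cumulatively across frames) until the rendered
#' covered fraction matches the true `C[t]` within one area-percent.
#'
#' @param dose drug dose (generator units, e.g. ng/mL).
#' @param ic50_true true half-maximal dose of the growth-rate suppression.
#' @param hill Hill exponent of the suppression.
#' @param r0 unsuppressed per-frame growth rate.
#' @param n_frames number of frames (>= 2; hourly default covers 48 h).
#' @param cell_radius_px rendered cell radius, pixels.
#' @param seed RNG seed.
#' @param frame_px frame side, pixels.
#' @param c0 initial covered fraction.
#' @param noise_sd additive Gaussian noise on the rendered frames.
#' @return list with `stack` (axes t,y,x) and `truth` (`confluency_true`,
#'   `confluency_rendered`, both fractions per frame, and `rate`).
#' @export
generate_confluency_movie <- function(dose, ic50_true = 18, hill = 2,
                                      r0 = 0.04, n_frames = 49,
                                      cell_radius_px = 4, seed = 1,
                                      frame_px = 96, c0 = 0.03,
                                      noise_sd = 0.02) {
  gp_validate(dose >= 0 && ic50_true > 0 && hill > 0 && r0 > 0,
              "rates and doses must be positive (dose may be 0)")
  gp_validate(n_frames >= 2, "need at least 2 frames")
  r <- r0 / (1 + (dose / ic50_true)^hill)
  C <- numeric(n_frames)
  C[1] <- c0
  for (t in seq_len(n_frames - 1)) C[t + 1] <- C[t] + r * C[t] * (1 - C[t])

  off <- disk_offsets(cell_radius_px)
  n <- frame_px
  px <- array(0, c(n_frames, n, n))
  rendered <- numeric(n_frames)
  with_seed(seed, {
    covered <- matrix(FALSE, n, n)
    tex <- matrix(0, n, n)   # per-pixel cell texture, fixed per cell placement
    for (t in seq_len(n_frames)) {
      frac <- mean(covered)
      guard <- 0
      while (frac < C[t] - 0.005 && guard < 5000) {
        ccy <- sample.int(n, 1); ccx <- sample.int(n, 1)
        iy <- off[, 1] + ccy; ix <- off[, 2] + ccx
        ok <- iy >= 1 & iy <= n & ix >= 1 & ix <= n
        idx <- cbind(iy[ok], ix[ok])
        covered[idx] <- TRUE
        tex[idx] <- pmax(tex[idx],
                         0.45 + 0.25 * off[ok, 3] +
                           rnorm(sum(ok), 0, 0.05))
        frac <- mean(covered)
        guard <- guard + 1
      }
      fr <- matrix(0.12, n, n)
      fr[covered] <- pmin(pmax(tex[covered], 0.3), 1)
      if (noise_sd > 0) fr <- fr + rnorm(n * n, 0, noise_sd)
      px[t, , ] <- pmin(pmax(fr, 0), 1)
      rendered[t] <- frac
    }
  })
  stack <- image_stack(px, c("t", "y", "x"), pixel_size_um = 1,
                       time_step_min = 60)
  list(stack = stack,
       truth = list(confluency_true = C, confluency_rendered = rendered,
                    rate = r))
}

# disk pixel offsets with a radial falloff weight column
disk_offsets <- function(radius) {
  d <- as.integer(ceiling(radius))
  g <- expand.grid(dy = -d:d, dx = -d:d)
  rr <- sqrt(g$dy^2 + g$dx^2)
  keep <- rr <= radius
  cbind(g$dy[keep], g$dx[keep], 1 - (rr[keep] / radius)^2)
}

#' Generate a synthetic FUCCI 4-channel time-lapse with ground truth
#'
#' Each nucleus runs the cycle state machine EG1 -> G1 -> S/G2 -> T -> M and
#' re-enters EG1 after division.  Channel intensities per state: G1 cyan
#' high; S/G2 magenta high; T both high; EG1 both low; M magenta high with
#' nuclear tubulin elevated above the cytoplasm background by a factor above
#' the mitotic detection threshold.  A `mitotic_fraction` of cells is
#' arrested in M (drug-like behaviour); a `fragment_fraction` gets a nuclear
#' area below half the population mean; `bleedthrough` adds that multiple of
#' the cyan channel onto the tubulin (green) channel.
#'
#' @param n_cells,n_frames scene size.
#' @param phase_durations named vector of phase lengths in frames
#'   (`EG1`, `G1`, `SG2`, `T`, `M`).
#' @param mitotic_fraction fraction of cells arrested in M.
#' @param fragment_fraction fraction of cells with fragmented nuclei.
#' @param bleedthrough linear cyan -> tubulin bleed-through coefficient.
#' @param seed RNG seed.
#' @param frame_px frame side, pixels.
#' @param pixel_size_um lateral calibration.
#' @param nucleus_radius_px nominal nuclear radius, pixels.
#' @param noise_sd additive Gaussian noise.
#' @return list with `stack` (axes t,c,y,x; channels actin, tubulin, cyan,
#'   magenta), `truth` (data.frame per frame x cell: positions, cycle class,
#'   mitotic / fragmented flags, track id) and `labels` (t,y,x label array).
#' @export
generate_fucci_timelapse <- function(n_cells = 40, n_frames = 12,
                                     phase_durations = c(EG1 = 2, G1 = 6,
                                                         SG2 = 8, T = 2,
                                                         M = 2),
                                     mitotic_fraction = 0,
                                     fragment_fraction = 0,
                                     bleedthrough = 0, seed = 1,
                                     frame_px = 192, pixel_size_um = 1,
                                     nucleus_radius_px = 5, noise_sd = 0) {
  gp_validate(all(phase_durations > 0), "phase durations must be > 0")
  gp_validate(mitotic_fraction >= 0 && mitotic_fraction <= 1 &&
                fragment_fraction >= 0 && fragment_fraction <= 1,
              "fractions must be in [0, 1]")
  gp_validate(bleedthrough >= 0, "bleedthrough must be >= 0")
  phases <- c("EG1", "G1", "SG2", "T", "M")
  durs <- phase_durations[phases]
  cyc <- sum(durs)
  cls_of <- rep(c("EG1", "G1", "SG2M", "T", "SG2M"), durs)  # reported class
  mito_of <- rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), durs)

  spacing <- 4 * nucleus_radius_px
  per_row <- floor(frame_px / spacing)
  gp_validate(per_row^2 >= n_cells,
              "too many cells for the frame at this nucleus radius")
  n <- frame_px
  px <- array(0, c(n_frames, 4L, n, n))
  labels <- array(0L, c(n_frames, n, n))
  rows <- list()
  bg <- 0.02; tub_cyto <- 0.2; hi <- 0.6; mito_boost <- 1.6

  with_seed(seed, {
    slots <- sample.int(per_row^2, n_cells)
    x0 <- ((slots - 1) %% per_row) * spacing + spacing / 2 +
      runif(n_cells, -1, 1)
    y0 <- ((slots - 1) %/% per_row) * spacing + spacing / 2 +
      runif(n_cells, -1, 1)
    arrested <- seq_len(n_cells) <= round(mitotic_fraction * n_cells)
    nfrag <- round(fragment_fraction * n_cells)
    fragmented <- rep(FALSE, n_cells)
    if (nfrag > 0)
      fragmented[sample(which(!arrested),
                        min(nfrag, sum(!arrested)))] <- TRUE
    offset <- sample.int(cyc, n_cells, replace = TRUE) - 1L
    radii <- ifelse(fragmented, nucleus_radius_px * 0.63, nucleus_radius_px)
    for (t in seq_len(n_frames)) {
      act <- matrix(bg, n, n); tub <- matrix(bg, n, n)
      cyn <- matrix(bg, n, n); mag <- matrix(bg, n, n)
      lab <- matrix(0L, n, n)
      dy <- rnorm(n_cells, 0, 0.8); dx <- rnorm(n_cells, 0, 0.8)
      y0 <- pmin(pmax(y0 + dy, spacing / 2), n - spacing / 2)
      x0 <- pmin(pmax(x0 + dx, spacing / 2), n - spacing / 2)
      for (i in seq_len(n_cells)) {
        ph_idx <- (offset[i] + t - 1L) %% cyc + 1L
        cls <- if (arrested[i]) "SG2M" else cls_of[ph_idx]
        mito <- if (arrested[i]) TRUE else mito_of[ph_idx]
        noff <- disk_offsets(radii[i])
        coff <- disk_offsets(2.2 * nucleus_radius_px)
        cyi <- round(y0[i]); cxi <- round(x0[i])
        nidx <- clip_idx(noff, cyi, cxi, n)
        cidx <- clip_idx(coff, cyi, cxi, n)
        act[cidx] <- 0.3
        tub[cidx] <- pmax(tub[cidx], tub_cyto)
        if (mito) tub[nidx] <- tub_cyto * mito_boost
        ch <- switch(if (mito) "M" else cls,
                     EG1 = c(0, 0), G1 = c(hi, 0), SG2M = c(0, hi),
                     T = c(hi, hi), M = c(0, hi))
        cyn[nidx] <- bg + ch[1]
        mag[nidx] <- bg + ch[2]
        lab[nidx] <- i
        rows[[length(rows) + 1]] <- data.frame(
          frame = t, cell = i, y = y0[i], x = x0[i],
          cycle_class = cls, mitotic = mito, fragmented = fragmented[i],
          area_px = nrow(noff))
      }
      tub <- tub + bleedthrough * cyn
      if (noise_sd > 0) {
        act <- act + rnorm(n * n, 0, noise_sd)
        tub <- tub + rnorm(n * n, 0, noise_sd)
        cyn <- cyn + rnorm(n * n, 0, noise_sd)
        mag <- mag + rnorm(n * n, 0, noise_sd)
      }
      px[t, 1, , ] <- pmax(act, 0); px[t, 2, , ] <- pmax(tub, 0)
      px[t, 3, , ] <- pmax(cyn, 0); px[t, 4, , ] <- pmax(mag, 0)
      labels[t, , ] <- lab
    }
  })
  stack <- image_stack(px, c("t", "c", "y", "x"),
                       channel_names = c("actin", "tubulin", "cyan",
                                         "magenta"),
                       pixel_size_um = pixel_size_um, time_step_min = 15)
  list(stack = stack, truth = do.call(rbind, rows), labels = labels)
}

clip_idx <- function(off, cy, cx, n) {
  iy <- off[, 1] + cy; ix <- off[, 2] + cx
  ok <- iy >= 1 & iy <= n & ix >= 1 & ix <= n
  cbind(iy[ok], ix[ok])
}

#' Generate a dry-state profilometry height map with instrument background
#'
#' Revolves a radial gel profile into a 2D height map and adds a quadratic
#' instrument background (spherical aberration / substrate curvature
#' surrogate) plus Gaussian noise.
#'
#' @param profile data.frame with columns `r_um` (ascending from 0) and
#'   `h_um`; heights beyond the last radius are zero (bare substrate).
#' @param background_poly2 coefficients `c(a, bx, cy, dxx, exy, fyy)` of the
#'   quadratic background in centred pixel coordinates.
#' @param noise_sd Gaussian noise SD, micrometres.
#' @param seed RNG seed.
#' @param map_px map side, pixels.
#' @param pixel_size_um lateral calibration.
#' @return list with `map` (a [height_map()]), and `truth` (noise-free gel
#'   surface, gel and substrate masks, background matrix).
#' @export
generate_dry_height_map <- function(profile, background_poly2 = rep(0, 6),
                                    noise_sd = 0, seed = 1, map_px = 128,
                                    pixel_size_um = 10) {
  gp_validate(is.data.frame(profile) &&
                all(c("r_um", "h_um") %in% names(profile)),
              "profile needs columns r_um, h_um")
  gp_validate(length(background_poly2) == 6,
              "background_poly2 needs 6 coefficients (order <= 2)")
  n <- map_px
  cy <- (n + 1) / 2; cx <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n) - cy
  xx <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  rr_um <- sqrt(yy^2 + xx^2) * pixel_size_um
  gel <- matrix(stats::approx(profile$r_um, profile$h_um, xout = rr_um,
                              yleft = profile$h_um[1], yright = 0,
                              rule = 2)$y, n, n)
  gel[rr_um > max(profile$r_um)] <- 0
  p <- background_poly2
  bgm <- p[1] + p[2] * xx + p[3] * yy + p[4] * xx^2 + p[5] * xx * yy +
    p[6] * yy^2
  hm <- gel + bgm
  if (noise_sd > 0)
    hm <- hm + with_seed(seed, matrix(rnorm(n * n, 0, noise_sd), n, n))
  map <- height_map(hm - min(hm, 0), pixel_size_um = pixel_size_um,
                    source = "profilometer")
  list(map = map,
       truth = list(gel_um = gel, background_um = bgm,
                    gel_mask = gel > 0, substrate_mask = gel == 0))
}
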