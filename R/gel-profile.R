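#' Per-pixel gel height map
#'
#' @param heights numeric matrix of gel heights, micrometres (0 where no
#'   signal).
#' @param pixel_size_um lateral pixel size.
#' @param center optional (row, col) footprint centre.
#' @param source `"zstack"` or `"profilometer"`.
#' @param nonnegative enforce `heights >= 0` (detrended maps carry residual
#'   negatives and disable this).
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size_um, center = NULL,
                       source = "zstack", nonnegative = TRUE) {
  heights <- as.matrix(heights)
  gp_validate(all(is.finite(heights)), "heights must be finite")
  if (nonnegative)
    gp_validate(min(heights) >= 0, "heights must be >= 0")
  gp_validate(pixel_size_um > 0, "pixel_size_um must be > 0")
  structure(list(heights = heights, pixel_size_um = pixel_size_um,
                 center = center, source = source), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %dx%d px (%.2f um/px), range %.2f..%.2f um, %s\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_um,
              min(x$heights), max(x$heights), x$source))
  invisible(x)
}

#' Extract a gel height map from a bead z-stack
#'
#' Otsu threshold on the global stack histogram, per-slice morphological
#' closing (2 px disk), then per (x, y) column the height is the z distance
#' between the first and last detected signals times the z step.  A column
#' with signal in a single slice yields 0 by this first-to-last convention;
#' `inclusive = TRUE` adds one z step instead.
#'
#' @param zstack single-channel [image_stack()] with >= 2 z slices, or a
#'   (z, y, x) array.
#' @param z_step_um axial step; defaults to the stack metadata.
#' @param inclusive use the (last - first + 1) convention.
#' @param per_slice threshold each slice separately instead of globally.
#' @return A [height_map()] (micrometres).
#' @export
extract_height_map <- function(zstack, z_step_um = NULL, inclusive = FALSE,
                               per_slice = FALSE) {
  if (inherits(zstack, "image_stack")) {
    st <- canonical_stack(zstack)
    arr <- if ("c" %in% st$axes) stack_channel(st, 1) else st$pixels
    if (is.null(z_step_um)) z_step_um <- st$z_step_um
  } else arr <- zstack
  gp_validate(!is.null(z_step_um) && is.finite(z_step_um) && z_step_um > 0,
              "z_step_um is required")
  gp_validate(length(dim(arr)) == 3 && dim(arr)[1] >= 2,
              "need a single-channel z-stack with >= 2 slices")
  nz <- dim(arr)[1]
  arrn <- norm01(arr)
  mask <- array(FALSE, dim(arr))
  if (per_slice) {
    for (k in seq_len(nz)) {
      sl <- arrn[k, , ]
      thr <- EBImage::otsu(EBImage::Image(sl))
      mask[k, , ] <- sl > thr
    }
  } else {
    thr <- EBImage::otsu(EBImage::Image(matrix(as.vector(arrn), ncol = 1)))
    mask <- arrn > thr
  }
  if (!any(mask)) gp_stop("no voxels above threshold", "gelplate_empty_map")
  for (k in seq_len(nz))
    mask[k, , ] <- EBImage::closing(mask[k, , ] * 1, brush5()) > 0
  first <- apply(mask, c(2, 3), function(v) {
    w <- which(v); if (length(w)) w[1] else NA_integer_ })
  last <- apply(mask, c(2, 3), function(v) {
    w <- which(v); if (length(w)) w[length(w)] else NA_integer_ })
  h <- (last - first + as.integer(inclusive)) * z_step_um
  h[is.na(h)] <- 0
  idx <- which(h > 0, arr.ind = TRUE)
  ctr <- if (nrow(idx)) colMeans(idx) else NULL
  ps <- if (inherits(zstack, "image_stack") &&
            is.finite(zstack$pixel_size_um)) zstack$pixel_size_um else 1
  height_map(h, pixel_size_um = ps, center = ctr, source = "zstack")
}

# centred moving average with shrink-to-valid edges; even windows take
# floor((w-1)/2) points to the left and the rest to the right
moving_avg <- function(x, window) {
  n <- length(x)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - left):min(n, i + right)])
  }, 0)
}

#' Radial height profile along a diameter
#'
#' Takes the row through the footprint centroid and smooths it with a
#' centred moving average (shrinking window at the edges).
#'
#' @param map a [height_map()].
#' @param smoothing_window_px moving-average window, pixels.
#' @return data.frame with `pos_px`, `pos_um`, `height_raw_um`, `height_um`.
#' @export
radial_profile <- function(map, smoothing_window_px = 15) {
  h <- map$heights
  idx <- which(h > 0, arr.ind = TRUE)
  gp_validate(nrow(idx) > 0, "empty height map")
  ctr <- if (!is.null(map$center)) map$center else colMeans(idx)
  extent <- diff(range(idx[, 2])) + 1
  gp_validate(extent >= smoothing_window_px,
              "footprint smaller than the smoothing window")
  row <- h[round(ctr[1]), ]
  sm <- moving_avg(row, smoothing_window_px)
  data.frame(pos_px = seq_along(row),
             pos_um = (seq_along(row) - ctr[2]) * map$pixel_size_um,
             height_raw_um = row, height_um = sm)
}

#' Two-plane thickness summary over fields of view
#'
#' Thickness per FOV is the z distance between the gel-top plane and the
#' substrate plane; flatness is reported as the SD of the per-FOV
#' thicknesses.
#'
#' @param z_top gel-top z positions, micrometres (one per FOV).
#' @param z_bottom substrate z position(s), micrometres (scalar or per FOV).
#' @return A `thickness_summary`: `thickness_um` (per FOV), `mean_um`,
#'   `flatness_sd_um`, `n_fov`.
#' @export
two_plane_thickness <- function(z_top, z_bottom) {
  gp_validate(length(z_top) >= 1, "need at least one FOV")
  gp_validate(length(z_bottom) %in% c(1, length(z_top)),
              "z_bottom must be scalar or one per FOV")
  th <- z_top - z_bottom
  gp_validate(all(th >= 0), "z_top must be >= z_bottom")
  structure(list(thickness_um = th, mean_um = mean(th),
                 flatness_sd_um = if (length(th) > 1) sd(th) else 0,
                 n_fov = length(th)), class = "thickness_summary")
}

#' @export
print.thickness_summary <- function(x, ...) {
  cat(sprintf("<thickness_summary> %.2f +/- %.2f um (SD over %d FOVs)\n",
              x$mean_um, x$flatness_sd_um, x$n_fov))
  invisible(x)
}

#' Detrend a dry-state profilometry map
#'
#' Fits `z = a + bx + cy + dx^2 + exy + fy^2` to the bare-substrate pixels
#' by least squares and subtracts it everywhere, removing instrument
#' background (aberration, substrate curvature).  Idempotent within
#' numerical tolerance.
#'
#' @param map a [height_map()].
#' @param substrate_mask logical matrix of bare-substrate pixels (>= 6).
#' @return A detrended [height_map()] (may contain residual negatives).
#' @export
detrend_dry_map <- function(map, substrate_mask) {
  h <- map$heights
  gp_validate(identical(dim(substrate_mask), dim(h)),
              "substrate_mask shape mismatch")
  gp_validate(sum(substrate_mask) >= 6,
              "need >= 6 substrate pixels for a quadratic fit")
  n <- nrow(h); m <- ncol(h)
  yy <- matrix(seq_len(n), n, m) - (n + 1) / 2
  xx <- matrix(seq_len(m), n, m, byrow = TRUE) - (m + 1) / 2
  df <- data.frame(z = h[substrate_mask], x = xx[substrate_mask],
                   y = yy[substrate_mask])
  fit <- lm(z ~ x + y + I(x^2) + I(x * y) + I(y^2), data = df)
  bg <- matrix(predict(fit, newdata = data.frame(x = as.vector(xx),
                                                 y = as.vector(yy))), n, m)
  height_map(h - bg, pixel_size_um = map$pixel_size_um, center = map$center,
             source = map$source, nonnegative = FALSE)
}

#' Centre cross-cuts with thickness and flatness estimates
#'
#' Extracts x- and y-cuts through the footprint centroid.  Thickness is the
#' mean over the central half of the gel extent; flatness is the fraction of
#' the gel extent along the cut where the local slope stays within 3 degrees
#' (the planarity convention of the meniscus model).
#'
#' @param map a [height_map()].
#' @param height_floor_um heights below this are treated as substrate.
#' @return list with `x_cut`, `y_cut` (data.frames pos_um/height_um),
#'   `thickness_um`, `flatness_pct` (mean over the two cuts) and the
#'   per-cut values.
#' @export
cross_cuts <- function(map, height_floor_um = NULL) {
  h <- map$heights
  idx <- which(h > 0, arr.ind = TRUE)
  gp_validate(nrow(idx) > 0, "empty height map")
  ctr <- if (!is.null(map$center)) map$center else colMeans(idx)
  if (is.null(height_floor_um)) height_floor_um <- 0.05 * max(h)
  cut_stats <- function(v, centre_idx) {
    pos <- (seq_along(v) - centre_idx) * map$pixel_size_um
    gel <- which(v > height_floor_um)
    if (length(gel) < 3)
      return(list(df = data.frame(pos_um = pos, height_um = v),
                  thickness = 0, flatness = 0))
    span <- range(gel)
    mid <- round(mean(span))
    halfw <- floor(diff(span) / 4)
    plateau <- v[(mid - halfw):(mid + halfw)]
    slopes <- abs(diff(v)) / map$pixel_size_um
    seg <- gel[gel < length(v)]
    planar <- sum(slopes[seg] <= tan(deg2rad(3)))
    list(df = data.frame(pos_um = pos, height_um = v),
         thickness = mean(plateau),
         flatness = 100 * planar / length(seg))
  }
  xs <- cut_stats(h[round(ctr[1]), ], ctr[2])
  ys <- cut_stats(h[, round(ctr[2])], ctr[1])
  list(x_cut = xs$df, y_cut = ys$df,
       thickness_um = mean(c(xs$thickness, ys$thickness)),
       flatness_pct = mean(c(xs$flatness, ys$flatness)),
       x_thickness_um = xs$thickness, y_thickness_um = ys$thickness,
       x_flatness_pct = xs$flatness, y_flatness_pct = ys$flatness)
}

#' Swelling ratio
#'
#' Hydrated thickness over dry thickness.
#'
#' @param hydrated_um hydrated gel thickness, micrometres.
#' @param dry_um dry gel thickness, micrometres (> 0).
#' @return unitless ratio (vectorized).
#' @export
swelling_ratio <- function(hydrated_um, dry_um) {
  gp_validate(all(dry_um > 0), "dry thickness must be > 0")
  hydrated_um / dry_um
}
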