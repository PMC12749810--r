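#' Preprocess a two-channel well z-stack for QC
#'
#' Computes per-channel maximum-intensity projections, recentres them on the
#' detected wall-ring centroid (rotation is a no-op for circular wells and is
#' omitted) and crops to a square of side 2.2 x the detected wall radius.
#'
#' @param stack an [image_stack()] with a z axis and two channels
#'   (wall, gel).
#' @param wall_ch,gel_ch channel names or indices.
#' @return list with `wall_mip`, `gel_mip`, `center` (row, col in the
#'   original frame), `wall_radius_px` and `empty` (TRUE when no wall ring is
#'   detectable, in which case the projections are returned uncropped).
#' @export
preprocess_well <- function(stack, wall_ch = "wall", gel_ch = "gel") {
  stack <- canonical_stack(stack)
  gp_validate("z" %in% stack$axes && "c" %in% stack$axes,
              "stack needs z and c axes")
  wall_mip <- mip_z(stack_channel(stack, wall_ch))
  gel_mip <- mip_z(stack_channel(stack, gel_ch))
  wn <- norm01(wall_mip)
  lev <- tryCatch(triangle_threshold(hist256(wn)),
                  gelplate_degenerate = function(e) NULL)
  mask <- if (is.null(lev)) wn > 2 else apply_level(wn, lev)
  if (sum(mask) < 20)
    return(list(wall_mip = wall_mip, gel_mip = gel_mip, center = NULL,
                wall_radius_px = NA_real_, empty = TRUE))
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  radius <- mean(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
  side <- dim(wall_mip)
  target <- (side + 1) / 2
  shift <- round(target - ctr)
  wall_mip <- shift_img(wall_mip, shift)
  gel_mip <- shift_img(gel_mip, shift)
  half <- round(1.1 * radius)
  r0 <- max(1, round(target[1]) - half); r1 <- min(side[1], round(target[1]) + half)
  c0 <- max(1, round(target[2]) - half); c1 <- min(side[2], round(target[2]) + half)
  list(wall_mip = wall_mip[r0:r1, c0:c1], gel_mip = gel_mip[r0:r1, c0:c1],
       center = ctr, wall_radius_px = radius, empty = FALSE)
}

# integer translation with zero padding
shift_img <- function(img, shift) {
  out <- img * 0
  d <- dim(img)
  sr <- shift[1]; sc <- shift[2]
  src_r <- max(1, 1 - sr):min(d[1], d[1] - sr)
  src_c <- max(1, 1 - sc):min(d[2], d[2] - sc)
  if (length(src_r) < 1 || length(src_c) < 1) return(out)
  out[src_r + sr, src_c + sc] <- img[src_r, src_c]
  out
}

brush5 <- function() EBImage::makeBrush(5, shape = "disc")

# fill holes smaller than max_px (keeps the large central cavity of a ring)
fill_small_holes <- function(mask, max_px) {
  filled <- EBImage::fillHull(mask * 1) > 0
  holes <- filled & !mask
  if (!any(holes)) return(mask)
  lab <- EBImage::bwlabel(holes * 1)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes <= max_px)
  mask | (array(lab, dim(lab)) %in% small & holes)
}

qc_mask_chain <- function(mip, method = c("triangle", "isodata"),
                          fill_all = FALSE, outlier_radius = 10) {
  method <- match.arg(method)
  img <- norm01(mip)^0.5  # gamma 0.5 on the normalized range
  lev <- tryCatch(
    switch(method, triangle = triangle_threshold(hist256(img)),
           isodata = isodata_threshold(hist256(img))),
    gelplate_degenerate = function(e) NULL)
  if (is.null(lev)) return(matrix(FALSE, nrow(mip), ncol(mip)))
  m <- apply_level(img, lev)
  m <- EBImage::opening(m * 1, brush5()) > 0
  m <- EBImage::closing(m * 1, brush5()) > 0
  m <- if (fill_all) EBImage::fillHull(m * 1) > 0
       else fill_small_holes(m, max_px = 100)
  if (any(m) && outlier_radius > 0) {
    # bright-outlier removal: a pixel deviating above its local median is
    # replaced by it; on a binary mask this strips specks, never adds
    med <- EBImage::medianFilter(m * 1, outlier_radius) >= 0.5
    m <- m & med
  }
  matrix(m, nrow(mip), ncol(mip))
}

#' Well-wall ring mask
#'
#' Gamma correction (0.5), triangle auto-threshold, opening/closing (2 px
#' disk), small-hole filling, median outlier removal (10 px radius).  The
#' cleaned ring band is returned; its boundary (binary edge) is available via
#' [mask_boundary()].
#'
#' @param wall_mip wall-channel maximum-intensity projection.
#' @return logical matrix (ring band); all-FALSE signals an empty well.
#' @export
wall_mask <- function(wall_mip) {
  qc_mask_chain(wall_mip, "triangle", fill_all = FALSE)
}

#' Gel footprint mask
#'
#' Same chain as [wall_mask()] with the isodata ("Default") threshold and
#' full hole filling, returning the filled gel footprint.
#'
#' @param gel_mip gel-channel maximum-intensity projection.
#' @return logical matrix; all-FALSE signals an empty well.
#' @export
gel_mask <- function(gel_mip) {
  qc_mask_chain(gel_mip, "isodata", fill_all = TRUE)
}

#' Binary mask boundary (edge detection on a binary image)
#'
#' @param mask logical matrix.
#' @return logical matrix of boundary pixels.
#' @export
mask_boundary <- function(mask) {
  er <- EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0
  mask & !er
}

#' Wall-contact detection
#'
#' Logical AND between the gel and wall masks; contact is declared when the
#' overlap exceeds `min_overlap` pixels (the bare AND rule is recovered with
#' `min_overlap = 0`).
#'
#' @param gel_mask,wall_mask same-shape logical matrices.
#' @param min_overlap overlap pixels strictly above which contact is called.
#' @return list with `contact` (logical) and `overlap_px` (count).
#' @export
detect_wall_contact <- function(gel_mask, wall_mask, min_overlap = 5) {
  gp_validate(identical(dim(gel_mask), dim(wall_mask)),
              "mask shapes differ")
  ov <- sum(gel_mask & wall_mask)
  list(contact = ov > min_overlap, overlap_px = ov)
}

#' Planar / concave shape call on the gel projection
#'
#' Secondary analysis: gamma 2, isodata auto-threshold, closing; the mean of
#' the binarized projection (0/255) over the gel footprint is the fill
#' metric, and the well is planar when it reaches 250 (i.e. ~98% of the
#' footprint stays above threshold).
#'
#' @param gel_mip gel-channel projection.
#' @param footprint logical footprint mask from [gel_mask()].
#' @return list with `class` ("planar"/"concave") and `gel_fill_mean`
#'   (0-255).
#' @export
shape_class <- function(gel_mip, footprint) {
  gp_validate(any(footprint), "empty gel footprint")
  img <- norm01(gel_mip)^2  # gamma 2 on the normalized range
  lev <- tryCatch(isodata_threshold(hist256(img)),
                  gelplate_degenerate = function(e) NULL)
  if (is.null(lev))
    return(list(class = "concave", gel_fill_mean = 0))
  m <- apply_level(img, lev)
  m <- EBImage::closing(m * 1, brush5()) > 0
  fill <- mean(255 * m[footprint])
  list(class = if (fill >= 250) "planar" else "concave",
       gel_fill_mean = fill)
}

#' Classify one well from its two-channel z-stack
#'
#' Chain: undetectable wall ring or empty gel mask gives "empty"; gel-wall
#' overlap gives "bad"; otherwise the planar/concave shape call.
#'
#' @inheritParams preprocess_well
#' @param min_overlap wall-contact overlap threshold, pixels.
#' @param well_id identifier carried into the record.
#' @return one-row data.frame: `well_id`, `qc_class`, `wall_overlap_px`,
#'   `gel_fill_mean`, `footprint_area_px`.
#' @export
classify_well <- function(stack, wall_ch = "wall", gel_ch = "gel",
                          min_overlap = 5, well_id = NA_character_) {
  pre <- preprocess_well(stack, wall_ch, gel_ch)
  rec <- function(cls, ov = 0, fill = 0, area = 0)
    data.frame(well_id = well_id, qc_class = cls, wall_overlap_px = ov,
               gel_fill_mean = fill, footprint_area_px = area,
               stringsAsFactors = FALSE)
  if (pre$empty) return(rec("empty"))
  wm <- wall_mask(pre$wall_mip)
  if (!any(wm)) return(rec("empty"))
  gm <- gel_mask(pre$gel_mip)
  if (sum(gm) < 20) return(rec("empty"))
  ct <- detect_wall_contact(gm, wm, min_overlap)
  if (ct$contact)
    return(rec("bad", ov = ct$overlap_px, area = sum(gm)))
  sc <- shape_class(pre$gel_mip, gm)
  rec(sc$class, ov = ct$overlap_px, fill = sc$gel_fill_mean, area = sum(gm))
}

qc_colors <- c(planar = "green", bad = "red", concave = "yellow",
               empty = "gray", error = "magenta")

#' Plate-scale QC report
#'
#' Classifies every well, aggregates class fractions and renders a tiled
#' montage of gel projections with class-colored frames (green planar, red
#' wall contact, yellow concave).  A well whose classification fails is
#' recorded as class "error" without aborting the plate.
#'
#' @param wells list of `list(well_id=, stack=)` (e.g. from
#'   [generate_plate()]).
#' @param out_dir optional output directory: writes `plate_qc.csv`,
#'   `plate_report.png` and `summary.json`.
#' @inheritParams classify_well
#' @return A `plate_report`: `records` (data.frame), `class_fractions`
#'   (percent, sums to 100) and `tile_image` (EBImage RGB montage).
#' @export
qc_plate <- function(wells, wall_ch = "wall", gel_ch = "gel",
                     min_overlap = 5, out_dir = NULL) {
  recs <- vector("list", length(wells))
  tiles <- vector("list", length(wells))
  tile_side <- 96L
  for (i in seq_along(wells)) {
    w <- wells[[i]]
    recs[[i]] <- tryCatch(
      classify_well(w$stack, wall_ch, gel_ch, min_overlap,
                    well_id = w$well_id),
      error = function(e)
        data.frame(well_id = w$well_id, qc_class = "error",
                   wall_overlap_px = NA, gel_fill_mean = NA,
                   footprint_area_px = NA, stringsAsFactors = FALSE))
    tiles[[i]] <- tryCatch({
      pre <- preprocess_well(w$stack, wall_ch, gel_ch)
      resize_square(norm01(pre$gel_mip), tile_side)
    }, error = function(e) matrix(0, tile_side, tile_side))
  }
  records <- do.call(rbind, recs)
  fr <- table(factor(records$qc_class, levels = names(qc_colors)))
  class_fractions <- 100 * as.numeric(fr) / nrow(records)
  names(class_fractions) <- names(qc_colors)
  rgb <- lapply(seq_along(tiles), function(i)
    frame_tile(tiles[[i]], qc_colors[[records$qc_class[i]]]))
  nx <- ceiling(sqrt(length(rgb)))
  montage <- EBImage::tile(EBImage::combine(rgb), nx = nx, lwd = 1)
  rep <- structure(list(records = records,
                        class_fractions = class_fractions,
                        tile_image = montage),
                   class = "plate_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(records, file.path(out_dir, "plate_qc.csv"), row.names = FALSE)
    EBImage::writeImage(montage, file.path(out_dir, "plate_report.png"))
    jsonlite::write_json(as.list(class_fractions),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.plate_report <- function(x, ...) {
  cat("<plate_report>", nrow(x$records), "wells;",
      paste(sprintf("%s %.1f%%", names(x$class_fractions),
                    x$class_fractions), collapse = ", "), "\n")
  invisible(x)
}

resize_square <- function(img, side) {
  as.matrix(EBImage::resize(EBImage::Image(img), w = side, h = side))
}

frame_tile <- function(gray, color) {
  side <- nrow(gray)
  rgbv <- grDevices::col2rgb(color) / 255
  arr <- array(0, c(side, side, 3))
  for (k in 1:3) arr[, , k] <- gray * 0.9
  b <- 3L
  edge <- c(1:b, (side - b + 1):side)
  for (k in 1:3) {
    arr[edge, , k] <- rgbv[k]
    arr[, edge, k] <- rgbv[k]
  }
  EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color")
}
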