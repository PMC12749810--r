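#' Default nucleus segmentation for FUCCI frames
#'
#' Combines the cyan and magenta channels, denoises (Gaussian), thresholds
#' with isodata and splits touching nuclei by watershed on the distance map.
#' The segmenter is pluggable: every downstream operation accepts any label
#' image.
#'
#' @param frame a (c, y, x) array or an [image_stack()] frame with channels
#'   actin, tubulin, cyan, magenta.
#' @param cyan_ch,magenta_ch channel indices.
#' @param sigma Gaussian denoising SD, pixels.
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(frame, cyan_ch = 3, magenta_ch = 4, sigma = 1) {
  arr <- frame_array(frame)
  comb <- array(arr[cyan_ch, , ], dim(arr)[2:3]) +
    array(arr[magenta_ch, , ], dim(arr)[2:3])
  img <- norm01(comb)
  if (sigma > 0) img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma))
  lev <- tryCatch(isodata_threshold(hist256(norm01(img))),
                  gelplate_degenerate = function(e) NULL)
  if (is.null(lev)) return(matrix(0L, dim(arr)[2], dim(arr)[3]))
  m <- apply_level(norm01(img), lev)
  m <- EBImage::opening(m * 1, EBImage::makeBrush(3, "disc")) > 0
  dm <- EBImage::distmap(m * 1)
  lab <- EBImage::watershed(dm, tolerance = 1)
  matrix(as.integer(lab), nrow(m), ncol(m))
}

frame_array <- function(frame) {
  if (inherits(frame, "image_stack")) {
    st <- canonical_stack(frame)
    gp_validate(!"t" %in% st$axes && !"z" %in% st$axes,
                "pass a single frame, not a stack")
    return(st$pixels)
  }
  gp_validate(is.array(frame) && length(dim(frame)) == 3,
              "frame must be a (c, y, x) array")
  frame
}

#' Classify nuclei into FUCCI cell-cycle states
#'
#' Per nucleus, the background (median intensity outside all nuclei) is
#' subtracted from the mean cyan and magenta intensities, and the four-way
#' rule applies: both above threshold = transition (T), cyan only = G1,
#' magenta only = S/G2/M, neither = early G1 (EG1).  Default thresholds are
#' dataset-calibrated as `k_mad` times the MAD of the background pixels.
#'
#' @param frame (c, y, x) array or [image_stack()] frame.
#' @param labels integer nucleus label matrix aligned with the frame.
#' @param cyan_thr,magenta_thr intensity thresholds on the
#'   background-subtracted means; `NULL` calibrates from the background MAD.
#' @param cyan_ch,magenta_ch channel indices.
#' @param k_mad threshold calibration factor.
#' @param pixel_size_um lateral calibration for areas (um^2).
#' @return data.frame with one row per nucleus: `label_id`, centroid `y`,
#'   `x`, `area_px`, `area_um2`, `mean_cyan`, `mean_magenta` (both
#'   background-subtracted) and `cycle_class`.
#' @export
classify_nuclei <- function(frame, labels, cyan_thr = NULL,
                            magenta_thr = NULL, cyan_ch = 3, magenta_ch = 4,
                            k_mad = 6, pixel_size_um = 1) {
  arr <- frame_array(frame)
  gp_validate(dim(arr)[1] >= max(cyan_ch, magenta_ch),
              "frame has fewer channels than expected")
  gp_validate(identical(dim(labels), dim(arr)[2:3]),
              "labels do not align with the frame")
  if (!any(labels > 0))
    return(data.frame(label_id = integer(), y = numeric(), x = numeric(),
                      area_px = integer(), area_um2 = numeric(),
                      mean_cyan = numeric(), mean_magenta = numeric(),
                      cycle_class = character()))
  cyn <- array(arr[cyan_ch, , ], dim(arr)[2:3])
  mag <- array(arr[magenta_ch, , ], dim(arr)[2:3])
  out <- labels == 0
  bg_c <- median(cyn[out]); bg_m <- median(mag[out])
  if (is.null(cyan_thr)) cyan_thr <- k_mad * max(mad(cyn[out]), 1e-6)
  if (is.null(magenta_thr)) magenta_thr <- k_mad * max(mad(mag[out]), 1e-6)
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(id) {
    sel <- labels == id
    idx <- which(sel, arr.ind = TRUE)
    mc <- mean(cyn[sel]) - bg_c
    mm <- mean(mag[sel]) - bg_m
    cls <- if (mc > cyan_thr && mm > magenta_thr) "T"
           else if (mc > cyan_thr) "G1"
           else if (mm > magenta_thr) "SG2M"
           else "EG1"
    data.frame(label_id = id, y = mean(idx[, 1]), x = mean(idx[, 2]),
               area_px = nrow(idx),
               area_um2 = nrow(idx) * pixel_size_um^2,
               mean_cyan = mc, mean_magenta = mm, cycle_class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mitotic detection from the tubulin channel
#'
#' The cyan channel times `bleed_coeff` is subtracted from the tubulin
#' (green) channel to correct bleed-through; per nucleus the corrected mean
#' is compared against the background estimated from a surrounding
#' cytoplasmic annulus (median, 5 px, other nuclei excluded).  A cell is
#' mitotic when the relative excess `(nucleus - background) / background`
#' reaches the substrate-specific threshold: 0.2 on plastic, 0.4 on
#' hydrogel (doubled for gel autofluorescence).
#'
#' @inheritParams classify_nuclei
#' @param substrate `"plastic"` or `"hydrogel"`.
#' @param bleed_coeff linear cyan bleed-through coefficient.
#' @param tubulin_ch tubulin channel index.
#' @param annulus_px annulus width, pixels.
#' @param threshold override of the substrate threshold.
#' @param relative compare the relative excess (default) or absolute excess.
#' @return data.frame: `label_id`, `tubulin_nucleus`, `tubulin_background`,
#'   `excess`, `mitotic` (NA when the background is non-positive).
#' @export
detect_mitotic <- function(frame, labels,
                           substrate = c("plastic", "hydrogel"),
                           bleed_coeff = 0, tubulin_ch = 2, cyan_ch = 3,
                           annulus_px = 5, threshold = NULL,
                           relative = TRUE) {
  substrate <- match.arg(substrate)
  gp_validate(bleed_coeff >= 0, "bleed_coeff must be >= 0")
  if (is.null(threshold))
    threshold <- c(plastic = 0.2, hydrogel = 0.4)[[substrate]]
  arr <- frame_array(frame)
  tub <- pmax(array(arr[tubulin_ch, , ], dim(arr)[2:3]) -
                bleed_coeff * array(arr[cyan_ch, , ], dim(arr)[2:3]), 0)
  any_nuc <- labels > 0
  ids <- sort(unique(labels[any_nuc]))
  br <- EBImage::makeBrush(2L * as.integer(annulus_px) + 1L, "disc")
  rows <- lapply(ids, function(id) {
    sel <- labels == id
    ring <- (EBImage::dilate(sel * 1, br) > 0) & !any_nuc
    bg <- if (any(ring)) median(tub[ring]) else NA_real_
    mn <- mean(tub[sel])
    if (is.na(bg) || bg <= 0)
      return(data.frame(label_id = id, tubulin_nucleus = mn,
                        tubulin_background = bg, excess = NA_real_,
                        mitotic = NA))
    exc <- if (relative) (mn - bg) / bg else mn - bg
    data.frame(label_id = id, tubulin_nucleus = mn, tubulin_background = bg,
               excess = exc, mitotic = exc >= threshold)
  })
  do.call(rbind, rows)
}

#' Exclude fragmented nuclei by area
#'
#' Marks records whose nuclear area falls strictly below
#' `exclusion_fraction` times the control mean area (the literal rule uses
#' fraction 1; it is intended for treated conditions where fragmentation
#' occurs).
#'
#' @param records data.frame with an `area_px` (or `area_um2`) column.
#' @param control_mean_area mean nuclear area of control cells (> 0), same
#'   units as the area column used.
#' @param exclusion_fraction multiplier of the control mean.
#' @param area_col which area column to compare.
#' @return `records` with a logical `excluded_fragmented` column.
#' @export
fragmentation_filter <- function(records, control_mean_area,
                                 exclusion_fraction = 1,
                                 area_col = "area_px") {
  gp_validate(control_mean_area > 0, "control_mean_area must be > 0")
  gp_validate(area_col %in% names(records), "missing area column")
  records$excluded_fragmented <-
    records[[area_col]] < exclusion_fraction * control_mean_area
  records
}

#' M-phase fold change relative to the vehicle control
#'
#' The mitotic fraction (mitotic count over total non-excluded count) per
#' condition, divided by the vehicle fraction.
#'
#' @param records data.frame with `condition`, `mitotic` and (optionally)
#'   `excluded_fragmented` columns.
#' @param vehicle_condition name of the vehicle (negative control).
#' @return data.frame: `condition`, `n`, `m_fraction`, `fold`.
#' @export
mphase_fold_change <- function(records, vehicle_condition) {
  gp_validate(all(c("condition", "mitotic") %in% names(records)),
              "records need condition and mitotic columns")
  if (!"excluded_fragmented" %in% names(records))
    records$excluded_fragmented <- FALSE
  keep <- !records$excluded_fragmented & !is.na(records$mitotic)
  records <- records[keep, ]
  gp_validate(vehicle_condition %in% records$condition,
              "vehicle condition absent from records")
  agg <- aggregate(mitotic ~ condition, records,
                   function(v) c(n = length(v), frac = mean(v)))
  out <- data.frame(condition = agg$condition, n = agg$mitotic[, "n"],
                    m_fraction = agg$mitotic[, "frac"])
  veh <- out$m_fraction[out$condition == vehicle_condition]
  if (veh <= 0)
    gp_stop("vehicle M fraction is zero; fold change undefined",
            "gelplate_undefined_fold")
  out$fold <- out$m_fraction / veh
  out
}

#' Greedy gap-closing track linking
#'
#' Frame-to-frame greedy assignment minimizing link distance under
#' `max_distance_um`; track ends are retried against later detections across
#' gaps of up to `max_gap_frames` missing frames.  Deterministic: candidate
#' links are ordered by distance with ties broken by smaller label id.
#'
#' @param detections data.frame with `frame`, `label_id`, `y`, `x`
#'   (pixel coordinates).
#' @param pixel_size_um lateral calibration (required).
#' @param max_distance_um maximum link distance, micrometres.
#' @param max_gap_frames maximum number of missing frames bridged.
#' @return A `track_set`: data.frame `tracks` with `track_id`, `frame`,
#'   `label_id`, `y`, `x`.
#' @export
link_tracks <- function(detections, pixel_size_um, max_distance_um = 50,
                        max_gap_frames = 3) {
  gp_validate(!missing(pixel_size_um) && is.finite(pixel_size_um) &&
                pixel_size_um > 0, "pixel_size_um is required")
  gp_validate(all(c("frame", "label_id", "y", "x") %in% names(detections)),
              "detections need frame, label_id, y, x")
  det <- detections[order(detections$frame, detections$label_id), ]
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  # active tracks: id, last frame, last y, x
  act <- data.frame(track_id = integer(), frame = integer(),
                    y = numeric(), x = numeric())
  next_id <- 1L
  for (f in frames) {
    cur <- which(det$frame == f)
    cand_tracks <- act[f - act$frame <= max_gap_frames + 1, , drop = FALSE]
    if (nrow(cand_tracks) > 0 && length(cur) > 0) {
      pairs <- expand.grid(ti = seq_len(nrow(cand_tracks)),
                           di = seq_along(cur))
      dist_um <- sqrt((cand_tracks$y[pairs$ti] - det$y[cur[pairs$di]])^2 +
                      (cand_tracks$x[pairs$ti] - det$x[cur[pairs$di]])^2) *
        pixel_size_um
      ok <- dist_um <= max_distance_um
      pairs <- pairs[ok, , drop = FALSE]
      dist_um <- dist_um[ok]
      ord <- order(dist_um, det$label_id[cur[pairs$di]],
                   cand_tracks$track_id[pairs$ti])
      used_t <- logical(nrow(cand_tracks)); used_d <- logical(length(cur))
      for (k in ord) {
        ti <- pairs$ti[k]; di <- pairs$di[k]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        id <- cand_tracks$track_id[ti]
        det$track_id[cur[di]] <- id
        act[act$track_id == id, c("frame", "y", "x")] <-
          list(f, det$y[cur[di]], det$x[cur[di]])
      }
    }
    for (di in which(is.na(det$track_id[cur]))) {
      det$track_id[cur[di]] <- next_id
      act <- rbind(act, data.frame(track_id = next_id, frame = f,
                                   y = det$y[cur[di]], x = det$x[cur[di]]))
      next_id <- next_id + 1L
    }
  }
  structure(list(tracks = det[order(det$track_id, det$frame),
                              c("track_id", "frame", "label_id", "y", "x")],
                 max_distance_um = max_distance_um,
                 max_gap_frames = max_gap_frames),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks over %d detections\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks)))
  invisible(x)
}
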