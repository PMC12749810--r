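#' Triangle auto-threshold
#'
#' Geometric threshold for unimodal histograms: a line is drawn from the
#' histogram peak to the far end of the longer tail (the farthest non-empty
#' bin); the threshold is the bin maximizing the perpendicular distance from
#' the line to the histogram.  Ties break toward the lower intensity.
#'
#' @param histogram integer vector of 256 bin counts (intensities 0-255).
#' @return threshold level (0-255 scale).
#' @export
triangle_threshold <- function(histogram) {
  h <- check_hist(histogram)
  nz <- which(h > 0)
  peak <- which.max(h)
  lo <- nz[1]; hi <- nz[length(nz)]
  right <- (hi - peak) >= (peak - lo)  # longer-tail side
  end <- if (right) hi else lo
  idx <- if (right) peak:end else end:peak
  # perpendicular distance from (i, h[i]) to the peak-end line
  x1 <- peak; y1 <- h[peak]; x2 <- end; y2 <- h[end]
  d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1)
  best <- idx[which.max(d)]  # which.max: first (lowest-intensity) maximum
  best - 1L
}

#' Isodata (intermeans) auto-threshold
#'
#' Iterates `level = (mean below + mean above) / 2` from the mid-intensity
#' start until a fixed point; the ImageJ "Default" method family.
#'
#' @inheritParams triangle_threshold
#' @return threshold level (0-255 scale).
#' @export
isodata_threshold <- function(histogram) {
  h <- check_hist(histogram)
  v <- 0:255
  level <- 127.5
  for (i in 1:1000) {
    below <- v <= level
    w1 <- sum(h[below]); w2 <- sum(h[!below])
    if (w1 == 0) { level <- level + 1; next }
    if (w2 == 0) { level <- level - 1; next }
    m1 <- sum(h[below] * v[below]) / w1
    m2 <- sum(h[!below] * v[!below]) / w2
    new <- (m1 + m2) / 2
    if (abs(new - level) < 0.5 && floor(new) == floor(level)) {
      level <- new; break
    }
    level <- new
  }
  as.integer(floor(level))
}

check_hist <- function(histogram) {
  gp_validate(is.numeric(histogram) && length(histogram) == 256,
              "histogram must have 256 bins")
  gp_validate(any(histogram > 0), "histogram is empty")
  if (sum(histogram > 0) < 2)
    gp_stop("degenerate single-valued histogram", "gelplate_degenerate")
  as.numeric(histogram)
}

# 256-bin histogram of an image normalized to [0, 1]
hist256 <- function(img) {
  tabulate(pmin(floor(img * 255), 255) + 1L, 256L)
}

# normalize intensities to [0, 1] by range (histogram-relative thresholds)
norm01 <- function(img) {
  rng <- range(img)
  if (rng[2] <= rng[1]) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1])
}

# apply a 0-255 threshold level to a [0,1] image (pixels strictly above)
apply_level <- function(img, level) {
  img * 255 > level
}
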