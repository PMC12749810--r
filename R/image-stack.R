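#' Multi-dimensional image stack
#'
#' A light container for microscope data: a numeric array plus axis labels
#' (subset of `t`, `z`, `c`, `y`, `x`; the last two axes must be `y`, `x`),
#' channel names and physical calibration.
#'
#' @param pixels numeric array of non-negative finite intensities.
#' @param axes character vector naming each array dimension.
#' @param channel_names optional channel names (length = size of `c` axis).
#' @param pixel_size_um lateral pixel size, micrometres.
#' @param z_step_um axial step between z slices, micrometres.
#' @param time_step_min time between frames, minutes.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, axes, channel_names = NULL,
                        pixel_size_um = NA_real_, z_step_um = NA_real_,
                        time_step_min = NA_real_) {
  pixels <- as.array(pixels)
  gp_validate(length(axes) == length(dim(pixels)),
              "axes must match the number of array dimensions")
  gp_validate(all(axes %in% c("t", "z", "c", "y", "x")) && !anyDuplicated(axes),
              "axes must be unique labels among t, z, c, y, x")
  nd <- length(axes)
  gp_validate(nd >= 2 && identical(axes[(nd - 1):nd], c("y", "x")),
              "the two trailing axes must be y, x")
  gp_validate(all(is.finite(pixels)) && min(pixels) >= 0,
              "intensities must be finite and >= 0")
  if (!is.null(channel_names)) {
    ci <- match("c", axes)
    gp_validate(!is.na(ci) && length(channel_names) == dim(pixels)[ci],
                "channel_names must match the size of the c axis")
  }
  structure(list(pixels = pixels, axes = axes, channel_names = channel_names,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 time_step_min = time_step_min),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> [%s] %s%s\n",
              paste(x$axes, collapse = ","),
              paste(dim(x$pixels), collapse = "x"),
              if (is.null(x$channel_names)) ""
              else paste0(" channels: ", paste(x$channel_names,
                                               collapse = ", "))))
  invisible(x)
}

# permute so leading axes follow t, z, c order (those present)
canonical_stack <- function(stack) {
  want <- c(intersect(c("t", "z", "c"), stack$axes), "y", "x")
  if (identical(want, stack$axes)) return(stack)
  perm <- match(want, stack$axes)
  image_stack(aperm(stack$pixels, perm), want, stack$channel_names,
              stack$pixel_size_um, stack$z_step_um, stack$time_step_min)
}

# extract one channel as an array without the c axis
stack_channel <- function(stack, ch) {
  ci <- match("c", stack$axes)
  gp_validate(!is.na(ci), "stack has no channel axis")
  if (is.character(ch)) {
    ch <- match(ch, stack$channel_names)
    gp_validate(!is.na(ch), "unknown channel name")
  }
  idx <- rep(list(quote(expr = )), length(stack$axes))
  idx[[ci]] <- ch
  out <- do.call(`[`, c(list(stack$pixels), idx, list(drop = FALSE)))
  dm <- dim(out)[-ci]
  array(out, dm)
}

# maximum-intensity projection of a (z, y, x) array over z
mip_z <- function(arr) {
  if (length(dim(arr)) == 2) return(arr)
  apply(arr, c(2, 3), max)
}

#' Write an image stack as a multi-page float TIFF
#'
#' Pages iterate over the leading (non `y`/`x`) axes, last leading axis
#' fastest.  Axis labels, channel names and calibration are stored in a JSON
#' sidecar `<path>.json`, which [read_stack()] uses to rebuild the stack
#' losslessly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  gp_validate(inherits(stack, "image_stack"), "stack must be an image_stack")
  px <- stack$pixels
  dm <- dim(px)
  nd <- length(dm)
  lead <- if (nd > 2) dm[seq_len(nd - 2)] else integer()
  npage <- prod(c(lead, 1))
  pages <- vector("list", npage)
  if (nd == 2) {
    pages[[1]] <- px
  } else {
    grid <- expand.grid(rev(lapply(lead, seq_len)), KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # last axis fastest
    for (p in seq_len(npage)) {
      idx <- c(as.list(as.integer(grid[p, ])),
               rep(list(quote(expr = )), 2))
      sl <- do.call(`[`, c(list(px), idx, list(drop = FALSE)))
      pages[[p]] <- array(sl, dm[(nd - 1):nd])
    }
  }
  # pages are stored as 32-bit float in [0, 1]; the scale restores intensities
  scale <- max(max(px), .Machine$double.eps)
  pages <- lapply(pages, function(p) p / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(axes = stack$axes, dim = dm,
               channel_names = stack$channel_names,
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               time_step_min = stack$time_step_min,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar `<path>.json` provides axes and
#'   calibration.  Without a sidecar the file is read as a plain (z, y, x)
#'   stack and `pixel_size_um` must be supplied.
#' @param pixel_size_um,z_step_um calibration overrides.
#' @param axes axis labels override (required if ambiguous).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL,
                       axes = NULL) {
  gp_validate(file.exists(path), sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    dm <- as.integer(meta$dim)
    ax <- as.character(meta$axes)
    nd <- length(dm)
    arr <- array(0, dm)
    if (nd == 2) {
      arr <- pages[[1]]
    } else {
      lead <- dm[seq_len(nd - 2)]
      grid <- expand.grid(rev(lapply(lead, seq_len)), KEEP.OUT.ATTRS = FALSE)
      grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
      for (p in seq_along(pages)) {
        idx <- c(as.list(as.integer(grid[p, ])),
                 rep(list(quote(expr = )), 2))
        arr <- do.call(`[<-`, c(list(arr), idx, list(value = pages[[p]])))
      }
    }
    if (!is.null(meta$intensity_scale))
      arr <- arr * as.numeric(meta$intensity_scale)
    cn <- meta$channel_names
    if (length(cn) == 0) cn <- NULL
    num_or_na <- function(v) if (length(v) == 0) NA_real_ else as.numeric(v)
    image_stack(arr, ax, cn,
                pixel_size_um = if (!is.null(pixel_size_um)) pixel_size_um
                                else num_or_na(meta$pixel_size_um),
                z_step_um = if (!is.null(z_step_um)) z_step_um
                            else num_or_na(meta$z_step_um),
                time_step_min = num_or_na(meta$time_step_min))
  } else {
    gp_validate(!is.null(pixel_size_um),
                "no metadata sidecar: pixel_size_um override is required")
    if (is.null(axes)) axes <- if (length(pages) > 1) c("z", "y", "x")
                               else c("y", "x")
    arr <- if (length(pages) > 1)
      aperm(simplify2array(pages), c(3, 1, 2)) else pages[[1]]
    image_stack(arr, axes, pixel_size_um = pixel_size_um,
                z_step_um = if (is.null(z_step_um)) NA_real_ else z_step_um)
  }
}
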