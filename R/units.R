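#' Unit conversion helpers
#'
#' The solver works in SI units (m, m^3, kg, s); bench protocols are stated in
#' microlitres and millimetres.  These helpers convert between the two.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ul_to_m3 <- function(x) x * 1e-9

#' @rdname units
#' @export
m3_to_ul <- function(x) x * 1e9

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
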