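#' Depolarized light image from a PS-SLO frame stack
#'
#' The crossed-detector signal of a polarization-preserving structure
#' varies sinusoidally with the input polarization angle, while a
#' depolarizing structure returns an angle-independent floor. The
#' depolarized light image is therefore the per-pixel minimum of the
#' crossed-detector frames over all input polarization angles, which
#' suppresses the preserving crosstalk and isolates the depolarizing
#' contribution.
#'
#' @param stack a `psslo_stack` (see [simulate_psslo_stack()]) or a 3-d
#'   array (x, b, angle).
#' @return object of class `depolarized_image` with the raw minimum matrix
#'   in `value`.
#' @export
depolarized_light_image <- function(stack) {
  frames <- if (inherits(stack, "psslo_stack")) stack$frames else stack
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] < 2)
    stop("need at least 2 input polarization angles to minimize over")
  value <- apply(frames, c(1, 2), min)
  structure(list(value = value, n_angles = dim(frames)[3]),
            class = "depolarized_image")
}

#' Min-max rescale of a depolarized light image to 8-bit grayscale
#'
#' Raw depolarized light images are too dark for direct reading; display
#' brightness is adjusted by mapping the image minimum..maximum linearly
#' onto 0..255, with rounding half away from zero. A constant image maps
#' to all zeros.
#'
#' @param image a `depolarized_image` or numeric matrix.
#' @return integer matrix in 0..255.
#' @export
rescale_grayscale <- function(image) {
  x <- if (inherits(image, "depolarized_image")) image$value else image
  rng <- range(x)
  if (diff(rng) == 0) {
    g <- matrix(0L, nrow(x), ncol(x))
    return(g)
  }
  g <- round_half_up(255 * (x - rng[1]) / (rng[2] - rng[1]))
  storage.mode(g) <- "integer"
  g
}
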