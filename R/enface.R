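#' En-face minimum-DOPU projection
#'
#' Per (x, b) pixel, the minimum DOPU over the valid voxels of the whole
#' depth column, or — when a segmentation is given — over the voxels
#' anterior to the RPE boundary only (`z < line[x, b]`, half-open). The
#' anterior projection removes the depolarization of the normal RPE and
#' choroid so that intraretinal depolarizing foci stand out. A pixel with
#' no valid voxel in range is flagged invalid and rendered 0.
#'
#' @param dopu a `dopu_volume`.
#' @param segmentation optional [segmentation_line()] on the same grid.
#' @return object of class `enface_image`: matrix `value`, logical matrix
#'   `valid`, and `kind` (`"min_dopu_whole"` or `"min_dopu_anterior"`).
#' @export
min_dopu_projection <- function(dopu, segmentation = NULL) {
  d <- dim(dopu$dopu)
  nx <- d[1]; nb <- d[2]; nz <- d[3]
  kind <- "min_dopu_whole"
  keep <- dopu$valid
  if (!is.null(segmentation)) {
    if (!identical(dim(segmentation$depth), c(nx, nb)))
      stop("segmentation grid does not match the DOPU volume")
    z_of <- rep(seq_len(nz), each = nx * nb)
    keep <- keep & array(z_of < as.vector(segmentation$depth), dim = d)
    kind <- "min_dopu_anterior"
  }
  masked <- ifelse(keep, dopu$dopu, Inf)
  value <- apply(masked, c(1, 2), min)
  valid <- is.finite(value)
  value[!valid] <- 0
  structure(list(value = value, valid = valid, kind = kind),
            class = "enface_image")
}

#' En-face mean-intensity projection
#'
#' Per (x, b), the linear-domain mean of S0 over depth and repeats,
#' log-compressed to 8 bits — the standard OCT en-face fundus view.
#'
#' @param stokes a `stokes_volume`.
#' @param window_db display dynamic range below the maximum, in dB.
#' @return object of class `enface_image` with `value` an 8-bit integer
#'   matrix, `linear` the pre-compression means, and
#'   `kind = "mean_intensity"`.
#' @export
mean_intensity_projection <- function(stokes, window_db = 40) {
  d <- dim(stokes$S0)
  margins <- c(1, 2)
  lin <- apply(stokes$S0, margins, mean)
  structure(list(value = log_compress_8bit(lin, window_db), linear = lin,
                 valid = matrix(TRUE, d[1], d[2]), kind = "mean_intensity"),
            class = "enface_image")
}

#' Composite DOPU B-scan overlay
#'
#' Overlays the low-DOPU area (strictly below the threshold, default 0.8)
#' in red on the log-compressed standard OCT B-scan, restricted to valid
#' signal pixels — the display used to localize depolarization within the
#' retinal layers.
#'
#' @param intensity_bscan numeric matrix (x, z) of linear S0 values.
#' @param dopu_bscan numeric matrix (x, z) of DOPU values.
#' @param valid_bscan logical matrix (x, z); overlay is suppressed on
#'   invalid (noise-masked) pixels.
#' @param threshold DOPU overlay threshold; strict `<` comparison, a pixel
#'   exactly at the threshold is not flagged.
#' @param window_db display window for the log compression.
#' @return object of class `composite_bscan`: `rgb` array (x, z, 3) in
#'   \[0, 1\], logical `overlay` matrix, `threshold`.
#' @export
composite_dopu_overlay <- function(intensity_bscan, dopu_bscan,
                                   valid_bscan = NULL, threshold = 0.8,
                                   window_db = 40) {
  if (!identical(dim(intensity_bscan), dim(dopu_bscan)))
    stop("intensity and DOPU B-scans must share a shape")
  if (is.null(valid_bscan)) valid_bscan <- intensity_bscan > 0
  if (!identical(dim(valid_bscan), dim(dopu_bscan)))
    stop("validity mask must share the B-scan shape")
  base <- log_compress_8bit(intensity_bscan, window_db) / 255
  overlay <- (dopu_bscan < threshold) & valid_bscan
  rgb <- array(rep(base, 3L), dim = c(dim(base), 3L))
  red <- rgb[, , 1]; green <- rgb[, , 2]; blue <- rgb[, , 3]
  red[overlay] <- 1
  green[overlay] <- 0
  blue[overlay] <- 0
  rgb[, , 1] <- red; rgb[, , 2] <- green; rgb[, , 3] <- blue
  structure(list(rgb = rgb, overlay = overlay, threshold = threshold),
            class = "composite_bscan")
}

#' Extract one B-scan of S0 (averaged over repeats) and DOPU
#'
#' @param stokes a `stokes_volume`.
#' @param dopu a `dopu_volume`.
#' @param b B-scan index.
#' @return list with matrices `intensity` (x, z), `dopu`, `valid`.
#' @export
extract_bscan <- function(stokes, dopu, b) {
  d <- dim(stokes$S0)
  s0 <- if (length(d) == 4L) apply(stokes$S0[, b, , , drop = FALSE], c(1, 3), mean)
        else stokes$S0[, b, ]
  list(intensity = s0, dopu = dopu$dopu[, b, ], valid = dopu$valid[, b, ])
}
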