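#' Shanbhag auto-threshold of a 256-bin histogram
#'
#' Shanbhag's fuzzy-information thresholding: for each candidate threshold
#' t the gray levels at or below t form the background class and those
#' above it the foreground; each class gets an information measure built
#' from fuzzy memberships derived from the cumulative histogram, and the
#' selected threshold minimizes the absolute difference between the two
#' measures. Ties break to the lowest candidate level. The returned level
#' is on the 0..255 scale and is used as "foreground iff gray > t".
#'
#' With background cumulative mass `P1` and foreground mass `P2 = 1 - P1`,
#' the background measure at threshold t is
#' `-(0.5/P1[t]) * sum_{g<=t} p_g * log(1 - 0.5*P1[g-1]/P1[t])`
#' and symmetrically for the foreground using the mass strictly above g.
#'
#' @param hist integer vector of 256 counts for gray levels 0..255.
#' @return integer threshold level in 0..255.
#' @export
shanbhag_threshold <- function(hist) {
  if (length(hist) != 256L || any(hist < 0))
    stop("hist must be 256 nonnegative counts")
  total <- sum(hist)
  if (total <= 0 || sum(hist > 0) < 2L)
    stop("degenerate histogram: need at least 2 populated gray levels")
  p <- hist / total
  P1 <- cumsum(p)
  P2 <- 1 - P1
  first_bin <- which(P1 > .Machine$double.eps)[1]
  last_bin <- max(which(P2 > .Machine$double.eps))
  P1_before <- c(0, P1[-256L])           # cumulative mass strictly below g

  best_t <- NA_integer_
  best_crit <- Inf
  for (t in first_bin:last_bin) {
    term_b <- 0.5 / P1[t]
    gs <- seq_len(t)
    ent_back <- -term_b * sum(p[gs] * log1p(-term_b * P1_before[gs]))
    term_f <- 0.5 / P2[t]
    ent_obj <- 0
    if (t < 256L) {
      gs <- (t + 1L):256L
      ent_obj <- -term_f * sum(p[gs] * log1p(-term_f * P2[gs]))
    }
    crit <- abs(ent_back - ent_obj)
    if (crit < best_crit) {
      best_crit <- crit
      best_t <- t
    }
  }
  best_t - 1L   # histogram bin 1 is gray level 0
}

#' Histogram of an 8-bit image
#' @param img integer matrix with values in 0..255.
#' @return integer vector of 256 counts.
#' @export
hist256 <- function(img) {
  stopifnot(all(img >= 0 & img <= 255))
  tabulate(as.integer(img) + 1L, nbins = 256L)
}

#' Binarize a B-scan with the Shanbhag auto-threshold
#'
#' @param bscan integer matrix (8-bit gray levels 0..255).
#' @return logical matrix; `TRUE` where gray > the Shanbhag threshold of
#'   the image's own histogram.
#' @export
binarize_bscan <- function(bscan) {
  t <- shanbhag_threshold(hist256(bscan))
  bscan > t
}

#' Log-compressed 8-bit standard B-scan image
#'
#' The "standard OCT B-scan" used for binarization: S0 averaged over
#' repeats, log-compressed, then brightness-normalized so the displayed
#' dynamic range runs from just above the noise floor (the 1st percentile
#' of the nonzero intensities, in dB) to the image maximum. Without this
#' floor-referenced windowing the vitreous collapses into gray level 0
#' and dominates the histogram, which defeats any histogram-shape
#' threshold.
#'
#' @param stokes a `stokes_volume`.
#' @param b B-scan index.
#' @param floor_quantile dB floor percentile of the positive intensities.
#' @return integer matrix (x, z) in 0..255.
#' @export
bscan_intensity_8bit <- function(stokes, b, floor_quantile = 0.01) {
  d <- dim(stokes$S0)
  s0 <- if (length(d) == 4L) apply(stokes$S0[, b, , , drop = FALSE], c(1, 3), mean)
        else stokes$S0[, b, ]
  mx <- max(s0)
  if (mx <= 0) return(matrix(0L, nrow(s0), ncol(s0)))
  db <- 20 * log10(pmax(s0 / mx, 1e-30))
  lo <- max(stats::quantile(db[s0 > 0], floor_quantile), -80)
  g <- round_half_up(255 * (pmax(db, lo) - lo) / (0 - lo))
  storage.mode(g) <- "integer"
  g
}

#' Truth-guided HRF region selection
#'
#' Stands in for the manual selection of HRF loci on the binarized
#' B-scans: the binary foreground of each B-scan is intersected with the
#' ground-truth voxel sets of the selected foci. Only voxels anterior to
#' the segmentation line are kept.
#'
#' @param stokes a `stokes_volume`.
#' @param truth_voxels list of integer (x, b, z) matrices (e.g.
#'   `truth$focus_voxels` of a synthetic eye), one per selected focus.
#' @param segmentation a [segmentation_line()].
#' @param binarize apply the Shanbhag binarization before intersecting
#'   (set `FALSE` to take the truth masks as-is).
#' @return object of class `hrf_region_set`: integer matrix `voxels` with
#'   columns x, b, z, and the selection source.
#' @export
select_hrf_regions <- function(stokes, truth_voxels, segmentation,
                               binarize = TRUE) {
  d <- dim(stokes$S0)
  vox <- if (length(truth_voxels)) do.call(rbind, truth_voxels) else
    matrix(integer(0), 0, 3)
  if (nrow(vox)) {
    vox <- vox[!duplicated(vox), , drop = FALSE]
    anterior <- vox[, 3] < segmentation$depth[cbind(vox[, 1], vox[, 2])]
    vox <- vox[anterior, , drop = FALSE]
  }
  if (binarize && nrow(vox)) {
    keep <- logical(nrow(vox))
    for (b in sort(unique(vox[, 2]))) {
      img <- bscan_intensity_8bit(stokes, b)
      fg <- binarize_bscan(img)
      rows <- which(vox[, 2] == b)
      keep[rows] <- fg[cbind(vox[rows, 1], vox[rows, 3])]
    }
    vox <- vox[keep, , drop = FALSE]
  }
  structure(list(voxels = vox, source = if (binarize) "truth-guided" else "truth"),
            class = "hrf_region_set")
}

#' HRF volume by the printed voxel formula
#'
#' Total segmented-HRF volume per eye: the number of selected voxels times
#' the voxel volume at the printed pitches,
#' 11.7 um x 23.5 um x 3.6 um = 989.82 um^3 per voxel, reported in mm^3.
#'
#' @param regions an `hrf_region_set`, or an integer voxel count.
#' @param params an [optic_params()] supplying the pitches.
#' @return object of class `volume_result` with `value` (mm^3),
#'   `pixel_count`, and `method = "voxel_formula"`.
#' @export
measure_hrf_volume <- function(regions, params = optic_params()) {
  n <- if (inherits(regions, "hrf_region_set")) nrow(regions$voxels)
       else as.integer(regions)
  stopifnot(n >= 0)
  structure(list(value = n * voxel_volume_um3(params) * 1e-9,
                 pixel_count = n, method = "voxel_formula"),
            class = "volume_result")
}

#' Per-B-scan PED cross-sectional areas from a segmentation
#'
#' The PED cross-section in each B-scan is the area between the elevated
#' RPE anterior boundary and its flat baseline: per A-line, the
#' depth-index lift times the depth pitch, summed over A-lines and scaled
#' by the transverse pitch.
#'
#' @param segmentation a [segmentation_line()] (the elevated boundary).
#' @param baseline baseline depth index (scalar) or matrix; voxels where
#'   the boundary is at or below the baseline contribute zero.
#' @param params an [optic_params()].
#' @return numeric vector of per-B-scan areas in mm^2.
#' @export
ped_cross_section_areas <- function(segmentation, baseline, params) {
  lift <- baseline - segmentation$depth
  lift[lift < 0] <- 0
  colSums(lift) * params$pitch_z * params$pitch_x * 1e-6
}

#' PED volume by the Cavalieri principle
#'
#' Stereological volume estimate from serial sections: the slice spacing
#' times the sum of the per-slice cross-sectional areas.
#'
#' @param areas numeric vector of per-B-scan areas in mm^2 (>= 0).
#' @param spacing_um inter-B-scan spacing in micrometres (default the
#'   printed 23.5 um pitch).
#' @return object of class `volume_result` with `value` (mm^3) and
#'   `method = "cavalieri"`.
#' @export
cavalieri_ped_volume <- function(areas, spacing_um = 23.5) {
  if (any(areas < 0)) stop("negative cross-sectional area")
  if (spacing_um <= 0) stop("spacing must be > 0")
  structure(list(value = spacing_um * 1e-3 * sum(areas),
                 pixel_count = NA_integer_, method = "cavalieri"),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("volume_result [%s]: %.6g mm^3", x$method, x$value))
  if (!is.na(x$pixel_count)) cat(sprintf(" (%d voxels)", x$pixel_count))
  cat("\n")
  invisible(x)
}
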