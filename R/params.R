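#' Acquisition geometry and detector-noise parameters
#'
#' Container for the raster-scan geometry of a polarization-sensitive OCT
#' volume and the mean additive detector-noise energy of its two
#' polarization channels. The nominal full-scale protocol is 512 A-lines by
#' 256 B-scans over a 6.0 x 6.0 mm macular region with each B-scan repeated
#' four times at the same location. Voxel pitches are stored independently
#' of the grid counts and default to the instrument's printed values
#' (11.7 x 23.5 x 3.6 um); note 6.0 mm / 512 = 11.72 um, so the printed
#' transverse pitch is a rounded figure — volume formulas use the printed
#' pitches throughout.
#'
#' @param n_alines number of A-lines per B-scan (x grid).
#' @param n_bscans number of B-scan locations (b grid).
#' @param n_depth number of depth pixels per A-line (z grid). The default
#'   (128) is a desk-scale depth range; the full instrument depth is
#'   available by raising it (up to 583 pixels for 2.1 mm at 3.6 um).
#' @param n_repeats number of repeated B-scans per location.
#' @param pitch_x,pitch_b,pitch_z voxel pitch in micrometres along the
#'   A-line, B-scan and depth axes.
#' @param noise_energy_ch1,noise_energy_ch2 mean additive detector-noise
#'   energy per channel, in the (arbitrary) intensity units of the field.
#' @param seed integer seed attached to volumes simulated with these
#'   parameters.
#' @return an object of class `optic_params`.
#' @examples
#' p <- optic_params(n_alines = 64, n_bscans = 16, n_depth = 48)
#' p$pitch_x * p$n_alines / 1000  # lateral field of view in mm
#' @export
optic_params <- function(n_alines = 512L, n_bscans = 256L, n_depth = 128L,
                         n_repeats = 4L,
                         pitch_x = 11.7, pitch_b = 23.5, pitch_z = 3.6,
                         noise_energy_ch1 = 0.01, noise_energy_ch2 = 0.01,
                         seed = 1L) {
  counts <- c(n_alines = n_alines, n_bscans = n_bscans,
              n_depth = n_depth, n_repeats = n_repeats)
  if (any(counts < 1) || any(counts != as.integer(counts)))
    stop("grid counts must be integers >= 1")
  pitches <- c(pitch_x, pitch_b, pitch_z)
  if (any(!is.finite(pitches)) || any(pitches <= 0))
    stop("voxel pitches must be positive")
  if (noise_energy_ch1 < 0 || noise_energy_ch2 < 0)
    stop("noise energies must be >= 0")
  structure(list(
    n_alines = as.integer(n_alines), n_bscans = as.integer(n_bscans),
    n_depth = as.integer(n_depth), n_repeats = as.integer(n_repeats),
    pitch_x = pitch_x, pitch_b = pitch_b, pitch_z = pitch_z,
    noise_energy_ch1 = noise_energy_ch1, noise_energy_ch2 = noise_energy_ch2,
    seed = as.integer(seed)
  ), class = "optic_params")
}

#' @export
print.optic_params <- function(x, ...) {
  cat(sprintf("optic_params: %d A-lines x %d B-scans x %d depth, %d repeats\n",
              x$n_alines, x$n_bscans, x$n_depth, x$n_repeats))
  cat(sprintf("  pitch (um): x=%.1f b=%.1f z=%.1f; noise energies (%g, %g)\n",
              x$pitch_x, x$pitch_b, x$pitch_z,
              x$noise_energy_ch1, x$noise_energy_ch2))
  invisible(x)
}

#' Voxel volume of the printed-pitch grid, in cubic micrometres
#' @param params an [optic_params()] object.
#' @return scalar, `pitch_x * pitch_b * pitch_z` in um^3.
#' @export
voxel_volume_um3 <- function(params) {
  params$pitch_x * params$pitch_b * params$pitch_z
}

#' The six study groups
#'
#' Group labels for the AMD stages handled by the cohort tools:
#' early-to-intermediate AMD, drusenoid pigment epithelial detachment (PED),
#' serous PED, remission stage of exudative AMD, end-stage AMD with
#' subretinal fibrosis, and dry AMD with geographic atrophy.
#'
#' @return character vector of the six canonical labels.
#' @export
study_groups <- function() {
  c("early_intermediate", "drusenoid_ped", "serous_ped",
    "remission", "fibrosis", "geographic_atrophy")
}
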