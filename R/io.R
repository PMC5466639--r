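#' Write a field volume as paired multi-page TIFF plus JSON sidecar
#'
#' Each page is one (x, z) B-scan plane; pages are ordered as
#' (component real/imag) x (channel) x (repeat) x (B-scan), slowest last.
#' Values are affinely mapped to \[0, 1\] 32-bit float samples; the scale
#' is recorded in the sidecar so [read_field_volume()] restores the
#' original values (to float-32 precision).
#'
#' @param fields a `field_volume`.
#' @param path base path; writes `<path>.tif` and `<path>.json`.
#' @return invisibly, the two file paths.
#' @export
write_field_volume <- function(fields, path) {
  p <- fields$params
  scale <- max(abs(c(Re(fields$E1), Im(fields$E1),
                     Re(fields$E2), Im(fields$E2))), 1e-300)
  pages <- list()
  for (b in seq_len(p$n_bscans)) for (r in seq_len(p$n_repeats))
    for (comp in list(Re, Im)) for (ch in 1:2) {
      E <- if (ch == 1) fields$E1 else fields$E2
      pages[[length(pages) + 1L]] <- (comp(E[, b, , r]) / scale + 1) / 2
    }
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L)
  sidecar <- list(n_alines = p$n_alines, n_bscans = p$n_bscans,
                  n_depth = p$n_depth, n_repeats = p$n_repeats,
                  pitch_x = p$pitch_x, pitch_b = p$pitch_b, pitch_z = p$pitch_z,
                  noise_energy_ch1 = p$noise_energy_ch1,
                  noise_energy_ch2 = p$noise_energy_ch2,
                  seed = fields$seed, scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paste0(path, ".tif"), paste0(path, ".json")))
}

#' Read a field volume written by [write_field_volume()]
#' @param path base path used when writing.
#' @return a `field_volume`.
#' @export
read_field_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  p <- optic_params(meta$n_alines, meta$n_bscans, meta$n_depth, meta$n_repeats,
                    meta$pitch_x, meta$pitch_b, meta$pitch_z,
                    meta$noise_energy_ch1, meta$noise_energy_ch2, meta$seed)
  E1 <- array(0i, dim = c(p$n_alines, p$n_bscans, p$n_depth, p$n_repeats))
  E2 <- E1
  unmap <- function(m) (m * 2 - 1) * meta$scale
  i <- 1L
  for (b in seq_len(p$n_bscans)) for (r in seq_len(p$n_repeats)) {
    re1 <- unmap(pages[[i]]); re2 <- unmap(pages[[i + 1L]])
    im1 <- unmap(pages[[i + 2L]]); im2 <- unmap(pages[[i + 3L]])
    i <- i + 4L
    E1[, b, , r] <- complex(real = re1, imaginary = im1)
    E2[, b, , r] <- complex(real = re2, imaginary = im2)
  }
  structure(list(E1 = E1, E2 = E2, params = p, seed = meta$seed),
            class = "field_volume")
}

#' Write an 8-bit en-face image as TIFF
#' @param img integer matrix in 0..255.
#' @param path output file.
#' @export
write_enface_tiff <- function(img, path) {
  tiff::writeTIFF(img / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write the ground-truth focus table of a synthetic eye as CSV
#'
#' One row per focus: eye id, centre voxel, radius, granule flags and the
#' migration truth label.
#'
#' @param eye a `synthetic_eye`.
#' @param path output CSV path.
#' @return the data.frame, invisibly.
#' @export
write_truth_csv <- function(eye, path) {
  foci <- eye$phantom$foci
  df <- if (length(foci)) do.call(rbind, lapply(seq_along(foci), function(i) {
    f <- foci[[i]]
    data.frame(eye_id = eye$eye_id %||% NA_character_, focus = i,
               x = f$center[1], b = f$center[2], z = f$center[3],
               radius_um = f$radius_um, melanin = f$melanin,
               lipofuscin = f$lipofuscin, melanolipofuscin = f$melanolipofuscin,
               migration_truth = f$migration_truth)
  })) else data.frame()
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Save a composite DOPU overlay B-scan as PNG
#' @param composite a `composite_bscan`.
#' @param path output PNG path.
#' @export
write_composite_png <- function(composite, path) {
  # rgb is (x, z, 3); PNG rows are the depth axis
  png::writePNG(aperm(composite$rgb, c(2, 1, 3)), path)
  invisible(path)
}
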