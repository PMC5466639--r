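#' Stokes parameters from two-channel complex fields
#'
#' Converts the two detection-channel complex fields of a Jones-matrix OCT
#' measurement into Stokes parameters per voxel and repeat:
#' \deqn{S_0=|E_1|^2+|E_2|^2,\quad Q=|E_1|^2-|E_2|^2,\quad
#'       U=2\,\mathrm{Re}(E_1 E_2^*),\quad V=-2\,\mathrm{Im}(E_1 E_2^*).}
#' The sign of V fixes the handedness convention: `(E1, E2) = (1, i)/sqrt(2)`
#' maps to `(S0, Q, U, V) = (1, 0, 0, 1)`.
#'
#' @param fields a `field_volume` (see [simulate_psoct_volume()]), or any
#'   list with complex arrays `E1`, `E2` of equal dimensions.
#' @return object of class `stokes_volume` with numeric arrays `S0`, `Q`,
#'   `U`, `V` of the same dimensions as the fields.
#' @examples
#' f <- list(E1 = array(1 + 0i, c(1, 1, 1, 1)), E2 = array(0i, c(1, 1, 1, 1)))
#' s <- stokes_from_fields(f)
#' c(s$S0, s$Q, s$U, s$V)  # 1 1 0 0
#' @export
stokes_from_fields <- function(fields) {
  E1 <- fields$E1; E2 <- fields$E2
  stopifnot(identical(dim(E1), dim(E2)))
  i1 <- Re(E1)^2 + Im(E1)^2
  i2 <- Re(E2)^2 + Im(E2)^2
  cross <- E1 * Conj(E2)
  structure(list(S0 = i1 + i2, Q = i1 - i2,
                 U = 2 * Re(cross), V = -2 * Im(cross),
                 params = fields$params),
            class = "stokes_volume")
}

#' Estimate per-channel additive-noise energy from a signal-free region
#'
#' The noise energy of channel i is the mean of `|Ei|^2` over the region
#' voxels and all repeats. The region is intended to be signal-free, e.g.
#' a vitreous band near the top of the volume.
#'
#' @param fields a `field_volume`.
#' @param region integer vector of linear voxel indices into the (x, b, z)
#'   grid, or a logical array of that shape.
#' @return object of class `noise_estimate` with fields `n1`, `n2` and the
#'   region size.
#' @export
estimate_noise <- function(fields, region) {
  if (is.array(region) && is.logical(region)) region <- which(region)
  if (length(region) == 0L) stop("noise region is empty")
  d <- dim(fields$E1)
  nrep <- if (length(d) == 4L) d[4L] else 1L
  nvox <- prod(d[1:3])
  idx <- as.vector(outer(region, (seq_len(nrep) - 1L) * nvox, "+"))
  n1 <- mean(Mod(fields$E1[idx])^2)
  n2 <- mean(Mod(fields$E2[idx])^2)
  structure(list(n1 = n1, n2 = n2, n_voxels = length(region)),
            class = "noise_estimate")
}

#' Signal-free vitreous band of a volume
#'
#' Convenience region for [estimate_noise()]: the top `n_slices` depth
#' pixels across the whole transverse grid, which the phantom keeps free
#' of tissue.
#'
#' @param params an [optic_params()].
#' @param n_slices number of anterior depth pixels to use.
#' @return integer vector of linear voxel indices.
#' @export
vitreous_region <- function(params, n_slices = 3L) {
  nxb <- params$n_alines * params$n_bscans
  as.vector(outer(seq_len(nxb), (seq_len(n_slices) - 1L) * nxb, "+"))
}
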