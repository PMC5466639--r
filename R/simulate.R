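#' Default layer reflectivities
#'
#' Mean backscattered signal energy per layer, in arbitrary intensity
#' units, relative to the neurosensory retina (1). The RPE is the
#' brightest band; focus reflectivity is set per focus by its
#' `reflectivity_gain`.
#'
#' @return named list of layer energies.
#' @export
layer_reflectivity <- function() {
  list(vitreous = 0, retina = 1, rpe = 5, choroid = 2.5)
}

# Per-voxel mean signal energy, depolarization flag and Jones vector for a
# phantom. Layers: vitreous (signal-free), retina (polarization-preserving),
# RPE band + choroid band (depolarizing), foci (depolarizing iff they carry
# melanin or melanolipofuscin) and exudate masses (depolarizing).
phantom_layer_map <- function(phantom, reflectivity = layer_reflectivity()) {
  p <- phantom$params
  nx <- p$n_alines; nb <- p$n_bscans; nz <- p$n_depth
  mu <- array(0, dim = c(nx, nb, nz))
  depol <- array(FALSE, dim = c(nx, nb, nz))
  jones1 <- array(1 + 0i, dim = c(nx, nb, nz))
  jones2 <- array(0 + 0i, dim = c(nx, nb, nz))

  z_of <- rep(seq_len(nz), each = nx * nb)
  rpe_line <- as.vector(phantom$rpe_depth_map)   # recycled over z
  in_retina <- z_of >= phantom$retina_top & z_of < rpe_line
  in_rpe <- z_of >= rpe_line & z_of < rpe_line + phantom$rpe_thickness
  in_choroid <- z_of >= rpe_line + phantom$rpe_thickness &
    z_of < rpe_line + phantom$rpe_thickness + phantom$choroid_thickness
  mu[in_retina] <- reflectivity$retina
  mu[in_rpe] <- reflectivity$rpe
  mu[in_choroid] <- reflectivity$choroid
  depol[in_rpe | in_choroid] <- TRUE

  set_region <- function(vox, energy, is_depol, j1, j2) {
    idx <- (vox[, 3L] - 1L) * nx * nb + (vox[, 2L] - 1L) * nx + vox[, 1L]
    mu[idx] <<- energy
    depol[idx] <<- is_depol
    jones1[idx] <<- j1
    jones2[idx] <<- j2
  }
  for (i in seq_along(phantom$foci)) {
    f <- phantom$foci[[i]]
    vox <- focus_voxels(phantom, i)
    f_depol <- f$melanin || f$melanolipofuscin
    # preserving foci scatter into their own fixed polarization state
    set_region(vox, reflectivity$retina * f$reflectivity_gain, f_depol,
               complex(real = 1 / sqrt(2)), complex(real = 1 / sqrt(2)))
  }
  for (m in phantom$exudate_masses) {
    vox <- ellipsoid_voxels(p, m$center, m$radius_um)
    set_region(vox, reflectivity$retina * m$reflectivity_gain, TRUE, 1 + 0i, 0 + 0i)
  }
  list(mu = mu, depol = depol, jones1 = jones1, jones2 = jones2)
}

#' Simulate a two-channel complex PS-OCT field volume
#'
#' Renders the phantom as speckled two-channel complex fields with repeats.
#' Polarization-preserving voxels are a single complex circular-Gaussian
#' scalar amplitude times the layer's fixed unit Jones vector, so their
#' normalized Stokes direction is constant within a layer. Depolarizing
#' voxels (RPE band, choroid band, melanin-bearing foci, exudate masses)
#' have two independent circular-Gaussian channels, giving normalized
#' Stokes directions uniform on the sphere across speckles. Additive
#' circular-Gaussian detector noise with the configured per-channel mean
#' energies is added to every voxel and repeat; vitreous voxels carry noise
#' only.
#'
#' @param phantom a [build_phantom()] result.
#' @param params an [optic_params()]; defaults to the phantom's.
#' @param seed integer seed (derived from the phantom's by default).
#' @param reflectivity layer energies, see [layer_reflectivity()].
#' @return object of class `field_volume`: complex arrays `E1`, `E2` with
#'   dim (x, b, z, repeat) and the `params`.
#' @export
simulate_psoct_volume <- function(phantom, params = phantom$params,
                                  seed = phantom$seed + 1L,
                                  reflectivity = layer_reflectivity()) {
  stopifnot(inherits(phantom, "retina_phantom"))
  if (!identical(dim(phantom$rpe_depth_map),
                 c(params$n_alines, params$n_bscans)))
    stop("phantom grid does not match params")
  lm <- phantom_layer_map(phantom, reflectivity)
  nx <- params$n_alines; nb <- params$n_bscans; nz <- params$n_depth
  nrep <- params$n_repeats
  n <- nx * nb * nz
  set.seed(seed)
  E1 <- array(0i, dim = c(nx, nb, nz, nrep))
  E2 <- array(0i, dim = c(nx, nb, nz, nrep))
  dp <- which(lm$depol)
  mu <- as.vector(lm$mu)
  for (r in seq_len(nrep)) {
    a <- rcomplex_gauss(n, mu)
    e1 <- a * as.vector(lm$jones1)
    e2 <- a * as.vector(lm$jones2)
    if (length(dp)) {
      e1[dp] <- rcomplex_gauss(length(dp), mu[dp] / 2)
      e2[dp] <- rcomplex_gauss(length(dp), mu[dp] / 2)
    }
    if (params$noise_energy_ch1 > 0)
      e1 <- e1 + rcomplex_gauss(n, params$noise_energy_ch1)
    if (params$noise_energy_ch2 > 0)
      e2 <- e2 + rcomplex_gauss(n, params$noise_energy_ch2)
    E1[, , , r] <- e1
    E2[, , , r] <- e2
  }
  structure(list(E1 = E1, E2 = E2, params = params, seed = as.integer(seed)),
            class = "field_volume")
}

#' Simulate NIR and SW autofluorescence en-face images
#'
#' Each image is a flat background plus one Gaussian blob per focus
#' footprint plus additive Gaussian pixel noise, quantized to 8 bits.
#' The NIR-AF (787 nm) blob is present iff the focus carries melanin or
#' melanolipofuscin; the SW-AF (488 nm) blob iff lipofuscin or
#' melanolipofuscin.
#'
#' @param phantom a `retina_phantom`.
#' @param params an [optic_params()].
#' @param seed integer seed.
#' @param background background gray level.
#' @param amplitude peak blob amplitude above background.
#' @param noise_sd pixel noise standard deviation (gray levels).
#' @return list with integer matrices `nir_af` and `sw_af` in 0..255.
#' @export
simulate_af_images <- function(phantom, params = phantom$params,
                               seed = phantom$seed + 2L,
                               background = 60, amplitude = 80,
                               noise_sd = 4) {
  set.seed(seed)
  nx <- params$n_alines; nb <- params$n_bscans
  x_um <- (seq_len(nx) - 1) * params$pitch_x
  b_um <- (seq_len(nb) - 1) * params$pitch_b
  blob_sum <- function(want) {
    img <- matrix(0, nx, nb)
    for (f in phantom$foci) {
      if (!want(f)) next
      s <- f$radius_um
      gx <- exp(-((x_um - (f$center[1] - 1) * params$pitch_x)^2) / (2 * s^2))
      gb <- exp(-((b_um - (f$center[2] - 1) * params$pitch_b)^2) / (2 * s^2))
      img <- img + amplitude * outer(gx, gb)
    }
    img
  }
  quantize <- function(img) {
    noisy <- img + matrix(stats::rnorm(nx * nb, sd = noise_sd), nx, nb)
    g <- round_half_up(pmin(pmax(noisy, 0), 255))
    storage.mode(g) <- "integer"
    g
  }
  nir <- quantize(background + blob_sum(function(f) f$melanin || f$melanolipofuscin))
  sw <- quantize(background + blob_sum(function(f) f$lipofuscin || f$melanolipofuscin))
  list(nir_af = nir, sw_af = sw)
}

#' Simulate a crossed-detector PS-SLO frame stack
#'
#' For each input polarization angle the crossed-detector frame is an
#' angle-independent floor contributed by the depolarizing structures in
#' each (x, b) column, plus an angle-dependent sinusoidal crosstalk term
#' (period pi in the input angle) from the polarization-preserving
#' structures, plus noise. The per-pixel minimum over angles therefore
#' isolates the depolarizing contribution up to the configured offset and
#' noise. Angles are `(k-1) * pi / n_angles`, so with the default zero
#' crosstalk phase the sinusoid attains its exact minimum at the first
#' angle.
#'
#' @param phantom a `retina_phantom`.
#' @param params an [optic_params()].
#' @param n_angles number of input polarization angles (>= 2).
#' @param seed integer seed.
#' @param offset angle-independent instrument offset of the crossed channel.
#' @param depol_gain scale from column depolarizing energy to crossed signal.
#' @param crosstalk_gain scale from column preserving energy to the
#'   sinusoid amplitude.
#' @param phase crosstalk phase (radians).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @return object of class `psslo_stack`: `frames` array (x, b, angle),
#'   `angles`, and the generator settings.
#' @export
simulate_psslo_stack <- function(phantom, params = phantom$params,
                                 n_angles = 8L, seed = phantom$seed + 3L,
                                 offset = 2, depol_gain = 0.15,
                                 crosstalk_gain = 0.05, phase = 0,
                                 noise_sd = 0.05) {
  if (n_angles < 2) stop("n_angles must be >= 2")
  lm <- phantom_layer_map(phantom)
  nx <- params$n_alines; nb <- params$n_bscans
  depol_col <- apply(lm$mu * lm$depol, c(1, 2), sum)
  pres_col <- apply(lm$mu * !lm$depol, c(1, 2), sum)
  set.seed(seed)
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  frames <- array(0, dim = c(nx, nb, n_angles))
  for (k in seq_len(n_angles)) {
    frames[, , k] <- offset + depol_gain * depol_col +
      crosstalk_gain * pres_col * sin(angles[k] - phase)^2 +
      matrix(stats::rnorm(nx * nb, sd = noise_sd), nx, nb)
  }
  structure(list(frames = frames, angles = angles, offset = offset,
                 depol_gain = depol_gain, crosstalk_gain = crosstalk_gain,
                 phase = phase, seed = as.integer(seed)),
            class = "psslo_stack")
}

#' RPE anterior-boundary segmentation line
#'
#' @param depth_map integer matrix of per-(x, b) depth indices (1-based).
#' @param provenance one of `"truth"`, `"manual"`, `"file"`.
#' @param n_depth optional depth-grid size for validation.
#' @return object of class `segmentation_line`.
#' @export
segmentation_line <- function(depth_map, provenance = c("truth", "manual", "file"),
                              n_depth = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(depth_map), all(depth_map >= 1))
  if (!is.null(n_depth) && any(depth_map > n_depth))
    stop("segmentation indices exceed the depth grid")
  structure(list(depth = depth_map, provenance = provenance),
            class = "segmentation_line")
}

#' Simulate one complete synthetic eye
#'
#' Assembles the co-registered multimodal dataset for one phantom: the
#' PS-OCT field volume with repeats, the PS-SLO frame stack, the NIR/SW
#' autofluorescence images, the truth RPE segmentation and the ground-truth
#' focus labels and PED volume. All en-face modalities share the (x, b)
#' grid by construction.
#'
#' @param phantom a `retina_phantom`.
#' @param params an [optic_params()].
#' @param n_angles PS-SLO angle count.
#' @return object of class `synthetic_eye`: fields, psslo, nir_af, sw_af,
#'   segmentation, group and a `truth` list (per-focus flags and labels,
#'   voxel sets, analytic + discrete PED volume).
#' @export
simulate_eye_dataset <- function(phantom, params = phantom$params,
                                 n_angles = 8L) {
  fields <- simulate_psoct_volume(phantom, params)
  af <- simulate_af_images(phantom, params)
  psslo <- simulate_psslo_stack(phantom, params, n_angles = n_angles)
  truth <- list(
    focus_flags = lapply(phantom$foci, function(f)
      list(melanin = f$melanin, lipofuscin = f$lipofuscin,
           melanolipofuscin = f$melanolipofuscin,
           migration = f$migration_truth)),
    focus_voxels = lapply(seq_along(phantom$foci),
                          function(i) focus_voxels(phantom, i)),
    ped_volume_analytic_mm3 = if (is.null(phantom$ped_dome)) 0 else
      dome_volume_mm3(phantom$ped_dome),
    ped_volume_discrete_mm3 = true_ped_volume_mm3(phantom)
  )
  structure(list(
    phantom = phantom, fields = fields, psslo = psslo,
    nir_af = af$nir_af, sw_af = af$sw_af,
    segmentation = segmentation_line(phantom$rpe_depth_map, "truth",
                                     params$n_depth),
    group = phantom$group, truth = truth
  ), class = "synthetic_eye")
}

#' Generate a synthetic cohort
#'
#' Builds one [simulate_eye_dataset()] per requested eye, with per-eye
#' seeds derived reproducibly from the master seed.
#'
#' @param counts named integer vector of eye counts per group (names from
#'   [study_groups()]); groups may be omitted or zero.
#' @param params an [optic_params()] shared by all eyes.
#' @param seed master seed.
#' @param config per-group phantom configuration ([group_config()]).
#' @param simulate if `FALSE`, return phantoms only (no field rendering);
#'   useful for geometry-only analyses such as PED volumetry.
#' @return list of `synthetic_eye` (or `retina_phantom`) objects with an
#'   `eye_id` and `seed` attached to each.
#' @export
generate_cohort <- function(counts, params = optic_params(), seed = 1L,
                            config = group_config(), simulate = TRUE) {
  stopifnot(all(counts >= 0), !is.null(names(counts)))
  bad <- setdiff(names(counts), study_groups())
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  groups <- rep(names(counts), times = counts)
  set.seed(seed)
  eye_seeds <- sample.int(.Machine$integer.max - 10L, length(groups))
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    ph <- build_phantom(params, groups[i], seed = eye_seeds[i], config = config)
    obj <- if (simulate) simulate_eye_dataset(ph) else ph
    obj$eye_id <- sprintf("eye%03d", i)
    obj$seed <- eye_seeds[i]
    out[[i]] <- obj
  }
  out
}
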