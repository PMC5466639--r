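#' Specify one intraretinal hyperreflective focus
#'
#' A hyperreflective focus (HRF) is a small bright intraretinal lesion. Its
#' granule content determines how it appears across the modalities: melanin
#' depolarizes (low DOPU on PS-OCT, depolarized signal on PS-SLO) and is
#' hyper-autofluorescent at 787 nm (NIR-AF); lipofuscin is
#' hyper-autofluorescent at 488 nm (SW-AF); melanolipofuscin behaves as
#' both. A focus counts as migrated RPE when it carries melanin and
#' lipofuscin together, or melanolipofuscin.
#'
#' @param center integer vector `c(x, b, z)` of the focus centre
#'   (1-based voxel indices).
#' @param radius_um focus radius in micrometres (isotropic in tissue; the
#'   voxel footprint is anisotropic because the pitches differ).
#' @param reflectivity_gain OCT reflectivity multiplier relative to the
#'   neurosensory retina; must exceed 1 (the focus is hyperreflective).
#' @param melanin,lipofuscin,melanolipofuscin logical content flags.
#' @return an object of class `focus_spec` with a `migration_truth` field.
#' @export
focus_spec <- function(center, radius_um = 25, reflectivity_gain = 4,
                       melanin = FALSE, lipofuscin = FALSE,
                       melanolipofuscin = FALSE) {
  stopifnot(length(center) == 3L, all(center >= 1), radius_um > 0)
  if (reflectivity_gain <= 1) stop("reflectivity_gain must be > 1")
  structure(list(
    center = as.integer(center), radius_um = radius_um,
    reflectivity_gain = reflectivity_gain,
    melanin = isTRUE(melanin), lipofuscin = isTRUE(lipofuscin),
    melanolipofuscin = isTRUE(melanolipofuscin),
    migration_truth = (isTRUE(melanin) && isTRUE(lipofuscin)) ||
      isTRUE(melanolipofuscin)
  ), class = "focus_spec")
}

#' Per-group phantom configuration
#'
#' Distributional defaults used by [build_phantom()] for each study group:
#' the kind of pigment-epithelial detachment (PED), the dome size, the
#' expected number of intraretinal foci and the probability that a focus
#' has migrated-RPE granule content. Serous PED domes are larger than
#' drusenoid ones, and in the serous group the expected focus load grows
#' with the dome volume so that HRF and PED volumes are positively coupled.
#' Groups in which hard-exudate masses would dominate are not emulated with
#' masses by default: eyes with apparent hard exudates are outside the
#' cohort definition, and masses can be injected explicitly with
#' [add_exudate_mass()].
#'
#' @return named list of per-group configuration lists.
#' @export
group_config <- function() {
  base <- function(ped, lambda, min_foci, p_mig,
                   height = 0, sx = 0, sy = 0) {
    list(ped_kind = ped, lambda_foci = lambda, min_foci = min_foci,
         p_migratory = p_mig, dome_height_um = height,
         dome_sigma_x_um = sx, dome_sigma_y_um = sy,
         focus_radius_um = c(18, 30))
  }
  list(
    early_intermediate = base("none", 1.2, 0L, 0.55),
    drusenoid_ped      = base("drusenoid", 2.0, 1L, 0.85,
                              height = 90, sx = 180, sy = 180),
    serous_ped         = base("serous", 2.5, 1L, 0.95,
                              height = 200, sx = 320, sy = 320),
    remission          = base("none", 2.0, 0L, 0.30),
    fibrosis           = base("none", 1.5, 0L, 0.12),
    geographic_atrophy = base("none", 1.2, 0L, 0.45)
  )
}

# Dome elevation in micrometres over the (x, b) grid for an elliptical
# Gaussian dome; centre and sigmas in micrometres.
dome_elevation_um <- function(params, dome) {
  x_um <- (seq_len(params$n_alines) - 1) * params$pitch_x
  b_um <- (seq_len(params$n_bscans) - 1) * params$pitch_b
  gx <- exp(-((x_um - dome$center_x_um)^2) / (2 * dome$sigma_x_um^2))
  gb <- exp(-((b_um - dome$center_b_um)^2) / (2 * dome$sigma_y_um^2))
  dome$height_um * outer(gx, gb)
}

#' Analytic volume of the elliptical Gaussian PED dome
#'
#' The dome elevation is `H * exp(-dx^2/(2*sx^2) - db^2/(2*sy^2))`; its
#' integral over the plane is `2 * pi * H * sx * sy`.
#'
#' @param dome the `ped_dome` element of a phantom.
#' @return dome volume in mm^3.
#' @export
dome_volume_mm3 <- function(dome) {
  2 * pi * dome$height_um * dome$sigma_x_um * dome$sigma_y_um * 1e-9
}

#' Build a synthetic retina phantom
#'
#' Draws a retina geometry for one eye of a given study group: a flat
#' vitreous/retina/RPE/choroid layering, an optional PED dome that lifts
#' the RPE anterior boundary, and a set of intraretinal hyperreflective
#' foci anterior to the RPE with granule-content flags drawn from the
#' group's migration probability. Depth indices are 1-based and increase
#' anterior to posterior; "anterior to the RPE" means `z < rpe_depth_map[x, b]`
#' (half-open).
#'
#' @param params an [optic_params()] object.
#' @param group one of [study_groups()].
#' @param seed integer seed; identical seeds give identical phantoms.
#' @param config per-group configuration, see [group_config()].
#' @return an object of class `retina_phantom`.
#' @export
build_phantom <- function(params, group, seed = params$seed,
                          config = group_config()) {
  if (!group %in% study_groups())
    stop(sprintf("unknown group label '%s'; expected one of: %s",
                 group, paste(study_groups(), collapse = ", ")))
  cfg <- config[[group]]
  set.seed(seed)
  nx <- params$n_alines; nb <- params$n_bscans; nz <- params$n_depth

  retina_top <- max(6L, as.integer(round(0.30 * nz)))
  rpe_base <- as.integer(round(0.72 * nz))
  rpe_thickness <- max(2L, as.integer(ceiling(10 / params$pitch_z)))
  choroid_thickness <- min(nz - rpe_base - rpe_thickness,
                           as.integer(ceiling(60 / params$pitch_z)))

  rpe_depth <- matrix(rpe_base, nx, nb)
  ped_dome <- NULL
  if (cfg$ped_kind != "none") {
    jit <- stats::runif(3, 0.85, 1.15)
    ped_dome <- list(
      center_x_um = (nx / 2 + stats::runif(1, -0.05, 0.05) * nx) * params$pitch_x,
      center_b_um = (nb / 2 + stats::runif(1, -0.05, 0.05) * nb) * params$pitch_b,
      height_um = cfg$dome_height_um * jit[1],
      sigma_x_um = cfg$dome_sigma_x_um * jit[2],
      sigma_y_um = cfg$dome_sigma_y_um * jit[3]
    )
    elev <- dome_elevation_um(params, ped_dome)
    rpe_depth <- rpe_depth - matrix(as.integer(round(elev / params$pitch_z)),
                                    nx, nb)
    rpe_depth <- pmax(rpe_depth, retina_top + 4L)
  }

  # focus load; in the serous group coupled to dome volume
  lambda <- cfg$lambda_foci
  if (group == "serous_ped" && !is.null(ped_dome)) {
    typical <- 2 * pi * cfg$dome_height_um *
      cfg$dome_sigma_x_um * cfg$dome_sigma_y_um * 1e-9
    lambda <- lambda * (0.4 + 1.2 * dome_volume_mm3(ped_dome) / typical)
  }
  n_foci <- max(cfg$min_foci, stats::rpois(1, lambda))

  foci <- list()
  taken <- matrix(FALSE, nx, nb)   # transverse footprints already used
  if (n_foci > 0) {
    for (i in seq_len(n_foci)) {
      radius <- stats::runif(1, cfg$focus_radius_um[1], cfg$focus_radius_um[2])
      rz_vox <- ceiling(radius / params$pitch_z)
      rx_vox <- ceiling(radius / params$pitch_x)
      rb_vox <- ceiling(radius / params$pitch_b)
      # rejection-sample a transverse position with enough anterior room
      # (under a tall dome the space above the apex can vanish) and a
      # footprint clear of earlier foci: distinct HRF are separate lesions,
      # and stacked depolarizing foci would read as one axial mass
      cx <- cb <- cz <- NA_integer_
      for (try in 1:60) {
        px <- sample(seq(1L + rx_vox, nx - rx_vox), 1)
        pb <- sample(seq(1L + rb_vox, max(1L + rb_vox, nb - rb_vox)), 1)
        xr <- max(1L, px - rx_vox - 2L):min(nx, px + rx_vox + 2L)
        br <- max(1L, pb - rb_vox - 2L):min(nb, pb + rb_vox + 2L)
        if (any(taken[xr, br])) next
        z_hi <- rpe_depth[px, pb] - rz_vox - 3L   # keep whole focus anterior
        z_lo <- retina_top + rz_vox + 1L
        if (z_hi > z_lo) {
          cx <- px; cb <- pb
          cz <- sample(seq(z_lo, z_hi), 1)
          taken[xr, br] <- TRUE
          break
        }
      }
      if (is.na(cx)) next
      if (stats::runif(1) < cfg$p_migratory) {
        flags <- if (stats::runif(1) < 0.5) c(TRUE, TRUE, FALSE) else c(FALSE, FALSE, TRUE)
      } else {
        flags <- switch(sample(3, 1),
                        c(TRUE, FALSE, FALSE),    # melanin only
                        c(FALSE, TRUE, FALSE),    # lipofuscin only
                        c(FALSE, FALSE, FALSE))   # plain HRF
      }
      foci[[length(foci) + 1L]] <- focus_spec(
        center = c(cx, cb, cz), radius_um = radius,
        reflectivity_gain = stats::runif(1, 3.5, 5),
        melanin = flags[1], lipofuscin = flags[2], melanolipofuscin = flags[3])
    }
  }

  structure(list(
    params = params, group = group, seed = as.integer(seed),
    retina_top = retina_top, rpe_base = rpe_base,
    rpe_thickness = rpe_thickness, choroid_thickness = choroid_thickness,
    rpe_depth_map = rpe_depth,
    ped_kind = cfg$ped_kind, ped_dome = ped_dome,
    foci = foci, exudate_masses = list()
  ), class = "retina_phantom")
}

#' Inject a hard-exudate-like depolarizing mass into a phantom
#'
#' Hard exudates appear as a congested mass of depolarizing foci; such
#' masses confound migrated-RPE reading and trigger the classifier's
#' exclusion rule. The mass is an ellipsoid of depolarizing tissue anterior
#' to the RPE.
#'
#' @param phantom a `retina_phantom`.
#' @param center `c(x, b, z)` voxel centre.
#' @param radius_um mass radius in micrometres (should be large enough to
#'   exceed the classifier's `mass_min_voxels`).
#' @param reflectivity_gain reflectivity multiplier.
#' @return the phantom with the mass appended.
#' @export
add_exudate_mass <- function(phantom, center, radius_um = 60,
                             reflectivity_gain = 4) {
  stopifnot(inherits(phantom, "retina_phantom"), length(center) == 3L)
  phantom$exudate_masses[[length(phantom$exudate_masses) + 1L]] <-
    list(center = as.integer(center), radius_um = radius_um,
         reflectivity_gain = reflectivity_gain)
  phantom
}

# Voxel index rows (x, b, z) of an ellipsoid of the given metric radius
# centred at `center`, clipped to the grid.
ellipsoid_voxels <- function(params, center, radius_um) {
  rx <- ceiling(radius_um / params$pitch_x)
  rb <- ceiling(radius_um / params$pitch_b)
  rz <- ceiling(radius_um / params$pitch_z)
  xs <- max(1L, center[1] - rx):min(params$n_alines, center[1] + rx)
  bs <- max(1L, center[2] - rb):min(params$n_bscans, center[2] + rb)
  zs <- max(1L, center[3] - rz):min(params$n_depth, center[3] + rz)
  g <- expand.grid(x = xs, b = bs, z = zs)
  d2 <- ((g$x - center[1]) * params$pitch_x)^2 +
    ((g$b - center[2]) * params$pitch_b)^2 +
    ((g$z - center[3]) * params$pitch_z)^2
  as.matrix(g[d2 <= radius_um^2, , drop = FALSE])
}

#' Voxel set of one focus
#'
#' @param phantom a `retina_phantom`.
#' @param i focus index.
#' @return integer matrix with columns x, b, z (1-based voxel indices).
#' @export
focus_voxels <- function(phantom, i) {
  f <- phantom$foci[[i]]
  ellipsoid_voxels(phantom$params, f$center, f$radius_um)
}

#' Discrete true PED volume of a phantom
#'
#' Sum over the footprint of the voxelized RPE elevation (depth-index lift
#' times the depth pitch) times the transverse pixel area. Differs from
#' [dome_volume_mm3()] only by depth quantization and grid truncation.
#'
#' @param phantom a `retina_phantom`.
#' @return volume in mm^3 (0 when the phantom has no PED).
#' @export
true_ped_volume_mm3 <- function(phantom) {
  if (phantom$ped_kind == "none") return(0)
  p <- phantom$params
  lift_vox <- pmax(0L, phantom$rpe_base - phantom$rpe_depth_map)
  sum(lift_vox) * p$pitch_z * p$pitch_x * p$pitch_b * 1e-9
}

#' @export
print.retina_phantom <- function(x, ...) {
  cat(sprintf("retina_phantom (%s): %d x %d grid, RPE base at z=%d, %d foci, PED=%s\n",
              x$group, x$params$n_alines, x$params$n_bscans, x$rpe_base,
              length(x$foci), x$ped_kind))
  invisible(x)
}
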