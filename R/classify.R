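#' Thresholds for the four-modality concordance rule
#'
#' A focus is read as migrated RPE only when all four modalities agree:
#' low DOPU within the focus on PS-OCT (strictly below `dopu_low`),
#' depolarization at its footprint on the PS-SLO depolarized light image,
#' and hyper-autofluorescence at its footprint on both NIR-AF and SW-AF.
#' The en-face evidence is operationalized as a z-score of the footprint
#' mean against a local background annulus (clinical grading judges these
#' by eye; the z-score thresholds are the reproducible surrogate).
#'
#' @param dopu_low DOPU threshold (strict `<`), default 0.8.
#' @param af_z minimum footprint z-score on each AF image.
#' @param psslo_z minimum footprint z-score on the depolarized light image.
#' @param mass_min_voxels minimum connected low-DOPU component size that
#'   counts as a hard-exudate-like "low-DOPU mass" for the exclusion rule.
#' @param annulus_um inner and outer background annulus radii beyond the
#'   focus radius, in micrometres.
#' @param mass_margin_vox depth margin (voxels) added to the segmentation
#'   line for the mass search (`z < line + margin`). The default of -2
#'   keeps the search strictly clear of the normal RPE band: the DOPU
#'   kernel has a half-width of one depth pixel, so the voxels immediately
#'   above the line already pool RPE samples and read low without any
#'   lesion being present.
#' @return object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(dopu_low = 0.8, af_z = 2, psslo_z = 2,
                                      mass_min_voxels = 200L,
                                      annulus_um = c(40, 160),
                                      mass_margin_vox = -2L) {
  stopifnot(dopu_low > 0, dopu_low < 1, af_z > 0, psslo_z > 0,
            mass_min_voxels >= 1, length(annulus_um) == 2L,
            annulus_um[2] > annulus_um[1])
  structure(list(dopu_low = dopu_low, af_z = af_z, psslo_z = psslo_z,
                 mass_min_voxels = as.integer(mass_min_voxels),
                 annulus_um = annulus_um,
                 mass_margin_vox = as.integer(mass_margin_vox)),
            class = "classification_thresholds")
}

# Dilate a voxel index set by +/- h voxels along the A-line and depth axes
# (the in-B-scan directions the DOPU kernel smears over).
dilate_voxels <- function(vox, hx, hz, dims) {
  if (nrow(vox) == 0) return(vox)
  off <- expand.grid(dx = -hx:hx, dz = -hz:hz)
  out <- do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    cbind(vox[, 1] + off$dx[i], vox[, 2], vox[, 3] + off$dz[i])))
  out <- out[out[, 1] >= 1 & out[, 1] <= dims[1] &
               out[, 3] >= 1 & out[, 3] <= dims[3], , drop = FALSE]
  out[!duplicated(out), , drop = FALSE]
}

# z-score of the footprint mean of `img` against a background annulus
# around the footprint. `exclude` marks pixels never used as background
# (all focus footprints).
footprint_zscore <- function(img, footprint, exclude, params, annulus_um) {
  stopifnot(nrow(footprint) > 0)
  nx <- nrow(img); nb <- ncol(img)
  x_um <- (seq_len(nx) - 1) * params$pitch_x
  b_um <- (seq_len(nb) - 1) * params$pitch_b
  fx <- (footprint[, 1] - 1) * params$pitch_x
  fb <- (footprint[, 2] - 1) * params$pitch_b
  # distance of every pixel to the nearest footprint pixel
  dmin <- matrix(Inf, nx, nb)
  for (i in seq_len(nrow(footprint))) {
    d2 <- outer((x_um - fx[i])^2, (b_um - fb[i])^2, "+")
    dmin <- pmin(dmin, d2)
  }
  dmin <- sqrt(dmin)
  ann <- dmin >= annulus_um[1] & dmin <= annulus_um[2] & !exclude
  if (sum(ann) < 8) stop("background annulus too small")
  bg <- img[ann]
  fg <- img[cbind(footprint[, 1], footprint[, 2])]
  s <- stats::sd(bg)
  (mean(fg) - mean(bg)) / max(s, .Machine$double.eps)
}

#' Score one focus against the four modalities
#'
#' Computes the minimum DOPU over the focus voxel set (valid voxels only)
#' and footprint z-scores on the PS-SLO depolarized light image and the
#' two AF images, all registered on the shared (x, b) grid.
#'
#' @param focus_vox integer (x, b, z) matrix of the focus voxels.
#' @param dopu a `dopu_volume`.
#' @param psslo_img matrix: the 8-bit (or raw) depolarized light image.
#' @param nir_af,sw_af 8-bit AF matrices.
#' @param params an [optic_params()].
#' @param thresholds a [classification_thresholds()].
#' @param all_footprints optional n x 2 matrix of every focus footprint in
#'   the eye; these pixels are excluded from every background annulus.
#' @param id focus identifier.
#' @return object of class `focus_observation` (unlabeled).
#' @export
score_focus_modalities <- function(focus_vox, dopu, psslo_img, nir_af, sw_af,
                                   params, thresholds = classification_thresholds(),
                                   all_footprints = NULL, id = 1L) {
  if (is.null(focus_vox) || nrow(focus_vox) == 0)
    stop("focus voxel set is empty")
  footprint <- unique(focus_vox[, 1:2, drop = FALSE])
  exclude <- matrix(FALSE, nrow(psslo_img), ncol(psslo_img))
  fp_all <- if (is.null(all_footprints)) footprint else all_footprints
  exclude[cbind(fp_all[, 1], fp_all[, 2])] <- TRUE

  vals <- dopu$dopu[focus_vox]
  ok <- dopu$valid[focus_vox]
  min_dopu <- if (any(ok)) min(vals[ok]) else NA_real_

  structure(list(
    id = id, voxels = focus_vox, footprint = footprint,
    min_dopu = min_dopu,
    psslo_z = footprint_zscore(psslo_img, footprint, exclude, params,
                               thresholds$annulus_um),
    nir_z = footprint_zscore(nir_af, footprint, exclude, params,
                             thresholds$annulus_um),
    sw_z = footprint_zscore(sw_af, footprint, exclude, params,
                            thresholds$annulus_um),
    excluded_mass = NA, label = NA_character_
  ), class = "focus_observation")
}

# Detect connected low-DOPU masses anterior to (segmentation + margin),
# outside the given focus voxels, and report which (x, b) columns any
# qualifying mass touches.
low_dopu_mass_columns <- function(dopu, segmentation, thresholds,
                                  exclude_vox = NULL) {
  d <- dim(dopu$dopu)
  z_of <- rep(seq_len(d[3]), each = d[1] * d[2])
  anterior <- array(z_of < as.vector(segmentation$depth) +
                      thresholds$mass_margin_vox, dim = d)
  mask <- (dopu$dopu < thresholds$dopu_low) & dopu$valid & anterior
  if (!is.null(exclude_vox) && nrow(exclude_vox))
    mask[exclude_vox] <- FALSE
  if (!any(mask)) return(matrix(integer(0), 0, 2))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes >= thresholds$mass_min_voxels)
  if (!length(big)) return(matrix(integer(0), 0, 2))
  pos <- arrayInd(which(lab > 0 & array(lab %in% big, dim = d)), d)
  unique(pos[, 1:2, drop = FALSE])
}

#' Apply the concordance rule and the low-DOPU-mass exclusion
#'
#' A focus is `excluded` when a connected low-DOPU mass of at least
#' `mass_min_voxels` voxels (outside the focus's own voxels, anterior to
#' the segmentation line plus a small margin so normal sub-RPE
#' depolarization never qualifies) overlaps the focus's (x, b) footprint
#' at any depth — the hard-exudate confound. Otherwise it is labeled
#' `migration` iff the minimum DOPU is strictly below `dopu_low` AND the
#' PS-SLO z-score and both AF z-scores meet their thresholds; else
#' `no_migration`.
#'
#' Because the DOPU kernel pools neighbouring pixels, the voxels within
#' one kernel half-width of the focus read low on account of the focus
#' itself; the focus set is dilated by the kernel half-widths before the
#' mass search so this halo is never mistaken for a separate mass.
#'
#' @param obs a scored `focus_observation`.
#' @param dopu the eye's `dopu_volume`.
#' @param segmentation the eye's [segmentation_line()].
#' @param thresholds a [classification_thresholds()].
#' @return the observation with `excluded_mass` and `label` filled in.
#' @export
classify_focus <- function(obs, dopu, segmentation,
                           thresholds = classification_thresholds()) {
  hx <- (dopu$kernel$transverse - 1L) %/% 2L
  hz <- (dopu$kernel$depth - 1L) %/% 2L
  halo <- dilate_voxels(obs$voxels, hx, hz, dim(dopu$dopu))
  mass_cols <- low_dopu_mass_columns(dopu, segmentation, thresholds,
                                     exclude_vox = halo)
  overlaps <- nrow(mass_cols) > 0 &&
    any(interaction(mass_cols[, 1], mass_cols[, 2]) %in%
          interaction(obs$footprint[, 1], obs$footprint[, 2]))
  obs$excluded_mass <- overlaps
  obs$label <- if (overlaps) {
    "excluded"
  } else if (!is.na(obs$min_dopu) && obs$min_dopu < thresholds$dopu_low &&
             obs$psslo_z >= thresholds$psslo_z &&
             obs$nir_z >= thresholds$af_z && obs$sw_z >= thresholds$af_z) {
    "migration"
  } else {
    "no_migration"
  }
  obs
}

#' Eye-level tally from labeled foci
#'
#' Mutually exclusive columns with migration precedence: an eye with any
#' migrating focus counts in the "HRF with RPE migration" column only;
#' an eye with only non-migrating foci counts in the "without" column.
#' Excluded foci are ignored for the tallies.
#'
#' @param foci list of labeled `focus_observation`s.
#' @param eye_id eye identifier.
#' @param group study group label.
#' @param hrf_volume_mm3 total HRF volume (voxel formula).
#' @param ped_volume_mm3 PED volume (Cavalieri), or `NA`.
#' @return object of class `eye_record`.
#' @export
classify_eye <- function(foci, eye_id = NA_character_,
                         group = NA_character_,
                         hrf_volume_mm3 = NA_real_, ped_volume_mm3 = NA_real_) {
  labels <- vapply(foci, function(f) f$label, character(1))
  has_mig <- any(labels == "migration")
  structure(list(
    eye_id = eye_id, group = group,
    has_migrating_hrf = has_mig,
    has_nonmigrating_hrf = !has_mig && any(labels == "no_migration"),
    n_foci = length(foci), n_excluded = sum(labels == "excluded"),
    hrf_volume_mm3 = hrf_volume_mm3, ped_volume_mm3 = ped_volume_mm3,
    focus_labels = labels
  ), class = "eye_record")
}

#' Cohen's kappa for interobserver agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and the
#' chance agreement `p_e` from the product of the two raters' marginal
#' frequencies. When both raters are constant and identical (`p_e = 1`),
#' agreement is perfect by convention and 1 is returned.
#'
#' @param ratings_a,ratings_b equal-length category vectors.
#' @return kappa value.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors differ in length")
  if (length(ratings_a) < 1) stop("need at least one rated item")
  cats <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = cats)
  b <- factor(as.character(ratings_b), levels = cats)
  n <- length(a)
  po <- mean(a == b)
  pe <- sum((table(a) / n) * (table(b) / n))
  if (abs(1 - pe) < .Machine$double.eps) return(1)
  (po - pe) / (1 - pe)
}
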