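test_that("Shanbhag threshold separates a two-level histogram and matches the oracle", {
  h <- integer(256); h[51] <- 700; h[201] <- 300   # levels 50 and 200
  t <- shanbhag_threshold(h)
  expect_identical(t, naive_shanbhag(h))
  expect_true(t >= 50 && t < 200)   # foreground (> t) is exactly level 200

  hu <- rep(10L, 256)               # uniform histogram
  expect_identical(shanbhag_threshold(hu), naive_shanbhag(hu))

  h1 <- integer(256); h1[100] <- 50
  expect_error(shanbhag_threshold(h1), "degenerate")
})

test_that("Shanbhag equals the exhaustive criterion scan on 100 random histograms", {
  set.seed(2024)
  for (i in 1:100) {
    h <- integer(256)
    k <- sample(2:256, 1)
    h[sample(256, k)] <- rpois(k, sample(c(2, 20, 200), 1)) + 1L
    expect_identical(shanbhag_threshold(h), naive_shanbhag(h))
  }
})

test_that("binarization keeps exactly the upper level of a two-level image", {
  img <- matrix(50L, 20, 20)
  img[5:8, 5:8] <- 200L
  fg <- binarize_bscan(img)
  expect_identical(fg, img == 200L)
  expect_error(binarize_bscan(matrix(7L, 4, 4)), "degenerate")
})

test_that("bright focus cores survive binarization of a high-contrast B-scan", {
  set.seed(55)
  img <- matrix(as.integer(pmin(pmax(round(rnorm(40 * 60, 40, 8)), 0), 255)), 40, 60)
  core <- cbind(rep(10:14, 5), rep(20:24, each = 5))
  img[core] <- as.integer(round(rnorm(nrow(core), 210, 10)))
  fg <- binarize_bscan(img)
  expect_true(all(fg[core]))          # foreground contains the focus cores
  expect_lt(shanbhag_threshold(hist256(img)), 180)
})

test_that("the voxel formula gives 989.82 cubic microns per voxel", {
  p <- optic_params()
  expect_equal(measure_hrf_volume(0, p)$value, 0)
  expect_equal(measure_hrf_volume(1, p)$value, 9.8982e-7)
  expect_equal(measure_hrf_volume(100, p)$value, 9.8982e-5)
})

test_that("HRF volume is additive over disjoint region sets", {
  p <- test_params()
  a <- structure(list(voxels = cbind(1:5, 1, 10), source = "truth"),
                 class = "hrf_region_set")
  b <- structure(list(voxels = cbind(1:7, 2, 12), source = "truth"),
                 class = "hrf_region_set")
  ab <- structure(list(voxels = rbind(a$voxels, b$voxels), source = "truth"),
                  class = "hrf_region_set")
  expect_equal(measure_hrf_volume(ab, p)$value,
               measure_hrf_volume(a, p)$value + measure_hrf_volume(b, p)$value)
})

test_that("Cavalieri sums slice areas times spacing", {
  expect_equal(cavalieri_ped_volume(0.01, 23.5)$value, 2.35e-4)
  expect_equal(cavalieri_ped_volume(rep(0, 10), 23.5)$value, 0)
  expect_error(cavalieri_ped_volume(c(0.1, -0.01)), "negative")
})

test_that("Cavalieri volumetry of the dome phantom is within 3% of the analytic volume", {
  p <- optic_params(n_depth = 256, noise_energy_ch1 = 0, noise_energy_ch2 = 0)
  ph <- build_phantom(p, "serous_ped", seed = 12)
  seg <- segmentation_line(ph$rpe_depth_map, "truth", p$n_depth)
  areas <- ped_cross_section_areas(seg, ph$rpe_base, p)
  est <- cavalieri_ped_volume(areas, p$pitch_b)$value
  expect_lt(abs(est / dome_volume_mm3(ph$ped_dome) - 1), 0.03)
})

test_that("halving the Cavalieri spacing changes the dome estimate within the discretization bound", {
  p1 <- optic_params(n_bscans = 128, n_depth = 256, pitch_b = 47,
                     noise_energy_ch1 = 0, noise_energy_ch2 = 0)
  p2 <- optic_params(n_bscans = 256, n_depth = 256, pitch_b = 23.5,
                     noise_energy_ch1 = 0, noise_energy_ch2 = 0)
  dome <- list(center_x_um = 3000, center_b_um = 3000, height_um = 200,
               sigma_x_um = 320, sigma_y_um = 320)
  vol_at <- function(p) {
    elev <- polrpe:::dome_elevation_um(p, dome)
    depth <- matrix(200L, p$n_alines, p$n_bscans) -
      round(elev / p$pitch_z)
    seg <- segmentation_line(depth, "manual", p$n_depth)
    cavalieri_ped_volume(ped_cross_section_areas(seg, 200L, p), p$pitch_b)$value
  }
  truth <- 2 * pi * 200 * 320 * 320 * 1e-9
  expect_lt(abs(vol_at(p1) - vol_at(p2)), 0.02 * truth)
  expect_lt(abs(vol_at(p2) / truth - 1), 0.03)
})

test_that("truth-guided selection recovers the generator's focus voxels on a clean eye", {
  # default noise level: the displayed noise floor anchors the histogram,
  # which is the regime the Shanbhag binarization is designed for
  p <- test_params(nx = 48, nb = 24, nz = 64, noise = 0.01)
  ph <- build_phantom(p, "remission", seed = 23)
  expect_gt(length(ph$foci), 0)
  f <- simulate_psoct_volume(ph, p)
  s <- stokes_from_fields(f)
  seg <- segmentation_line(ph$rpe_depth_map, "truth", p$n_depth)
  tv <- lapply(seq_along(ph$foci), function(i) focus_voxels(ph, i))
  # pure truth path: exact voxel-count recovery by construction
  sel_truth <- select_hrf_regions(s, tv, seg, binarize = FALSE)
  expect_identical(nrow(sel_truth$voxels), sum(vapply(tv, nrow, 1L)))
  # binarized path on a high-SNR eye keeps the full hyperreflective set
  sel_bin <- select_hrf_regions(s, tv, seg, binarize = TRUE)
  expect_identical(nrow(sel_bin$voxels), nrow(sel_truth$voxels))
})
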