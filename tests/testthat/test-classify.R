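# A hand-built eye on a small grid: flat segmentation at z = 20, one focus
# occupying a 3x3x3 block, constructed DOPU/en-face images.
toy_params <- function() test_params(nx = 30, nb = 20, nz = 24)

toy_focus <- function() as.matrix(expand.grid(x = 14:16, b = 9:11, z = 10:12))

toy_dopu <- function(focus_low = TRUE) {
  arr <- array(0.95, c(30, 20, 24))
  arr[, , 20:24] <- 0.2                       # RPE/choroid depolarization
  if (focus_low) arr[14:16, 9:11, 10:12] <- 0.3
  structure(list(dopu = arr, valid = array(TRUE, dim(arr)),
                 kernel = kernel_spec(), noise = no_noise()),
            class = "dopu_volume")
}

toy_seg <- function() segmentation_line(matrix(20L, 30, 20), "manual")

toy_enface <- function(hot = TRUE, level = 100, bump = 50) {
  img <- matrix(level, 30, 20) + matrix(rnorm(600, 0, 2), 30, 20)
  if (hot) img[14:16, 9:11] <- level + bump
  img
}

score_toy <- function(dopu, psslo_hot = TRUE, nir_hot = TRUE, sw_hot = TRUE,
                      seed = 1) {
  set.seed(seed)
  score_focus_modalities(toy_focus(), dopu, toy_enface(psslo_hot),
                         toy_enface(nir_hot), toy_enface(sw_hot),
                         toy_params())
}

test_that("footprint z-scores reflect the contrast against the background annulus", {
  set.seed(2)
  dv <- toy_dopu()
  flat <- score_focus_modalities(toy_focus(), dv, toy_enface(hot = FALSE),
                                 toy_enface(FALSE), toy_enface(FALSE),
                                 toy_params())
  expect_lt(abs(flat$psslo_z), 1.5)
  hot <- score_focus_modalities(toy_focus(), dv,
                                toy_enface(TRUE, bump = 10),   # +5 sigma
                                toy_enface(FALSE), toy_enface(FALSE),
                                toy_params())
  expect_gt(hot$psslo_z, 3.5)
  expect_lt(hot$psslo_z, 6.5)
  expect_equal(hot$min_dopu, 0.3)
  expect_error(score_focus_modalities(toy_focus()[0, ], dv, toy_enface(),
                                      toy_enface(), toy_enface(), toy_params()),
               "empty")
})

test_that("the concordance rule requires all four modalities", {
  seg <- toy_seg()
  dv <- toy_dopu()
  all_pass <- classify_focus(score_toy(dv), dv, seg)
  expect_identical(all_pass$label, "migration")
  sw_fail <- classify_focus(score_toy(dv, sw_hot = FALSE), dv, seg)
  expect_identical(sw_fail$label, "no_migration")
  dopu_fail <- classify_focus(score_toy(toy_dopu(focus_low = FALSE)),
                              toy_dopu(focus_low = FALSE), seg)
  expect_identical(dopu_fail$label, "no_migration")
})

test_that("a qualifying low-DOPU mass in the axial column forces exclusion", {
  seg <- toy_seg()
  dv <- toy_dopu()
  # mass: 8x8x4 = 256 voxels overlapping the focus footprint, above the RPE
  dv$dopu[10:17, 6:13, 3:6] <- 0.1
  obs <- classify_focus(score_toy(dv), dv, seg)
  expect_identical(obs$label, "excluded")
  expect_true(obs$excluded_mass)
  # the same mass shifted clear of the footprint does not exclude
  dv2 <- toy_dopu()
  dv2$dopu[20:27, 1:8, 3:6] <- 0.1
  obs2 <- classify_focus(score_toy(dv2), dv2, seg)
  expect_identical(obs2$label, "migration")
  # a sub-threshold mass (too few voxels) does not exclude
  dv3 <- toy_dopu()
  dv3$dopu[10:14, 6:10, 3:6] <- 0.1   # 100 voxels
  expect_identical(classify_focus(score_toy(dv3), dv3, seg)$label, "migration")
})

test_that("raising the AF threshold never converts no_migration into migration", {
  seg <- toy_seg()
  dv <- toy_dopu()
  labs <- vapply(c(2, 4, 8, 20), function(z) {
    classify_focus(score_toy(dv), dv, seg,
                   classification_thresholds(af_z = z))$label
  }, character(1))
  # once the focus drops out it must stay out at stricter thresholds
  dropped <- which(labs == "no_migration")
  if (length(dropped))
    expect_true(all(labs[min(dropped):length(labs)] == "no_migration"))
  expect_identical(labs[1], "migration")
})

test_that("eye-level tallies use migration precedence and ignore excluded foci", {
  mk <- function(lab) structure(list(label = lab), class = "focus_observation")
  both <- classify_eye(list(mk("migration"), mk("no_migration")))
  expect_true(both$has_migrating_hrf)
  expect_false(both$has_nonmigrating_hrf)
  none <- classify_eye(list())
  expect_false(none$has_migrating_hrf || none$has_nonmigrating_hrf)
  excl <- classify_eye(list(mk("excluded")))
  expect_false(excl$has_migrating_hrf || excl$has_nonmigrating_hrf)
  only_non <- classify_eye(list(mk("no_migration"), mk("excluded")))
  expect_true(only_non$has_nonmigrating_hrf)
})

test_that("Cohen's kappa matches hand values and the contingency oracle", {
  expect_equal(cohen_kappa(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(cohen_kappa(c("a", "a"), c("a", "a")), 1)  # p_e = 1 convention
  expect_error(cohen_kappa(1:3, 1:4), "length")
  set.seed(77)
  for (i in 1:5) {
    a <- sample(c("mig", "non", "none"), 100, TRUE)
    b <- ifelse(runif(100) < 0.7, a, sample(c("mig", "non", "none"), 100, TRUE))
    expect_equal(cohen_kappa(a, b), naive_kappa(a, b), tolerance = 1e-12)
  }
})

test_that("two automatic graders with jittered thresholds agree strongly on a clean cohort", {
  p <- test_params(nx = 40, nb = 20, nz = 56)
  eyes <- generate_cohort(c(remission = 4, geographic_atrophy = 3,
                            early_intermediate = 3), p, seed = 99)
  grade <- function(th) {
    vapply(eyes, function(e) {
      r <- analyze_eye(e, thresholds = th)
      if (r$record$has_migrating_hrf) "mig"
      else if (r$record$has_nonmigrating_hrf) "non" else "none"
    }, character(1))
  }
  a <- grade(classification_thresholds(af_z = 1.8, psslo_z = 1.8))
  b <- grade(classification_thresholds(af_z = 2.4, psslo_z = 2.4, dopu_low = 0.75))
  if (length(unique(c(a, b))) > 1) {
    expect_gt(cohen_kappa(a, b), 0.8)
  } else {
    expect_identical(a, b)
  }
})
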