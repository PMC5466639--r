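mk_eye <- function(group, mig, non = FALSE, hrf = NA_real_, ped = NA_real_,
                   id = "e") {
  structure(list(eye_id = id, group = group, has_migrating_hrf = mig,
                 has_nonmigrating_hrf = non, hrf_volume_mm3 = hrf,
                 ped_volume_mm3 = ped), class = "eye_record")
}

test_that("count summaries recompute percentages from raw records", {
  single <- cohort_table(list(mk_eye("serous_ped", TRUE)))
  sc <- summarize_counts(single)
  expect_equal(sc$pct_migrating[sc$group == "serous_ped"], 100.0)

  eyes <- c(lapply(1:3, function(i) mk_eye("remission", TRUE)),
            lapply(1:5, function(i) mk_eye("remission", FALSE, TRUE)),
            lapply(1:8, function(i) mk_eye("fibrosis", FALSE, FALSE)))
  tab <- summarize_counts(cohort_table(eyes))
  rem <- tab[tab$group == "remission", ]
  expect_equal(rem$n_eyes, 8)
  expect_equal(rem$pct_migrating, round_half_up(100 * 3 / 8, 1))
  ov <- tab[tab$group == "overall", ]
  expect_equal(ov$n_eyes, 16)
  expect_equal(ov$pct_migrating, round_half_up(100 * 3 / 16, 1))
})

test_that("volume summaries match a brute-force recomputation", {
  eyes <- list(mk_eye("remission", TRUE, hrf = 1), mk_eye("remission", TRUE, hrf = 3),
               mk_eye("fibrosis", FALSE, hrf = 0.5))
  tab <- summarize_volumes(cohort_table(eyes))
  rem <- tab[tab$group == "remission", ]
  expect_equal(rem$mean_mm3, 2)
  expect_equal(rem$sd_mm3, sqrt(2))
  expect_equal(c(rem$min_mm3, rem$max_mm3), c(1, 3))
  fib <- tab[tab$group == "fibrosis", ]
  expect_equal(fib$sd_mm3, 0)
  expect_true(fib$single_eye)

  set.seed(3)
  eyes <- lapply(1:40, function(i)
    mk_eye(sample(study_groups(), 1), TRUE, hrf = runif(1)))
  ct <- cohort_table(eyes)
  tab <- summarize_volumes(ct)
  for (g in tab$group) {
    v <- ct$hrf_volume_mm3[ct$group == g]
    expect_equal(tab$mean_mm3[tab$group == g], sum(v) / length(v),
                 tolerance = 1e-12)
    if (length(v) > 1)
      expect_equal(tab$sd_mm3[tab$group == g],
                   sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                   tolerance = 1e-12)
  }
})

test_that("chi-square against the rest matches closed forms and the expected-counts oracle", {
  eq <- c(lapply(1:10, function(i) mk_eye("remission", TRUE)),
          lapply(1:10, function(i) mk_eye("remission", FALSE)),
          lapply(1:5, function(i) mk_eye("fibrosis", TRUE)),
          lapply(1:5, function(i) mk_eye("fibrosis", FALSE)))
  r <- chi_square_group_vs_rest(cohort_table(eq), "remission")
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  perfect <- c(lapply(1:10, function(i) mk_eye("remission", TRUE)),
               lapply(1:10, function(i) mk_eye("fibrosis", FALSE)))
  r2 <- chi_square_group_vs_rest(cohort_table(perfect), "remission")
  expect_equal(r2$statistic, 20, tolerance = 1e-10)   # n for perfect association

  # serous PED 24/24 migrating vs 28 of 131 in the rest
  eyes <- c(lapply(1:24, function(i) mk_eye("serous_ped", TRUE)),
            lapply(1:28, function(i) mk_eye("fibrosis", TRUE)),
            lapply(1:103, function(i) mk_eye("fibrosis", FALSE)))
  r3 <- chi_square_group_vs_rest(cohort_table(eyes), "serous_ped")
  tab <- matrix(c(24, 0, 28, 103), 2, byrow = TRUE)
  expect_equal(r3$statistic, naive_chisq(tab), tolerance = 1e-10)
  expect_equal(r3$df, 1)

  degen <- lapply(1:4, function(i) mk_eye("remission", TRUE))
  expect_error(chi_square_group_vs_rest(cohort_table(degen), "remission"),
               "margin")
})

test_that("Mann-Whitney U matches symmetry, enumeration, and wilcox.test", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 3 * 3 / 2)

  r <- mann_whitney_u(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 6)   # C(4,2) = 6 equally likely assignments

  set.seed(21)
  x <- rnorm(5); y <- rnorm(6)
  ours <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  x <- rnorm(15); y <- rnorm(18) + 0.5
  ours <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis handles ties, identical groups, and matches kruskal.test", {
  expect_equal(kruskal_wallis(rep(5, 9), rep(1:3, each = 3)),
               list(H = 0, df = 2L, p_value = 1))
  set.seed(8)
  v <- round(rnorm(30), 1)   # induce some ties
  g <- rep(1:3, each = 10)
  ours <- kruskal_wallis(v, g)
  ref <- kruskal.test(v, factor(g))
  expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Pearson correlation reports r, R-squared and the t-test p-value", {
  x <- c(0.2, 0.5, 1.1, 2.3, 3.1)
  lin <- pearson_r2(x, 2 * x + 1)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)

  r <- pearson_r2(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r, 0.5, tolerance = 1e-12)
  expect_equal(r$r_squared, 0.25, tolerance = 1e-12)

  # brute-force formula oracle
  set.seed(4)
  a <- rnorm(20); b <- 0.4 * a + rnorm(20)
  got <- pearson_r2(a, b)
  rr <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tt <- rr * sqrt(18 / (1 - rr^2))
  expect_equal(got$r, rr, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(tt), 18), tolerance = 1e-12)

  expect_error(pearson_r2(rep(1, 5), 1:5), "constant")
})

test_that("serous-PED coupling yields a positive HRF-PED volume correlation", {
  # geometry-only phantoms: dome volume vs migratory focus load
  p <- optic_params(n_alines = 256, n_bscans = 128, n_depth = 256,
                    pitch_x = 23.4, pitch_b = 47)
  phs <- generate_cohort(c(serous_ped = 24), p, seed = 5, simulate = FALSE)
  ped <- vapply(phs, true_ped_volume_mm3, 1)
  hrf <- vapply(phs, function(ph) {
    sum(vapply(seq_along(ph$foci), function(i)
      if (ph$foci[[i]]$migration_truth) nrow(focus_voxels(ph, i)) else 0L, 1L)) *
      voxel_volume_um3(p) * 1e-9
  }, 1)
  r <- pearson_r2(ped, hrf)
  expect_gt(r$r, 0)
  expect_lt(r$p_value, 0.05)
})
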