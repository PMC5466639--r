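#' Assemble eye records into a cohort table
#'
#' @param eyes list of `eye_record`s.
#' @return data.frame with one row per eye (class `cohort_table`).
#' @export
cohort_table <- function(eyes) {
  stopifnot(length(eyes) > 0)
  df <- do.call(rbind, lapply(eyes, function(e) {
    data.frame(eye_id = e$eye_id, group = e$group,
               has_migrating_hrf = e$has_migrating_hrf,
               has_nonmigrating_hrf = e$has_nonmigrating_hrf,
               hrf_volume_mm3 = e$hrf_volume_mm3,
               ped_volume_mm3 = e$ped_volume_mm3,
               stringsAsFactors = FALSE)
  }))
  bad <- setdiff(unique(df$group), study_groups())
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  class(df) <- c("cohort_table", class(df))
  df
}

#' Per-group counts of eyes with / without migrating HRF
#'
#' The standard cohort count table: per group (and
#' overall), the number of eyes, the number and percentage with migrating
#' HRF, and the number and percentage with non-migrating HRF only.
#' Percentages are reported to one decimal, rounding half away from zero.
#'
#' @param cohort a [cohort_table()].
#' @return data.frame with one row per group plus an `overall` row.
#' @export
summarize_counts <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  pct <- function(n, tot) round_half_up(100 * n / tot, 1)
  one <- function(df, label) {
    tot <- nrow(df)
    n_mig <- sum(df$has_migrating_hrf)
    n_non <- sum(df$has_nonmigrating_hrf)
    data.frame(group = label, n_eyes = tot,
               n_migrating = n_mig, pct_migrating = pct(n_mig, tot),
               n_nonmigrating = n_non, pct_nonmigrating = pct(n_non, tot),
               stringsAsFactors = FALSE)
  }
  groups <- intersect(study_groups(), unique(cohort$group))
  rows <- lapply(groups, function(g) one(cohort[cohort$group == g, ], g))
  rbind(do.call(rbind, rows), one(cohort, "overall"))
}

#' Per-group HRF volume summary
#'
#' Mean, sample standard deviation (n - 1 denominator) and range of the
#' per-eye HRF volumes in each group. A single-eye group reports SD 0 with
#' a flag; empty groups are omitted with a warning.
#'
#' @param cohort a [cohort_table()].
#' @return data.frame, one row per group present.
#' @export
summarize_volumes <- function(cohort) {
  groups <- intersect(study_groups(), unique(cohort$group))
  missing <- setdiff(unique(cohort$group), groups)
  rows <- lapply(groups, function(g) {
    v <- cohort$hrf_volume_mm3[cohort$group == g]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning("group '", g, "' has no volumes; omitted")
      return(NULL)
    }
    data.frame(group = g, n_eyes = length(v), mean_mm3 = mean(v),
               sd_mm3 = if (length(v) > 1) stats::sd(v) else 0,
               min_mm3 = min(v), max_mm3 = max(v),
               single_eye = length(v) == 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Chi-square test of one group's migration frequency against the rest
#'
#' Pearson chi-square without continuity correction (flag available) on
#' the 2 x 2 table of (group vs all other groups) x (migrating HRF vs
#' not), df = 1.
#'
#' @param cohort a [cohort_table()].
#' @param group the group to contrast with the rest; or a vector of groups
#'   to combine.
#' @param outcome column to tally (`"has_migrating_hrf"` or
#'   `"has_nonmigrating_hrf"`).
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `df`, `p_value`, `table`.
#' @export
chi_square_group_vs_rest <- function(cohort, group,
                                     outcome = "has_migrating_hrf",
                                     correct = FALSE) {
  in_group <- cohort$group %in% group
  y <- cohort[[outcome]]
  tab <- table(factor(in_group, levels = c(TRUE, FALSE)),
               factor(y, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: a margin is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}

# Mann-Whitney U (number of (x, y) pairs with x > y, +1/2 per tie) via
# midranks.
mw_u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Reports U for the first sample. For pooled sizes up to `exact_max` the
#' p-value is exact by full enumeration of the group assignments (midranks,
#' so ties are handled); above that, the normal approximation with tie
#' correction (no continuity correction) is used.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (one-sided
#'   alternatives refer to the first sample's tendency to smaller/larger
#'   values).
#' @param exact_max largest pooled size enumerated exactly.
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           exact_max = 12L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_obs <- mw_u_statistic(x, y)
  if (n <= exact_max) {
    r <- rank(c(x, y))
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p_le <- mean(us <= u_obs + 1e-9)
    p_ge <- mean(us >= u_obs - 1e-9)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- switch(alternative,
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE),
                two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(U = u_obs, p_value = p, method = method)
}

#' Kruskal-Wallis rank test across groups
#'
#' Wrapper around [stats::kruskal.test()] (midranks, tie correction). The
#' degenerate all-identical case, where the tie correction removes all
#' variance, is reported as H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups grouping factor of the same length.
#' @return list with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pearson correlation with R-squared
#'
#' Pearson r between two volume vectors, its square, and the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(x))
}
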