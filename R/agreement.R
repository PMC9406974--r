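# Between-method agreement statistics: ICC(2,1) with F-based confidence
# intervals, interpretation bands, Bland-Altman limits of agreement,
# exact/approximate Wilcoxon signed-rank, and triage concordance.

#' Two-way random-effects, absolute-agreement, single-measures ICC
#'
#' ICC(2,1) from the two-way ANOVA decomposition of an n-subjects by
#' 2-raters table, with the F-distribution confidence interval of McGraw
#' and Wong.
#'
#' @param x,y paired measurements (raters A and B), n >= 5.
#' @param conf_level confidence level (default 0.95).
#' @return list: `icc`, `ci` (length 2), `msr`, `msc`, `mse`, `n`, `k`.
#' @export
icc_two_way <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop_dimension("x and y lengths differ")
  n <- length(x)
  if (n < 5L) stop_sample_size("ICC needs at least 5 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_parameter("ICC inputs must be finite")
  k <- 2L
  dat <- cbind(x, y)
  grand <- mean(dat)
  if (sum((dat - grand)^2) == 0)
    stop_degenerate("zero total variance; ICC undefined")
  rowm <- rowMeans(dat)
  colm <- colMeans(dat)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  ci <- c(NA_real_, NA_real_)
  if (mse > 0 && icc < 1) {
    alpha <- 1 - conf_level
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  } else if (icc >= 1) {
    ci <- c(1, 1)
  }
  list(icc = icc, ci = ci, msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Interpret an ICC value
#'
#' Bands: below 0.50 poor; 0.50-0.75 moderate; above 0.75 up to 0.90
#' good; above 0.90 excellent.
#'
#' @param value ICC in \[-1, 1\].
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
interpret_icc <- function(value) {
  assert_scalar_num(value, "value")
  if (value < -1 || value > 1)
    stop_parameter(sprintf("ICC must be in [-1, 1], got %g", value))
  if (value < 0.50) "poor"
  else if (value <= 0.75) "moderate"
  else if (value <= 0.90) "good"
  else "excellent"
}

#' Bland-Altman analysis with limits-of-agreement confidence intervals
#'
#' Differences are `d = x - y` (reference minus variable). Limits of
#' agreement are `mean(d) +/- 1.96 sd(d)`; each limit's CI is
#' `limit +/- t(0.975, n-1) * sd(d) * sqrt(3/n)`.
#'
#' @param x reference measurements.
#' @param y comparison measurements.
#' @param conf_level confidence level for the LoA CIs (default 0.95).
#' @return list: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `loa_low_ci`, `loa_high_ci`, `n`, and per-case `means`/`diffs` for
#'   scatter export.
#' @export
bland_altman <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop_dimension("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stop_sample_size("Bland-Altman needs at least 3 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  loa_low <- md - 1.96 * sdd
  loa_high <- md + 1.96 * sdd
  half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * sdd * sqrt(3 / n)
  list(mean_diff = md, sd_diff = sdd,
       loa_low = loa_low, loa_high = loa_high,
       loa_low_ci = c(loa_low - half, loa_low + half),
       loa_high_ci = c(loa_high - half, loa_high + half),
       n = n, means = (x + y) / 2, diffs = d)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on `d = x - y`. Zero differences are dropped. The null
#' distribution is exact (sign-enumeration over midranks, computed by
#' dynamic programming) for up to `exact_cutoff` non-zero differences,
#' otherwise a normal approximation with tie and continuity corrections.
#'
#' @param x,y paired measurements.
#' @param exact_cutoff maximum n for the exact null (default 25).
#' @return list: `p`, `statistic` (W+, sum of positive ranks), `n`
#'   (non-zero differences), `exact`, `degenerate`.
#' @export
wilcoxon_paired <- function(x, y, exact_cutoff = 25L) {
  if (length(x) != length(y)) stop_dimension("x and y lengths differs")
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, statistic = 0, n = 0L, exact = TRUE, degenerate = TRUE))
  if (n < 5L)
    stop_sample_size(sprintf("need >= 5 non-zero differences, got %d", n))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_cutoff) {
    p <- wilcoxon_exact_p(r, w)
    list(p = p, statistic = w, n = n, exact = TRUE, degenerate = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(p = p, statistic = w, n = n, exact = FALSE, degenerate = FALSE)
  }
}

# Exact two-sided p for W+ = w given midranks r: distribution of the sum
# of a uniformly random subset of r, via DP over 2*r (integers).
wilcoxon_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)   # counts[s+1] = #subsets with sum s
  counts[1L] <- 1
  for (v in r2) {
    shifted <- c(numeric(v), counts[seq_len(total + 1L - v)])
    counts <- counts + shifted
  }
  nsub <- 2^length(r2)
  w2 <- round(2 * w)
  p_le <- sum(counts[seq_len(w2 + 1L)]) / nsub
  p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / nsub
  min(1, 2 * min(p_le, p_ge))
}

#' Pair two sets of per-case volumetric results
#'
#' @param case_id vector of unique case identifiers.
#' @param volumes_a,volumes_b lists of [mismatch_profile()] results, one
#'   per case, in `case_id` order.
#' @return a `paired_cohort` with per-case triage decisions attached.
#' @export
paired_cohort <- function(case_id, volumes_a, volumes_b) {
  n <- length(case_id)
  if (length(volumes_a) != n || length(volumes_b) != n)
    stop_dimension("case_id, volumes_a, volumes_b lengths differ")
  if (anyDuplicated(case_id)) stop_parameter("case_id must be unique")
  structure(list(case_id = case_id, volumes_a = volumes_a,
                 volumes_b = volumes_b,
                 decisions_a = lapply(volumes_a, triage_defuse3),
                 decisions_b = lapply(volumes_b, triage_defuse3)),
            class = "paired_cohort")
}

#' Triage concordance table with 70-mL subgroups
#'
#' Cases are split by the package-A core volume at 70 mL (boundary 70
#' assigned to the ">= 70" side). Per subgroup: eligible / not-eligible
#' counts per package, concordant-case count and rate. Overall agreement
#' is ICC(2,1) on decisions coded 0/1; if that ICC is degenerate (zero
#' variance) it is reported as 1 when the decision vectors are identical
#' and NA otherwise.
#'
#' @param cohort a [paired_cohort()].
#' @return list: `table` (data.frame, one row per subgroup plus overall),
#'   `icc`, `concordance_rate`, `n`.
#' @export
triage_concordance <- function(cohort) {
  stopifnot(inherits(cohort, "paired_cohort"))
  n <- length(cohort$case_id)
  if (n == 0L) stop_parameter("empty cohort")
  da <- vapply(cohort$decisions_a, `[[`, logical(1), "eligible")
  db <- vapply(cohort$decisions_b, `[[`, logical(1), "eligible")
  icv_a <- vapply(cohort$volumes_a, `[[`, numeric(1), "icv")
  grp <- ifelse(icv_a >= 70, "ICV >= 70 mL", "ICV < 70 mL")

  row_for <- function(sel, label) {
    data.frame(subgroup = label, n = sum(sel),
               eligible_a = sum(da[sel]), not_eligible_a = sum(!da[sel]),
               eligible_b = sum(db[sel]), not_eligible_b = sum(!db[sel]),
               concordant = sum(da[sel] == db[sel]),
               rate = if (any(sel)) sum(da[sel] == db[sel]) / sum(sel) else NA_real_)
  }
  tab <- rbind(row_for(grp == "ICV >= 70 mL", "ICV >= 70 mL"),
               row_for(grp == "ICV < 70 mL", "ICV < 70 mL"),
               row_for(rep(TRUE, n), "overall"))
  agree_fallback <- function(e) if (identical(da, db)) 1 else NA_real_
  icc <- tryCatch(icc_two_way(as.numeric(da), as.numeric(db))$icc,
                  perf_degenerate_error = agree_fallback,
                  perf_sample_size_error = agree_fallback)
  list(table = tab, icc = icc,
       concordance_rate = sum(da == db) / n, n = n)
}

#' Full agreement report for a paired cohort
#'
#' Runs ICC, Bland-Altman and the Wilcoxon paired test for core and
#' penumbra volumes (direction: A minus B) and triage concordance.
#'
#' @param cohort a [paired_cohort()].
#' @return nested list with elements `icv`, `pv` (each: `icc`, `icc_ci`,
#'   `icc_band`, `bland_altman`, `wilcoxon_p`) and `triage`.
#' @export
agreement_report <- function(cohort) {
  stopifnot(inherits(cohort, "paired_cohort"))
  one <- function(field) {
    a <- vapply(cohort$volumes_a, `[[`, numeric(1), field)
    b <- vapply(cohort$volumes_b, `[[`, numeric(1), field)
    icc <- icc_two_way(a, b)
    wt <- wilcoxon_paired(a, b)
    list(icc = icc$icc, icc_ci = icc$ci, icc_band = interpret_icc(icc$icc),
         bland_altman = bland_altman(a, b), wilcoxon_p = wt$p,
         wilcoxon_degenerate = wt$degenerate)
  }
  list(icv = one("icv"), pv = one("pv"), triage = triage_concordance(cohort))
}
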