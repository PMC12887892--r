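# Two-group comparison workflow for session metrics: assumption checks,
# Student t / Mann-Whitney U tests, Bonferroni adjustment, Cohen's d and
# r = |Z|/sqrt(N) effect sizes, and parametric or bootstrap confidence
# intervals.

as_group <- function(x, name) {
  x <- as.numeric(x)
  if (anyNA(x)) stopf("group %s contains missing values", name)
  x
}

#' Check the parametric assumptions for a two-group comparison
#'
#' Shapiro-Wilk normality per group and Levene's test (centered on the
#' mean) for homogeneity of variances, both gated at 0.05. A
#' constant-valued group leaves normality undefined and fails the gate.
#'
#' @param group_a,group_b Numeric samples, each of size >= 3.
#' @return List: `shapiro_p` (length 2), `levene_p`, `parametric_ok`,
#'   `flag`.
#' @export
check_assumptions <- function(group_a, group_b) {
  a <- as_group(group_a, "a"); b <- as_group(group_b, "b")
  if (length(a) < 3L || length(b) < 3L) {
    stopf("assumption checks need at least 3 observations per group")
  }
  sw <- vapply(list(a = a, b = b), function(g) {
    tryCatch(stats::shapiro.test(g)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  lev <- tryCatch({
    d <- data.frame(y = c(a, b),
                    g = factor(rep(c("a", "b"), c(length(a), length(b)))))
    as.numeric(car::leveneTest(y ~ g, data = d, center = mean)[1, "Pr(>F)"])
  }, error = function(e) NA_real_)
  flag <- if (anyNA(sw)) "normality undefined (constant group)" else NA_character_
  ok <- !anyNA(sw) && !is.na(lev) && all(sw > 0.05) && lev > 0.05
  list(shapiro_p = sw, levene_p = lev, parametric_ok = ok, flag = flag)
}

#' Independent-samples Student t test (pooled variance)
#'
#' @param group_a,group_b Numeric samples of size >= 2.
#' @param conf_level Confidence level for the difference interval.
#' @return List: `t`, `df`, `p_value`, `mean_diff` (a - b), `ci_diff`.
#' @export
t_test_independent <- function(group_a, group_b, conf_level = 0.95) {
  a <- as_group(group_a, "a"); b <- as_group(group_b, "b")
  if (length(a) < 2L || length(b) < 2L) stopf("t test needs at least 2 observations per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_diff = 0, ci_diff = c(0, 0)))
    }
    stopf("degenerate data: zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE, conf.level = conf_level)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = mean(a) - mean(b),
       ci_diff = as.numeric(ht$conf.int))
}

# exact null distribution of U (counts over 0..na*nb) for untied samples:
# dp over subset size and rank sum
u_exact_counts <- function(na, nb) {
  N <- na + nb
  maxw <- sum((N - na + 1):N)
  dp <- matrix(0, nrow = na + 1L, ncol = maxw + 1L)  # [k+1, w+1]
  dp[1, 1] <- 1
  for (r in seq_len(N)) {
    for (k in min(na, r):1) {
      w <- seq(r, maxw)
      dp[k + 1L, w + 1L] <- dp[k + 1L, w + 1L] + dp[k, w - r + 1L]
    }
  }
  wmin <- na * (na + 1) / 2
  dp[na + 1L, (wmin:maxw) + 1L]  # counts of U = W - wmin = 0..na*nb
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The standardized Z
#' uses the normal approximation with tie-corrected variance and a
#' continuity correction; its sign follows the group order as passed
#' (positive when the first group ranks higher). The two-tailed p-value is
#' exact (full enumeration of the U null distribution) when the pooled
#' sample has at most `exact_max` observations and no ties, otherwise the
#' normal approximation is used.
#'
#' @param group_a,group_b Numeric samples (each non-empty).
#' @param exact_max Largest pooled size for the exact path.
#' @return List: `U` (first group), `Z`, `p_value`, `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 12L) {
  a <- as_group(group_a, "a"); b <- as_group(group_b, "b")
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks
  Ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    # all observations identical: no evidence either way
    return(list(U = Ua, Z = 0, p_value = 1, method = "degenerate"))
  }
  sigma <- sqrt(sigma2)
  cc <- if (Ua == mu) 0 else 0.5 * sign(Ua - mu)
  Z <- (Ua - mu - cc) / sigma

  has_ties <- any(ties > 1)
  if (N <= exact_max && !has_ties) {
    cnt <- u_exact_counts(na, nb)
    tot <- sum(cnt)
    u <- round(Ua)
    p_lo <- sum(cnt[seq_len(u + 1L)]) / tot          # P(U <= u)
    p_hi <- sum(cnt[(u + 1L):length(cnt)]) / tot     # P(U >= u)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    method <- "normal_approximation"
  }
  list(U = Ua, Z = Z, p_value = p, method = method)
}

effect_label_d <- function(d) {
  ad <- abs(d)
  if (ad >= 1.20) "very large" else if (ad >= 0.80) "large"
  else if (ad >= 0.50) "medium" else if (ad >= 0.20) "small" else "negligible"
}

effect_label_r <- function(r) {
  ar <- abs(r)
  if (ar >= 0.50) "large" else if (ar >= 0.30) "medium"
  else if (ar >= 0.10) "small" else "negligible"
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_a - mean_b) / s_pooled`; the sign is preserved and the
#' magnitude labeled small/medium/large/very large at 0.20/0.50/0.80/1.20.
#'
#' @param group_a,group_b Numeric samples of size >= 2.
#' @return List: `d`, `label`.
#' @export
cohens_d <- function(group_a, group_b) {
  a <- as_group(group_a, "a"); b <- as_group(group_b, "b")
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("Cohen's d needs at least 2 observations per group")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) stopf("Cohen's d is undefined for zero pooled standard deviation")
  d <- (mean(a) - mean(b)) / sp
  list(d = d, label = effect_label_d(d))
}

#' Rank-biserial style effect size r = |Z| / sqrt(N)
#'
#' @param z Standardized Mann-Whitney statistic.
#' @param n_total Pooled sample size.
#' @return List: `r`, `label`.
#' @export
effect_size_r <- function(z, n_total) {
  stopifnot(n_total >= 1)
  r <- abs(z) / sqrt(n_total)
  list(r = r, label = effect_label_r(r))
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of primary comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 3L) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Parametric confidence interval for a mean
#'
#' `mean +/- t_{n-1, (1+level)/2} * SD / sqrt(n)`.
#'
#' @param sample Numeric sample of size >= 2.
#' @param level Confidence level.
#' @return `c(lo, hi)`.
#' @export
ci_mean <- function(sample, level = 0.95) {
  x <- as_group(sample, "sample")
  n <- length(x)
  if (n < 2L) stopf("a mean confidence interval needs at least 2 observations")
  half <- stats::qt((1 + level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(mean(x) - half, mean(x) + half)
}

#' Bootstrap percentile confidence interval for a median
#'
#' Seeded nonparametric bootstrap (percentile method).
#'
#' @param sample Numeric sample of size >= 5.
#' @param level Confidence level.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the resampling.
#' @return `c(lo, hi)`.
#' @export
ci_median <- function(sample, level = 0.95, n_boot = 10000L, seed = 1L) {
  x <- as_group(sample, "sample")
  n <- length(x)
  if (n < 5L) stopf("a median confidence interval needs at least 5 observations")
  if (stats::sd(x) == 0) return(c(x[1], x[1]))
  meds <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stats::median(x[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  unname(stats::quantile(meds, c((1 - level) / 2, (1 + level) / 2), type = 7))
}

VARIABLE_COLUMNS <- c(VMRS = "mean_vmrs_s", DS = "mean_ds_s",
                      RC = "rc_percent", CMS = "cms_s")
PRIMARY_VARIABLES <- c("VMRS", "DS", "RC")

#' Compare two groups of session metrics
#'
#' For each requested variable the parametric assumptions are checked and
#' the test chosen accordingly (Student t when Shapiro-Wilk and Levene both
#' pass, Mann-Whitney U otherwise). With `force_test_mapping = TRUE` the
#' fixed mapping t for VMRS/DS and Mann-Whitney for RC/CMS is applied
#' regardless of the checks. The significance level of the three primary
#' variables (VMRS, DS, RC) is Bonferroni-adjusted to `alpha / 3`; CMS is
#' exploratory and compared at the unadjusted level. Cohen's d (pooled SD)
#' accompanies t tests, `r = |Z|/sqrt(N)` accompanies Mann-Whitney tests;
#' group summaries carry t-based mean CIs or bootstrap median CIs.
#'
#' @param metrics_a,metrics_b Session-metric data frames (one row per
#'   athlete, as from [summarize_session()]), or plain numeric vectors when
#'   a single variable is requested.
#' @param variables Subset of `c("VMRS", "DS", "RC", "CMS")`.
#' @param alpha Family-wise significance level.
#' @param force_test_mapping Apply the fixed t / Mann-Whitney mapping.
#' @param n_boot Bootstrap replicates for median CIs.
#' @param seed Seed for the bootstrap.
#' @return Data frame of class `group_comparison`, one row per variable.
#' @export
compare_groups <- function(metrics_a, metrics_b,
                           variables = c("VMRS", "DS", "RC", "CMS"),
                           alpha = 0.05, force_test_mapping = FALSE,
                           n_boot = 10000L, seed = 1L) {
  if (!length(variables)) {
    return(structure(data.frame(), class = c("group_comparison", "data.frame")))
  }
  variables <- match.arg(variables, several.ok = TRUE)
  get_var <- function(m, v) {
    if (is.data.frame(m)) as.numeric(m[[VARIABLE_COLUMNS[[v]]]]) else as.numeric(m)
  }
  m_primary <- length(PRIMARY_VARIABLES)

  rows <- lapply(seq_along(variables), function(vi) {
    v <- variables[vi]
    a <- get_var(metrics_a, v); b <- get_var(metrics_b, v)
    if (length(a) < 3L || length(b) < 3L) {
      stopf("group comparison for %s needs at least 3 athletes per group", v)
    }
    assum <- check_assumptions(a, b)
    use_t <- if (force_test_mapping) v %in% c("VMRS", "DS") else assum$parametric_ok
    alpha_adj <- if (v %in% PRIMARY_VARIABLES) bonferroni_alpha(alpha, m_primary) else alpha

    if (use_t) {
      ht <- t_test_independent(a, b)
      es <- cohens_d(a, b)
      cia <- ci_mean(a); cib <- ci_mean(b)
      data.frame(
        variable = v, test = "t_independent", statistic = ht$t,
        z_value = NA_real_, p_value = ht$p_value, alpha_adjusted = alpha_adj,
        significant = ht$p_value < alpha_adj,
        center_a = mean(a), center_b = mean(b),
        dispersion_a = stats::sd(a), dispersion_b = stats::sd(b),
        dispersion_type = "sd", mean_diff = ht$mean_diff,
        ci_lo_a = cia[1], ci_hi_a = cia[2], ci_lo_b = cib[1], ci_hi_b = cib[2],
        effect_size_value = es$d, effect_size_type = "cohens_d",
        effect_size_label = es$label,
        shapiro_p_a = assum$shapiro_p[1], shapiro_p_b = assum$shapiro_p[2],
        levene_p = assum$levene_p, stringsAsFactors = FALSE
      )
    } else {
      mw <- mann_whitney(a, b)
      es <- effect_size_r(mw$Z, length(a) + length(b))
      cia <- ci_median(a, n_boot = n_boot, seed = seed + vi)
      cib <- ci_median(b, n_boot = n_boot, seed = seed + vi + 1000L)
      data.frame(
        variable = v, test = "mann_whitney", statistic = mw$U,
        z_value = mw$Z, p_value = mw$p_value, alpha_adjusted = alpha_adj,
        significant = mw$p_value < alpha_adj,
        center_a = stats::median(a), center_b = stats::median(b),
        dispersion_a = stats::IQR(a), dispersion_b = stats::IQR(b),
        dispersion_type = "iqr", mean_diff = mean(a) - mean(b),
        ci_lo_a = cia[1], ci_hi_a = cia[2], ci_lo_b = cib[1], ci_hi_b = cib[2],
        effect_size_value = es$r, effect_size_type = "r",
        effect_size_label = es$label,
        shapiro_p_a = assum$shapiro_p[1], shapiro_p_b = assum$shapiro_p[2],
        levene_p = assum$levene_p, stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Write group comparisons to JSON
#' @param comparisons A [compare_groups()] result.
#' @param path Output file.
#' @export
write_comparisons_json <- function(comparisons, path) {
  jsonlite::write_json(as.data.frame(comparisons), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
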