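# Group-comparison statistics: assumption gates, tests, effect sizes,
# confidence intervals.

test_that("assumption checks gate on Shapiro-Wilk and Levene", {
  expect_error(check_assumptions(c(1, 2), c(1, 2, 3)), "at least 3")

  set.seed(10)
  ok <- replicate(50, {
    check_assumptions(rnorm(30), rnorm(30))$parametric_ok
  })
  expect_gt(mean(ok), 0.75)  # false-flag rate should stay near nominal

  set.seed(11)
  skewed <- replicate(50, {
    check_assumptions(rexp(30), rnorm(30))$parametric_ok
  })
  expect_gte(mean(!skewed), 0.9)

  const <- check_assumptions(rep(1, 10), rnorm(10))
  expect_false(const$parametric_ok)
  expect_match(const$flag, "constant")
})

test_that("the pooled t test reproduces hand-computed values", {
  same <- c(1, 2, 3, 4)
  r0 <- t_test_independent(same, same)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)

  # {1,2,3} vs {4,5,6}: pooled SD = 1, SE = sqrt(2/3), t = -3 * sqrt(3/2)
  r <- t_test_independent(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 * sqrt(1.5), tolerance = 1e-9)
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$p_value, 2 * stats::pt(-3 * sqrt(1.5), 4), tolerance = 1e-9)
  expect_equal(round(r$p_value, 3), 0.021)
  expect_equal(r$mean_diff, -3)

  expect_error(t_test_independent(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_identical(r$method, "exact")
  expect_equal(r$p_value, 0.1)  # 2 * 1/20 over all C(6,3) rank splits

  same <- c(2, 4, 6, 8)
  ri <- mann_whitney(same, same)
  expect_equal(ri$Z, 0)
  expect_equal(ri$p_value, 1)

  set.seed(12)
  a <- rnorm(5); b <- rnorm(6)
  r1 <- mann_whitney(a, b); r2 <- mann_whitney(b, a)
  expect_equal(r1$U, 5 * 6 - r2$U)
  expect_equal(abs(r1$Z), abs(r2$Z))
  expect_equal(r1$p_value, r2$p_value)
})

test_that("the exact Mann-Whitney path agrees with wilcox.test", {
  set.seed(13)
  for (i in 1:40) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- sample(1000, na + nb)  # distinct values: no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    ours <- mann_whitney(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_identical(ours$method, "exact")
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("effect sizes follow their defining formulas and labels", {
  g <- c(1, 2, 3)
  expect_equal(cohens_d(g, g)$d, 0)
  # one pooled SD apart
  expect_equal(abs(cohens_d(c(1, 2, 3), c(2, 3, 4))$d), 1)
  # group means 0.96 vs 0.77 at common SD 0.12 -> d near 1.583
  set.seed(14)
  mk <- function(m, s, n) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / stats::sd(x)
  }
  a <- mk(0.96, 0.12, 14); b <- mk(0.77, 0.12, 15)
  expect_equal(cohens_d(a, b)$d, 0.19 / 0.12, tolerance = 1e-9)
  expect_identical(cohens_d(a, b)$label, "very large")
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), "zero pooled")

  expect_equal(round(effect_size_r(3.13, 29)$r, 2), 0.58)
  expect_equal(round(effect_size_r(-0.544, 29)$r, 2), 0.10)
  expect_equal(effect_size_r(0, 10)$r, 0)
  expect_identical(effect_size_r(3.13, 29)$label, "large")

  expect_equal(round(bonferroni_alpha(0.05, 3), 4), 0.0167)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 5), 0.002)
})

test_that("mean CIs are t-based and nested across levels", {
  expect_equal(ci_mean(rep(2.5, 6)), c(2.5, 2.5))
  set.seed(15)
  x <- rnorm(15)
  x <- 0.77 + 0.12 * (x - mean(x)) / stats::sd(x)
  ci <- ci_mean(x)
  half <- stats::qt(0.975, 14) * 0.12 / sqrt(15)
  expect_equal(ci, c(0.77 - half, 0.77 + half), tolerance = 1e-9)
  expect_equal(half, 0.0665, tolerance = 1e-3)
  ci99 <- ci_mean(x, level = 0.99)
  expect_lt(ci99[1], ci[1]); expect_gt(ci99[2], ci[2])
  expect_error(ci_mean(1), "at least 2")
})

test_that("median CIs are reproducible seeded bootstraps with fair coverage", {
  expect_equal(ci_median(rep(3, 8)), c(3, 3))
  set.seed(16)
  x <- rnorm(40)
  expect_identical(ci_median(x, seed = 9), ci_median(x, seed = 9))
  expect_error(ci_median(c(1, 2, 3, 4)), "at least 5")

  cover <- sapply(1:120, function(i) {
    set.seed(2000 + i)
    s <- rnorm(60)
    ci <- ci_median(s, n_boot = 400L, seed = i)
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gt(mean(cover), 0.85)
  expect_lte(mean(cover), 1)
})

test_that("compare_groups gates tests, adjusts alpha and attaches effects", {
  set.seed(17)
  mk_metrics <- function(n, vm, ds, rc_p) {
    data.frame(athlete_id = paste0("a", seq_len(n)), n_trials = 16L,
               mean_vmrs_s = rnorm(n, vm, 0.12),
               mean_ds_s = rnorm(n, ds, 0.1),
               rc_percent = 100 * rbinom(n, 16, rc_p) / 16,
               cms_s = NA)
  }
  a <- mk_metrics(15, 0.77, 0.76, 0.97)
  b <- mk_metrics(14, 0.96, 0.64, 0.9375)
  a$cms_s <- a$mean_vmrs_s + a$mean_ds_s
  b$cms_s <- b$mean_vmrs_s + b$mean_ds_s

  cmp <- compare_groups(a, b, force_test_mapping = TRUE, n_boot = 300L)
  expect_equal(cmp$variable, c("VMRS", "DS", "RC", "CMS"))
  expect_equal(cmp$test, c("t_independent", "t_independent",
                           "mann_whitney", "mann_whitney"))
  expect_equal(cmp$alpha_adjusted, c(0.05 / 3, 0.05 / 3, 0.05 / 3, 0.05))
  expect_equal(cmp$effect_size_type, c("cohens_d", "cohens_d", "r", "r"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))

  expect_equal(nrow(compare_groups(a, b, variables = character(0))), 0L)
  expect_error(compare_groups(a[1:2, ], b), "at least 3")
})

test_that("r is invariant under positive rescaling of the data", {
  set.seed(18)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  z1 <- mann_whitney(a, b)$Z
  z2 <- mann_whitney(a * 3.7, b * 3.7)$Z
  expect_equal(z1, z2)
  expect_equal(effect_size_r(z1, 27)$r, effect_size_r(z2, 27)$r)
})

test_that("t and Mann-Whitney p-values agree asymptotically", {
  set.seed(19)
  a <- rnorm(200, 0.1); b <- rnorm(200)
  pt <- t_test_independent(a, b)$p_value
  pm <- mann_whitney(a, b)$p_value
  expect_lt(abs(pt - pm), 0.02)
})

test_that("comparisons serialize to JSON", {
  set.seed(20)
  a <- data.frame(mean_vmrs_s = rnorm(10, 0.8, 0.1))
  b <- data.frame(mean_vmrs_s = rnorm(10, 0.9, 0.1))
  cmp <- compare_groups(a, b, variables = "VMRS", n_boot = 100L)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_comparisons_json(cmp, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$variable, "VMRS")
  expect_equal(back$p_value, cmp$p_value, tolerance = 1e-12)
})
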