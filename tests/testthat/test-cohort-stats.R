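test_that("cardiovascular risk score counts the five component flags", {
  all_false <- list(hypertension = FALSE, diabetes = FALSE, dyslipidemia = FALSE,
                    smoking = FALSE, obesity = FALSE)
  expect_equal(compute_crs(all_false), 0L)
  all_true <- lapply(all_false, function(x) TRUE)
  expect_equal(compute_crs(all_true), 5L)
  two <- all_false; two$hypertension <- TRUE; two$smoking <- TRUE
  expect_equal(compute_crs(two), 2L)
  expect_error(compute_crs(all_false[-2]), "missing risk flags: diabetes")
})

test_that("group assignment follows the boundary conventions", {
  coh <- data.frame(subject_id = sprintf("S%d", 1:6),
                    age = c(54, 61.9, 62, 68.9, 69, 78),
                    sex = c("F", "M", "F", "M", "F", "M"),
                    apoe = c("e3/e3", "e3/e4", "e2/e3", "e4/e4", "e3/e3", "e3/e4"),
                    crs = c(0, 1, 2, 0, 1, 2),
                    bmi = c(25, 25.01, 24, 31, 26, 20))
  grp <- assign_groups(coh)
  expect_equal(grp$age_group, c("54-62", "54-62", "62-69", "62-69", "69-78", "69-78"))
  expect_equal(grp$apoe_carrier, c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  # BMI = 25 exactly is not overweight (strict inequality)
  expect_equal(grp$overweight, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_false(any(grp$excluded))

  coh_bad <- coh; coh_bad$age[1] <- 45
  expect_warning(grp2 <- assign_groups(coh_bad), "outside")
  expect_true(grp2$excluded[1])
})

test_that("age regression matches the closed-form OLS oracle", {
  # exact line
  x <- c(54, 60, 66, 72)
  fit <- fit_age_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$slope_se, 0, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    ages <- stats::runif(n, 54, 78)
    y <- stats::rnorm(n, 10 + 0.5 * ages, 4)
    fit <- fit_age_regression(ages, y)
    orc <- ols_oracle(ages, y)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$slope_se, orc$slope_se, tolerance = 1e-10)
    expect_equal(fit$p_value, orc$p_value, tolerance = 1e-10)
  }
  expect_error(fit_age_regression(c(60, 60, 60), c(1, 2, 3)), "zero age variance")
  expect_error(fit_age_regression(c(60, 61), c(1, 2)), "3 complete")
})

test_that("Mann-Whitney matches the enumeration oracle on small untied samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p_value, 0.1)  # 2/20 arrangements in each tail
  expect_true(mw$exact)

  set.seed(17)
  for (na in 2:7) for (nb in c(2, 4, 7)) {
    a <- stats::rnorm(na)
    b <- stats::rnorm(nb, 0.5)
    mw <- mann_whitney(a, b)
    orc <- mw_enumeration_oracle(a, b)
    expect_equal(mw$u, orc$u)
    expect_equal(mw$p_value, orc$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney symmetry, tie handling and the U identity", {
  mw_same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw_same$u, 9 / 2)
  expect_equal(mw_same$p_value, 1)

  set.seed(23)
  for (i in 1:10) {
    a <- sample(1:10, sample(3:8, 1), replace = TRUE)
    b <- sample(1:10, sample(3:8, 1), replace = TRUE)
    ua <- mann_whitney(a, b)$u
    ub <- mann_whitney(b, a)$u
    expect_equal(ua + ub, length(a) * length(b))
  }
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.0001), 0.0112)
  expect_equal(bonferroni(0.02), 1)
  expect_equal(bonferroni(0), 0)
  expect_error(bonferroni(0.1, factor = 0), "factor")
  expect_error(bonferroni(1.3), "p_raw")
})

test_that("the comparison plan enumerates 16 pairs and 112 tests", {
  plan <- comparison_plan()
  expect_equal(sum(plan$parameter == "age"), 3L)
  expect_equal(sum(plan$parameter == "sex"), 1L)
  expect_equal(sum(plan$parameter == "age_sex"), 6L)
  expect_equal(sum(plan$parameter == "apoe"), 1L)
  expect_equal(sum(plan$parameter == "crs"), 3L)
  expect_equal(sum(plan$parameter == "bmi"), 2L)
  expect_equal(attr(plan, "n_pairs"), 16L)
  expect_equal(attr(plan, "n_tests"), 112L)
})

test_that("group comparisons report medians, percent differences and corrections", {
  a <- c(10, 20, 30, 40)
  res <- compare_two_groups(a, a)
  expect_equal(res$percent_difference, 0)
  expect_equal(res$p_raw, 1)

  # negative reference median: |median_a| denominator keeps the sign of b - a
  res_neg <- compare_two_groups(c(-12, -10, -8), c(-7, -5, -3))
  expect_equal(res_neg$percent_difference, 100 * ((-5) - (-10)) / 10)
  expect_gt(res_neg$percent_difference, 0)

  sim <- simulate_cohort(seed = 3)
  cmp <- compare_groups(sim$roi, sim$cohort)
  expect_equal(nrow(cmp), 112L * 2L)
  expect_equal(sum(cmp$metric == "qsm_ppb"), 112L)
  expect_true(all(cmp$p_bonferroni >= cmp$p_raw, na.rm = TRUE))
  expect_equal(cmp$p_bonferroni, pmin(1, 112 * cmp$p_raw), tolerance = 1e-12)
  ok <- !is.na(cmp$u_statistic)
  expect_true(all(cmp$u_statistic[ok] >= 0 &
                    cmp$u_statistic[ok] <= cmp$n_a[ok] * cmp$n_b[ok]))
})

test_that("an injected CRS effect is recovered as a median percent difference", {
  eff <- list(list(variable = "crs", level = 2, roi = "putamen",
                   metric = "qsm_ppb", multiplier = 1.217))
  pct <- vapply(0:39, function(s) {
    sim <- simulate_cohort(seed = s, group_effects = eff)
    coh <- assign_groups(sim$cohort)
    vals <- sim$roi[sim$roi$roi_name == "putamen" & sim$roi$metric == "qsm_ppb", ]
    a <- vals$trimmed_mean[vals$subject_id %in% coh$subject_id[coh$crs <= 1]]
    b <- vals$trimmed_mean[vals$subject_id %in% coh$subject_id[coh$crs == 2]]
    compare_two_groups(a, b)$percent_difference
  }, numeric(1))
  expect_lt(abs(mean(pct) - 21.7), 4)
})
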