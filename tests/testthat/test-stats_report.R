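test_that("normalization schemes divide by the documented references", {
  v <- c(2, 3, 4)
  expect_equal(as.numeric(normalize_measure(v, "to_t0")), c(1, 1.5, 2))
  expect_equal(attr(normalize_measure(v, "to_t0"), "normalization"), "to_t0")
  expect_equal(as.numeric(normalize_measure(3, "to_iso_control",
                                            reference = c(1.5, 2.5))), 1.5)
  expect_equal(as.numeric(normalize_measure(v, "to_reference_signal",
                                            reference = 2)), v / 2)
  expect_equal(as.numeric(normalize_measure(v, "to_ca0_pvp_control",
                                            reference = 4)), v / 4)
  # schemes commute with positive rescaling of the raw values
  expect_equal(as.numeric(normalize_measure(v * 13, "to_t0")),
               as.numeric(normalize_measure(v, "to_t0")))
  expect_error(normalize_measure(v, "to_iso_control"), "control")
  expect_error(normalize_measure(c(0, 1), "to_t0"), "zero")
  # outputs from different schemes are marked as such
  a <- normalize_measure(v, "to_t0")
  b <- normalize_measure(v, "to_reference_signal", reference = 2)
  expect_false(identical(attr(a, "normalization"),
                         attr(b, "normalization")))
})

test_that("the two-group gate picks the documented test paths", {
  set.seed(101)
  norm_paths <- replicate(60, gated_two_group(rnorm(30), rnorm(30))$test_name)
  expect_gt(mean(norm_paths %in% c("student_t", "welch_t")), 0.9)
  heavy_paths <- replicate(40,
                           gated_two_group(rcauchy(20), rcauchy(20))$test_name)
  expect_gt(mean(heavy_paths == "mann_whitney_u"), 0.7)
  # unequal variances on normal data route to Welch
  set.seed(5)
  welch <- replicate(40, gated_two_group(rnorm(40, 0, 1),
                                         rnorm(40, 0, 6))$test_name)
  expect_gt(mean(welch == "welch_t"), 0.7)
  expect_error(gated_two_group(1:2, 1:5), "at least 3")
})

test_that("the gate is deterministic and its trace explains the choice", {
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20, 1)
  r1 <- gated_two_group(a, b)
  r2 <- gated_two_group(a, b)
  expect_identical(r1$test_name, r2$test_name)
  expect_identical(r1$p_value, r2$p_value)
  gt <- r1$gate_trace
  if (gt$normal) {
    expect_true(gt$shapiro_a > 0.05 && gt$shapiro_b > 0.05)
    expect_identical(r1$test_name,
                     if (gt$equal_var) "student_t" else "welch_t")
  } else {
    expect_identical(r1$test_name, "mann_whitney_u")
  }
})

test_that("type-I error of the gated two-group test is calibrated", {
  set.seed(7)
  rej <- mean(replicate(2000,
                        gated_two_group(rnorm(15), rnorm(15))$p_value <= 0.05))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("Games-Howell matches an independent reference computation", {
  # expected values computed with pingouin.pairwise_gameshowell on the
  # same fixed samples (frozen)
  a <- c(4.1, 5.2, 3.9, 4.8, 5.5, 4.2, 4.9)
  b <- c(6.3, 7.1, 6.8, 5.9, 7.4, 6.1)
  c3 <- c(5.0, 5.3, 4.7, 5.9, 5.1, 4.6, 5.4, 5.2)
  gh <- games_howell(list(a, b, c3))
  expect_equal(gh$statistic, c(5.844576, 1.825295, 5.134936),
               tolerance = 1e-5)
  expect_equal(gh$df, c(10.747260, 10.396846, 8.457425), tolerance = 1e-5)
  expect_equal(gh$p_value, c(0.000330, 0.209114, 0.001920),
               tolerance = 1e-3)
  r <- gated_multi_group(list(a, b, c3))
  expect_identical(r$test_name, "welch_anova")
  expect_equal(r$statistic, 17.760693, tolerance = 1e-5)  # pingouin Welch F
  expect_equal(r$p_value, 0.000418, tolerance = 1e-3)
})

test_that("Dunn's z statistics match the closed form on tie-free ranks", {
  # groups {1,2,3},{4,5,6},{7,8,9}: mean ranks 2,5,8, s2 = N(N+1)/12 = 7.5
  d <- dunn_test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  z12 <- -3 / sqrt(7.5 * (2 / 3))
  expect_equal(d$statistic[1], z12, tolerance = 1e-10)
  expect_equal(d$p_value[1], 2 * pnorm(z12), tolerance = 1e-10)
  db <- dunn_test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
                  p_adjust = "bonferroni")
  expect_equal(db$p_value[1], min(1, d$p_value[1] * 3))
})

test_that("a shifted group dominates the post hoc table", {
  set.seed(9)
  g1 <- rnorm(25); g2 <- rnorm(25); g3 <- rnorm(25, 3)
  r <- gated_multi_group(list(g1, g2, g3))
  ph <- r$posthoc
  involving3 <- ph$group_i == 3 | ph$group_j == 3
  expect_true(all(ph$p_value[involving3] < 0.001))
  expect_gt(ph$p_value[!involving3], 0.05)
  expect_error(gated_multi_group(list(g1, g2)), "3 groups")
  expect_error(gated_multi_group(list(rep(1, 5), rep(1, 5), rep(1, 5))),
               "zero variance")
})

test_that("OLS rate fitting recovers slopes with full diagnostics", {
  ser <- data.frame(time = rep(seq(4, 5, 0.25), each = 3))
  set.seed(2)
  ser$S <- 1 + 0.3 * ser$time + rnorm(nrow(ser), 0, 1e-4)
  fit <- ols_rate(ser)
  expect_equal(fit$slope, 0.3, tolerance = 1e-2)
  expect_gt(fit$r_squared, 0.999)
  expect_true(fit$ci[1] <= fit$slope && fit$slope <= fit$ci[2])
  expect_true(all(c("breusch_pagan_p", "shapiro_resid_p",
                    "durbin_watson") %in% names(fit$diagnostics)))
  # two time points only: still fits, linearity checks not applicable
  two <- data.frame(time = rep(c(4, 5), each = 12),
                    S = rep(c(2, 2.3), each = 12) + rnorm(24, 0, 0.05))
  f2 <- ols_rate(two)
  expect_equal(f2$n, 24L)
  expect_error(ols_rate(data.frame(time = rep(4.5, 6), S = rnorm(6))),
               "2 time points")
  expect_error(ols_rate(data.frame(time = rep(c(4, 5), 3), S = rep(1, 6))),
               "zero variance")
})

test_that("heteroscedastic residuals trigger the HC3 fallback", {
  set.seed(3)
  flags <- replicate(40, {
    t <- rep(seq(4, 5, 0.25), each = 10)
    S <- 1 + 0.3 * t + rnorm(length(t), 0, 0.01 + 0.4 * (t - 4))
    ols_rate(data.frame(time = t, S = S))$robust_se_used
  })
  expect_gt(mean(flags), 0.9)
})

test_that("slope recovery is unbiased at 25 cells with 10% noise", {
  set.seed(13)
  slopes <- replicate(200, {
    t <- rep(seq(4, 5, 0.25), each = 25)
    S <- 1 + 0.3 * t + rnorm(length(t), 0, 0.1)
    ols_rate(data.frame(time = t, S = S))$slope
  })
  expect_lt(abs(mean(slopes) / 0.3 - 1), 0.02)
})

test_that("Pearson fits report r, p and a finite confidence band", {
  p <- pearson_fit(1:10, 2 * (1:10))
  expect_equal(p$r, 1)
  expect_equal(p$slope, 2)
  expect_true(all(p$band$lower <= p$band$fit & p$band$fit <= p$band$upper))
  set.seed(21)
  rs <- replicate(40, pearson_fit(rnorm(1000), rnorm(1000))$r)
  expect_gt(mean(abs(rs) < 0.1), 0.95)
  expect_error(pearson_fit(1:2, 2:3), "at least 3")
  expect_error(pearson_fit(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("equivalent radii follow r = sqrt(A/pi)", {
  expect_equal(area_to_radius(pi), 1)
  expect_equal(area_to_radius(0), 0)
  expect_equal(area_to_radius(100 * pi), 10)
  expect_error(area_to_radius(-1), "non-negative")
})

test_that("significance stars use the published thresholds", {
  stars <- tensimetry:::significance_stars(c(0.2, 0.04, 0.009, 5e-4, 5e-5))
  expect_identical(stars, c("ns", "*", "**", "***", "****"))
})
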