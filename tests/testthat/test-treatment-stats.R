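# Independent oracle: balanced two-way ANOVA sums of squares from cell and
# marginal means (projection formulas), no model-fitting machinery.
anova_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- table(a, b)[1, 1]
  grand <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- n * nlevels(b) * sum((ma - grand)^2)
  ss_b <- n * nlevels(a) * sum((mb - grand)^2)
  ss_ab <- n * sum((sweep(sweep(mab, 1, ma), 2, mb) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  c(a = ss_a, b = ss_b, ab = ss_ab, resid = ss_tot - ss_a - ss_b - ss_ab,
    total = ss_tot)
}

test_that("two-way ANOVA matches the projection oracle and conserves SS", {
  set.seed(101)
  des <- expand.grid(rep = 1:4, a = c("0.9", "4.7", "7.0"),
                     b = c("0.17", "0.29"))
  for (i in 1:5) {
    y <- rnorm(nrow(des), mean = 10 + 2 * (des$a == "0.9") - (des$b == "0.29"))
    got <- two_way_anova(y, des$a, des$b)
    want <- anova_oracle(y, des$a, des$b)
    expect_equal(got$sumsq, unname(want[c("a", "b", "ab", "resid")]),
                 tolerance = 1e-8)
    expect_equal(sum(got$sumsq), unname(want["total"]), tolerance = 1e-8)
    expect_equal(got$df, c(2, 1, 2, 18))
  }
})

test_that("constant response yields zero total SS; invalid designs are rejected", {
  des <- expand.grid(rep = 1:2, a = c("x", "y"), b = c("u", "v"))
  got <- two_way_anova(rep(3.3, nrow(des)), des$a, des$b)
  expect_equal(sum(got$sumsq), 0)
  expect_error(two_way_anova(1:6, c("x", "x", "x", "y", "y", "y"),
                             c("u", "u", "v", "v", "v", "v")), "balanced|empty")
  expect_error(two_way_anova(1:4, c("x", "x", "y", "y"), c("u", "v", "u", "v")),
               "replicates")
})

test_that("ANOVA type-I error under the null stays near nominal", {
  set.seed(202)
  des <- expand.grid(rep = 1:4, a = 1:3, b = 1:2)
  reject <- replicate(1000, {
    y <- rnorm(nrow(des))
    two_way_anova(y, des$a, des$b)$p_value[1] < 0.05
  })
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})

test_that("Duncan letters separate clear differences and merge equal means", {
  # two groups far apart
  g2 <- duncan_mrt(c(lo = 1, hi = 100), ms_error = 1, df_error = 10,
                   n_per_group = 5)
  expect_equal(g2$letters, c("a", "b"))
  # equal means share a letter
  g3 <- duncan_mrt(c(a = 5, b = 5, c = 5), ms_error = 1, df_error = 10,
                   n_per_group = 5)
  expect_true(all(g3$letters == "a"))
  # the salinity Pn pattern with a small pooled error: all pairwise distinct
  g <- duncan_mrt(c(`0.9` = 21.2, `4.7` = 16.0, `7.0` = 13.2),
                  ms_error = 0.5, df_error = 18, n_per_group = 8)
  expect_equal(g$letters, c("a", "b", "c"))
  expect_equal(g$level, c("0.9", "4.7", "7.0"))
  # non-overlapping letters imply a gap larger than the pairwise critical
  # range at the comparisonwise level
  r2 <- qtukey(0.95, 2, 18) * sqrt(0.5 / 8)
  expect_gt(16.0 - 13.2, r2)
  expect_error(duncan_mrt(c(1, 2), 1, 0, 4), "positive")
})

test_that("Duncan letters coarsen with larger error variance", {
  m <- c(a = 10, b = 9.5, c = 5)
  tight <- duncan_mrt(m, ms_error = 0.05, df_error = 18, n_per_group = 4)
  loose <- duncan_mrt(m, ms_error = 5, df_error = 18, n_per_group = 4)
  expect_equal(tight$letters, c("a", "b", "c"))
  # with a large pooled error the top two merge
  expect_equal(loose$letters[1], loose$letters[2])
})

test_that("ANCOVA detects unequal slopes and matches a brute-force GLM oracle", {
  set.seed(303)
  # identical slopes, zero noise: interaction SS exactly zero
  gs <- rep(seq(0.1, 0.9, length.out = 10), 2)
  grp <- rep(c("A", "B"), each = 10)
  pn0 <- ifelse(grp == "A", 1, 4) + 5 * log(gs)
  res0 <- ancova_slope_test(pn0, gs, grp)
  expect_lt(res0$interaction_ss, 1e-20)
  expect_equal(unname(res0$slopes), c(5, 5), tolerance = 1e-10)
  # slopes 3 vs 6 with small noise: overwhelming evidence
  gs1 <- rep(seq(0.05, 1, length.out = 30), 2)
  grp1 <- rep(c("A", "B"), each = 30)
  pn1 <- ifelse(grp1 == "A", 2 + 3 * log(gs1), 2 + 6 * log(gs1)) +
    rnorm(60, 0, 0.1)
  res1 <- ancova_slope_test(pn1, gs1, grp1)
  expect_lt(res1$interaction_p, 0.001)
  expect_false(res1$common_slope_adopted)
  # oracle: interaction F from explicit normal-equation projections
  set.seed(304)
  gs2 <- runif(12, 0.1, 1)
  grp2 <- rep(c("A", "B"), each = 6)
  pn2 <- 3 + 2 * log(gs2) + (grp2 == "B") * 1.5 + rnorm(12, 0, 0.4)
  res2 <- ancova_slope_test(pn2, gs2, grp2)
  x <- log(gs2); d <- as.numeric(grp2 == "B")
  Xf <- cbind(1, d, x, d * x)
  Xr <- cbind(1, d, x)
  rss <- function(X, y) {
    b <- ols_normal_equations(X, y)
    sum((y - X %*% b)^2)
  }
  f_oracle <- ((rss(Xr, pn2) - rss(Xf, pn2)) / 1) / (rss(Xf, pn2) / (12 - 4))
  expect_equal(res2$interaction_f, f_oracle, tolerance = 1e-8)
  # per-group slopes equal separate OLS fits
  for (g in c("A", "B")) {
    sl <- ols_normal_equations(cbind(1, x[grp2 == g]), pn2[grp2 == g])[2, 1]
    expect_equal(unname(res2$slopes[g]), sl, tolerance = 1e-8)
  }
})

test_that("simple regression matches the normal equations and flags degeneracy", {
  x <- 1:6
  y <- 2 + 0.5 * x
  fit <- linear_regression_r2(x, y)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  set.seed(404)
  x2 <- rnorm(40); y2 <- rnorm(40)
  fit2 <- linear_regression_r2(x2, y2)
  beta <- ols_normal_equations(cbind(1, x2), y2)
  expect_equal(fit2$intercept, as.numeric(beta[1, 1]), tolerance = 1e-10)
  expect_equal(fit2$slope, as.numeric(beta[2, 1]), tolerance = 1e-10)
  expect_lt(fit2$r_squared, 0.2)
  expect_error(linear_regression_r2(rep(1, 5), 1:5), "variance")
})

test_that("treatment_table combines ANOVA, letters and stars for a response", {
  set.seed(505)
  ex <- generate_experiment(experiment_design(), generation_model())
  tt <- treatment_table(ex$gas_exchange, "pn")
  expect_equal(tt$anova$term, c("ec", "lf", "ec:lf", "Residuals"))
  expect_equal(nrow(tt$means_a), 3)
  expect_equal(nrow(tt$means_b), 2)
  # salinity effect on Pn is large relative to the generator noise
  expect_equal(tt$stars[["ec"]], "***")
  # averaging over days first leaves one value per pot: residual df = 18
  expect_equal(tt$anova$df[4], 18)
  # pooling mode uses all 72 rows
  tt_pool <- treatment_table(ex$gas_exchange, "pn", pooling = "pool")
  expect_equal(tt_pool$anova$df[4], 66)
})
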