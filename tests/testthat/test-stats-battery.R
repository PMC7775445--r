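test_that("3-SD outlier exclusion is single-pass on full-sample moments", {
  v <- c(rep(0, 30), 100)
  keep <- exclude_outliers(v)
  expect_false(keep[31])
  expect_true(all(keep[1:30]))
  expect_true(all(exclude_outliers(rep(5, 10))))
  withr::with_seed(1, {
    z <- rnorm(31)
    expect_gte(sum(exclude_outliers(z)), 30)
  })
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("the Shapiro-Wilk gate selects Pearson vs Spearman", {
  withr::with_seed(42, {
    x <- rnorm(31); y <- rnorm(31)
    expect_equal(choose_method(x, y)$method, "pearson")
    # heavy right skew triggers the gate with high probability
    n_spear <- 0
    for (i in 1:50) {
      sk <- rlnorm(31, 0, 1)
      if (choose_method(rnorm(31), sk)$method == "spearman")
        n_spear <- n_spear + 1
    }
    expect_gt(n_spear / 50, 0.8)
    # the gate is invariant to affine rescaling
    g1 <- choose_method(x, y)
    g2 <- choose_method(3 * x - 7, 0.1 * y + 2)
    expect_equal(g1$method, g2$method)
    expect_equal(g1$shapiro_x, g2$shapiro_x, tolerance = 1e-8)
  })
  # constant input: Shapiro-Wilk undefined, falls back to Spearman
  expect_equal(choose_method(rep(1, 10), rnorm(10))$method, "spearman")
})

test_that("partial correlation equals the precision-matrix oracle", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- 31
      Z <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5), iq = rnorm(n))
      x <- rnorm(n) + 0.4 * Z[, 1]
      y <- rnorm(n) + 0.3 * Z[, 1]
      for (m in c("pearson", "spearman")) {
        pc <- partial_correlation(x, y, Z, method = m)
        expect_equal(pc$estimate, precision_partial(x, y, Z, m),
                     tolerance = 1e-10)
        expect_equal(pc$df, n - 5)
      }
    }
  })
})

test_that("partial correlation handles orthogonal and confounded cases", {
  withr::with_seed(8, {
    n <- 40
    Z <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    # make x and y exactly orthogonal to the covariates in sample
    x <- lm.fit(cbind(1, Z), rnorm(n))$residuals
    y <- lm.fit(cbind(1, Z), rnorm(n))$residuals
    pc <- partial_correlation(x, y, Z, method = "pearson")
    expect_equal(pc$estimate, cor(x, y), tolerance = 1e-10)
    # y equal to a covariate: perfect confound removal
    pc2 <- partial_correlation(x, Z[, 1], Z, method = "pearson")
    expect_lt(abs(pc2$estimate), 1e-7)
    # collinear covariates are rejected by name
    Zbad <- cbind(Z, dup = Z[, 1])
    expect_error(partial_correlation(x, y, Zbad, method = "pearson"),
                 "rank-deficient")
    expect_error(partial_correlation(x[1:5], y[1:5], Z[1:5, ]), "n > k")
  })
})

test_that("one-sample t matches closed forms and reports effect size", {
  r <- one_sample_t(rep(3, 5), mu = 3)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- one_sample_t(c(1, 2, 3), mu = 0)
  expect_equal(r2$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r2$df, 2)
  expect_equal(r2$d, 2)
  expect_equal(r2$mean_diff, 2)
  expect_error(one_sample_t(1), "at least 2")
})

test_that("extreme-group contrast uses terciles and the Levene gate", {
  withr::with_seed(9, {
    rec <- data.frame(subject_id = sprintf("S%02d", 1:30),
                      adhd_index = sample(rep(0:14, 2)),
                      y = rnorm(30))
    r <- independent_t_extreme_groups(rec, "y")
    expect_equal(r$group_sizes, c(10, 10))
    expect_equal(r$df, 18)           # pooled df with 10 + 10
    expect_true(r$pooled)
    # constructed groups: t matches the pooled-variance hand formula
    rec2 <- data.frame(subject_id = sprintf("S%02d", 1:30),
                       adhd_index = rep(c(0, 5, 10), each = 10),
                       y = c(rnorm(10, 0, 0.3), rnorm(10, 0.5, 0.3),
                             rnorm(10, 1, 0.3)))
    r2 <- independent_t_extreme_groups(rec2, "y")
    lo <- rec2$y[1:10]; hi <- rec2$y[21:30]
    sp <- sqrt((var(lo) + var(hi)) / 2)
    t_hand <- (mean(hi) - mean(lo)) / (sp * sqrt(2 / 10))
    expect_equal(r2$t, t_hand, tolerance = 1e-10)
    expect_error(independent_t_extreme_groups(rec[1:5, ], "y"), "grouping")
  })
})

test_that("identical group distributions give small t on average", {
  withr::with_seed(10, {
    ts <- replicate(200, {
      rec <- data.frame(subject_id = sprintf("S%02d", 1:30),
                        adhd_index = sample(30), y = rnorm(30))
      independent_t_extreme_groups(rec, "y")$t
    })
    expect_lt(abs(mean(ts)), 0.2)
  })
})

test_that("polynomial fits report R2 against a normal-equations oracle", {
  withr::with_seed(11, {
    x <- rnorm(31, 5, 2)
    y_quad <- 1 + 2 * x - 0.5 * x^2
    expect_equal(polynomial_fit_r2(x, y_quad, "quadratic"), 1,
                 tolerance = 1e-10)
    y <- rnorm(31)
    xl <- if (min(x) <= 0) x - min(x) + 1 else x
    for (form in c("log", "quadratic", "cubic")) {
      X <- switch(form, log = cbind(1, log(xl)),
                  quadratic = cbind(1, x, x^2),
                  cubic = cbind(1, x, x^2, x^3))
      beta <- solve(t(X) %*% X, t(X) %*% y)
      r2_oracle <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
      expect_equal(polynomial_fit_r2(x, y, form), r2_oracle,
                   tolerance = 1e-9)
    }
    # nesting: the quadratic fit can never undercut the linear fit
    expect_gte(polynomial_fit_r2(x, y, "quadratic") + 1e-12, cor(x, y)^2)
    expect_error(polynomial_fit_r2(rep(1, 10), rnorm(10), "log"),
                 "degenerate")
  })
})

test_that("analytic thresholds match the published design numbers", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_equal(round(min_detectable_r(31), 2), 0.48)
  expect_equal(min_detectable_r(50),
               tanh((qnorm(0.975) + qnorm(0.8)) / sqrt(47)),
               tolerance = 1e-12)
  # monotone decrease toward zero with growing n
  r <- sapply(c(10, 31, 100, 1000, 10000), min_detectable_r)
  expect_true(all(diff(r) < 0))
  expect_lt(r[5], 0.03)
  expect_error(min_detectable_r(3), "n > 3")
})

test_that("the battery produces one gated row per component/site/measure", {
  rec <- null_records(31, seed = 12)
  bat <- run_correlation_battery(rec)
  expect_equal(nrow(bat), 20)
  expect_equal(sum(bat$primary), 12)   # 3 components x 4 measures
  key <- paste(bat$component, bat$site, bat$measure)
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(bat$method %in% c("pearson", "spearman")))
  expect_true(all(abs(bat$coefficient) <= 1))
  expect_true(all(bat$n + bat$n_outliers == 31))
  expect_true(all(bat$sig_bonf <= bat$sig_unc))
  expect_equal(attr(bat, "bonferroni_threshold"), 0.0125)
  # the ADHD index is right-skewed, so its cells should gate to Spearman
  expect_gt(mean(bat$method == "spearman"), 0.5)
})
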