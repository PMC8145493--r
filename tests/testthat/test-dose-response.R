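test_that("Abbott correction matches the closed form and its identities", {
  expect_equal(abbott_correct(56.8, 0), 56.8)
  expect_equal(abbott_correct(60, 20), 50)
  expect_equal(abbott_correct(20, 20), 0)
  expect_equal(abbott_correct(10, 20), 0) # floored, never negative
  expect_error(abbott_correct(50, 100), "control")

  set.seed(7)
  for (i in 1:20) {
    c0 <- runif(1, 0, 80)
    t1 <- runif(1, c0, 100)
    t2 <- min(100, t1 + runif(1, 0, 100 - t1))
    # monotone increasing in treated mortality
    expect_true(abbott_correct(t2, c0) >= abbott_correct(t1, c0))
    # for treated > control, decreasing in control mortality
    if (t1 > c0 + 1) {
      expect_true(abbott_correct(t1, c0 / 2) >= abbott_correct(t1, c0))
    }
  }
})

test_that("angular transform and empirical probit hit their anchors", {
  expect_equal(angular_transform(c(0, 0.5, 1)), c(0, 45, 90))
  expect_error(angular_transform(1.2), "\\[0, 1\\]")
  expect_equal(empirical_probit(0.5), 5)
  expect_equal(empirical_probit(0.975), 5 + qnorm(0.975), tolerance = 1e-10)
  expect_equal(empirical_probit(pnorm(-1)), 4)
  expect_error(empirical_probit(0), "continuity")
  expect_error(empirical_probit(1), "continuity")
})

test_that("continuity adjustment pulls extremes inside (0, 1)", {
  expect_equal(continuity_adjust(0, 250), 1 / 500)
  expect_equal(continuity_adjust(250, 250), 1 - 1 / 500)
  expect_equal(continuity_adjust(125, 250), 0.5)
  expect_error(continuity_adjust(1, 0), "n_exposed")
  expect_error(continuity_adjust(5, 4), "n_dead")
})

test_that("both fitters recover a noiseless probit line exactly", {
  s <- model_series(slope = 2, log_lc50 = 0.5)
  ols <- fit_probit(s, method = "ols")
  ml <- fit_probit(s, method = "ml")
  expect_equal(ols$slope, 2, tolerance = 1e-8)
  expect_equal(ols$log_lc50, 0.5, tolerance = 1e-8)
  expect_equal(ml$slope, ols$slope, tolerance = 1e-6)
  expect_equal(ml$log_lc50, ols$log_lc50, tolerance = 1e-6)
  expect_lt(ml$chi2_het, 1e-10)
  expect_equal(ml$df, 3L)
})

test_that("two groups symmetric about c* on the log scale give lc50 = c*", {
  c_star <- 2.4
  delta <- 0.3
  conc <- c(10^(log10(c_star) - delta), 10^(log10(c_star) + delta))
  s <- bioassay_series(conc, mortality_pct = c(40, 60))
  for (m in c("ols", "ml")) {
    f <- fit_probit(s, method = m)
    expect_equal(10^f$log_lc50, c_star, tolerance = 1e-6)
  }
})

test_that("the IRLS maximum-likelihood fit agrees with glm binomial probit", {
  for (s in example_series()) {
    ml <- fit_probit(s, method = "ml")
    g <- s$groups
    # fractional pooled deaths are fine for glm's IRLS (warning suppressed)
    ref <- suppressWarnings(
      glm(cbind(n_dead, n_exposed - n_dead) ~ log10(concentration),
          family = binomial(link = "probit"), data = g))
    expect_equal(ml$slope, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_equal(ml$intercept - 5, unname(coef(ref)[1]), tolerance = 1e-6)
    # asymptotic covariances from the same information matrix
    expect_equal(ml$cov, unname(vcov(ref)), tolerance = 1e-4)
  }
})

test_that("OLS and ML LC50s agree within 15% on the example series", {
  for (s in example_series()) {
    lc_ols <- 10^fit_probit(s, method = "ols")$log_lc50
    lc_ml <- 10^fit_probit(s, method = "ml")$log_lc50
    expect_lt(abs(lc_ols - lc_ml) / lc_ml, 0.15)
  }
})

test_that("fiducial limits bracket the estimate and collapse as g -> 0", {
  for (s in example_series()) {
    e <- lc50_with_limits(fit_probit(s))
    expect_true(e$limits_defined)
    expect_lt(e$g, 1)
    expect_true(e$lower <= e$lc50 && e$lc50 <= e$upper)
    expect_gte(e$heterogeneity_factor, 1)
  }
  # negligible parameter variance: limits collapse onto the point estimate
  fit <- structure(list(slope = 2, intercept = 4, log_lc50 = 0.5,
                        cov = diag(c(1e-12, 1e-12)), chi2_het = 0, df = 3L,
                        method = "ml"), class = "probit_fit")
  e0 <- lc50_with_limits(fit)
  expect_equal(e0$lower, e0$lc50, tolerance = 1e-4)
  expect_equal(e0$upper, e0$lc50, tolerance = 1e-4)
  expect_lt(e0$g, 1e-6)
})

test_that("limits are flagged undefined when g >= 1", {
  fit <- structure(list(slope = 0.5, intercept = 4.9, log_lc50 = 0.2,
                        cov = matrix(c(0.5, 0, 0, 0.5), 2), chi2_het = 0,
                        df = 3L, method = "ml"), class = "probit_fit")
  e <- lc50_with_limits(fit)
  expect_false(e$limits_defined)
  expect_gte(e$g, 1)
  expect_true(is.na(e$lower) && is.na(e$upper))
})

test_that("series construction validates, pools and Abbott-corrects", {
  expect_no_error(bioassay_series(1.5, mortality_pct = 50))
  expect_error(fit_probit(bioassay_series(1.5, mortality_pct = 50)),
               "at least 2")
  expect_error(bioassay_series(c(-1, 2), mortality_pct = c(10, 20)),
               "concentration")
  expect_error(bioassay_series(c(1, 2), mortality_pct = c(10, 120)),
               "\\[0, 100\\]")
  # duplicate concentrations pooled by summing deaths and exposures
  s <- bioassay_series(c(1, 1, 2), n_dead = c(10, 20, 40),
                       n_exposed = c(50, 50, 50))
  expect_equal(nrow(s$groups), 2L)
  expect_equal(s$groups$n_dead[1], 30)
  expect_equal(s$groups$n_exposed[1], 100)
  # Abbott correction applied when a control mortality is declared
  s2 <- bioassay_series(c(1, 2), mortality_pct = c(60, 20),
                        control_mortality_pct = 20)
  expect_equal(s2$groups$mortality_pct, c(50, 0))
})

test_that("a flat series draws a non-positive-slope warning", {
  s <- bioassay_series(c(1, 2, 4), mortality_pct = c(60, 50, 40))
  expect_warning(fit_probit(s, method = "ols"), "non-positive")
})
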