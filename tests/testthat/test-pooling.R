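random_meta <- function(seed) {
  set.seed(seed)
  k <- sample(3:7, 1)
  list(
    yi = rnorm(k, 0.3, 0.4),
    vi = runif(k, 0.01, 0.1)
  )
}

test_that("identical estimates pool to themselves with zero heterogeneity", {
  p <- pool_metric(rep(0.42, 5), rep(0.02, 5))
  expect_equal(p$estimate, 0.42)
  expect_equal(p$tau2, 0)
})

test_that("REML pooling matches a grid-search restricted-likelihood maximiser", {
  toy <- pool_metric(c(0.2, 0.5, 0.9), c(0.04, 0.04, 0.04))
  oracle <- reml_grid_oracle(c(0.2, 0.5, 0.9), c(0.04, 0.04, 0.04))
  expect_equal(toy$tau2, oracle$tau2, tolerance = 1e-4)
  expect_equal(toy$estimate, oracle$mu, tolerance = 1e-4)

  for (seed in 101:120) {
    m <- random_meta(seed)
    p <- pool_metric(m$yi, m$vi)
    o <- reml_grid_oracle(m$yi, m$vi)
    expect_equal(p$tau2, o$tau2, tolerance = 1e-4)
    expect_equal(p$estimate, o$mu, tolerance = 1e-4)
    expect_equal(p$se, o$se, tolerance = 1e-4)
  }
})

test_that("an infinitely imprecise study carries no weight", {
  p3 <- pool_metric(c(0.1, 0.3, 5.0), c(0.02, 0.02, 1e8))
  p2 <- pool_metric(c(0.1, 0.3), c(0.02, 0.02))
  expect_equal(p3$estimate, p2$estimate, tolerance = 1e-3)
  expect_lt(p3$studies$weight[3], 1e-4)
})

test_that("the prediction interval follows the t closed form and contains the CI", {
  for (seed in 121:140) {
    m <- random_meta(seed)
    p <- pool_metric(m$yi, m$vi)
    o <- reml_grid_oracle(m$yi, m$vi)
    k <- length(m$yi)
    half <- qt(0.975, k - 2) * sqrt(o$tau2 + o$se^2)
    expect_equal(p$pri_upper - p$pri_lower, 2 * half, tolerance = 1e-3)
    expect_lte(p$pri_lower, p$ci_lower + 1e-10)
    expect_gte(p$pri_upper, p$ci_upper - 1e-10)
    expect_true(p$ci_lower <= p$estimate && p$estimate <= p$ci_upper)
    # convex weighting keeps the pooled value inside the study range
    expect_gte(p$estimate, min(m$yi))
    expect_lte(p$estimate, max(m$yi))
  }
})

test_that("homogeneous large meta-analyses have PrI approaching the CI", {
  p <- pool_metric(rep(0.5, 30), runif(30, 0.01, 0.02))
  expect_equal(p$tau2, 0)
  ratio <- (p$pri_upper - p$pri_lower) / (p$ci_upper - p$ci_lower)
  expect_equal(ratio, qt(0.975, 28) / qnorm(0.975), tolerance = 1e-6)
})

test_that("prediction intervals need at least three studies", {
  p <- pool_metric(c(0.2, 0.6), c(0.02, 0.03))
  expect_warning(pi2 <- prediction_interval(p),
                 class = "picnicc_pri_omitted")
  expect_false(pi2$available)
  expect_error(pool_metric(0.3, 0.02), class = "picnicc_pool_error")
})

test_that("tau2 is shift invariant and the pooled estimate shifts along", {
  m <- random_meta(55)
  p0 <- pool_metric(m$yi, m$vi)
  p1 <- pool_metric(m$yi + 2.5, m$vi)
  expect_equal(p1$tau2, p0$tau2, tolerance = 1e-6)
  expect_equal(p1$estimate, p0$estimate + 2.5, tolerance = 1e-6)
})

test_that("analysis scales back-transform exactly in tidy output", {
  perf <- small_perf()
  pooled <- suppressWarnings(pool_performance(perf))
  td <- tidy(pooled)
  c_row <- td[td$metric == "c_statistic", ]
  expect_equal(plogis(c_row$estimate_analysis), c_row$estimate,
               tolerance = 1e-12)
  eo_row <- td[td$metric == "e_o_ratio", ]
  expect_equal(exp(eo_row$estimate_analysis), eo_row$estimate,
               tolerance = 1e-12)
  slope_row <- td[td$metric == "calib_slope", ]
  expect_equal(slope_row$estimate_analysis, slope_row$estimate)
  expect_true(all(td$k <= nrow(perf)))
})

test_that("meta-regression recovers a linear intercept-on-proportion relation", {
  set.seed(77)
  prop <- runif(12, 0.1, 0.4)
  yi <- -4 + 2 * prop + rnorm(12, 0, 0.03)
  vi <- rep(0.01, 12)
  mr <- meta_regress(yi, vi, prop)
  expect_equal(mr$slope, 2, tolerance = 0.35)
  # interpolation at an observed covariate value lies on the fitted line
  expect_equal(
    mr$interpolate(prop[3]),
    mr$intercept + mr$slope * prop[3],
    tolerance = 1e-12
  )
})

test_that("meta-regression handles degenerate and undersized inputs", {
  expect_warning(
    mr <- meta_regress(c(-4, -4.2, -3.9), rep(0.02, 3), rep(0.25, 3)),
    class = "picnicc_metareg_degenerate"
  )
  expect_true(mr$degenerate)
  expect_true(is.na(mr$slope))
  expect_equal(
    mr$intercept,
    pool_metric(c(-4, -4.2, -3.9), rep(0.02, 3))$estimate
  )
  expect_error(meta_regress(c(-4, -4.1), rep(0.02, 2), c(0.2, 0.3)),
               class = "picnicc_pool_error")
  mr2 <- meta_regress(c(-4, -4.2, -3.9, -3.6), rep(0.02, 4),
                      c(0.18, 0.22, 0.27, 0.33))
  expect_warning(mr2$interpolate(0.5),
                 class = "picnicc_metareg_extrapolation")
})
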