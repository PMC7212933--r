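test_that("C-statistic handles separation, ties and one-class inputs", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(c_statistic(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_warning(
    expect_true(is.na(c_statistic(c(0.2, 0.4), c(1, 1)))),
    class = "picnicc_undefined_metric"
  )
})

test_that("C-statistic equals exhaustive pairwise concordance on random instances", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    # coarse grid of risks forces cross-class ties regularly
    risks <- sample(seq(0.05, 0.95, by = 0.1), n, replace = TRUE)
    outcomes <- rbinom(n, 1, 0.4)
    if (sum(outcomes) == 0 || sum(outcomes) == n) next
    expect_equal(
      c_statistic(risks, outcomes),
      brute_force_c(risks, outcomes),
      tolerance = 1e-12
    )
  }
})

test_that("C-statistic is invariant under increasing transforms and flips with the outcome", {
  set.seed(7)
  for (i in 1:10) {
    risks <- runif(40)
    outcomes <- rbinom(40, 1, 0.3)
    if (sum(outcomes) %in% c(0, 40)) next
    c0 <- c_statistic(risks, outcomes)
    expect_equal(c_statistic(qlogis(risks), outcomes), c0)
    expect_equal(c_statistic(risks^3, outcomes), c0)
    expect_equal(c_statistic(risks, 1 - outcomes), 1 - c0)
  }
})

test_that("E/O ratio is direct arithmetic and scales linearly", {
  expect_equal(e_o_ratio(c(0.6, 0.6), c(1, 0)), 1.2)
  expect_equal(e_o_ratio(rep(0.5, 10), rep(c(1, 0), 5)), 1)
  expect_warning(
    expect_true(is.na(e_o_ratio(c(0.2, 0.3), c(0, 0)))),
    class = "picnicc_undefined_metric"
  )
  set.seed(3)
  risks <- runif(50, 0.05, 0.45)
  outcomes <- rbinom(50, 1, 0.3)
  expect_equal(
    e_o_ratio(2 * risks, outcomes),
    2 * e_o_ratio(risks, outcomes)
  )
})

test_that("E/O is near 1 when outcomes are drawn from the risks", {
  set.seed(19)
  risks <- runif(50000, 0.02, 0.6)
  outcomes <- rbinom(length(risks), 1, risks)
  expect_equal(e_o_ratio(risks, outcomes), 1, tolerance = 0.02)
})

test_that("calibration fit matches an independent Newton-Raphson oracle", {
  lp <- c(-2.1, -1.4, -0.7, -0.2, 0.3, 0.9, 1.6, 2.2)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  fit <- calibration_fit(lp, y)
  oracle <- irls_logistic(cbind(1, lp), y)
  expect_equal(fit$intercept, oracle$coef[1], tolerance = 1e-6)
  expect_equal(fit$slope, oracle$coef[2], tolerance = 1e-6)
  expect_equal(fit$slope_se, sqrt(oracle$vcov[2, 2]), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("calibration fit recovers a known generating slope", {
  set.seed(99)
  lp <- rnorm(40000, -1.2, 1)
  y <- rbinom(length(lp), 1, plogis(0.5 * lp))
  fit <- calibration_fit(lp, y)
  expect_equal(fit$slope, 0.5, tolerance = 0.05)
})

test_that("calibration fit flags degenerate inputs", {
  expect_warning(
    out <- calibration_fit(rep(0.3, 20), rbinom(20, 1, 0.5)),
    class = "picnicc_undefined_metric"
  )
  expect_true(is.na(out$slope))
  expect_true(is.finite(out$citl))
  expect_warning(
    calibration_fit(rnorm(10), rep(1, 10)),
    class = "picnicc_undefined_metric"
  )
})

test_that("confusion counts partition events and non-events", {
  out <- confusion_at_threshold(c(0.05, 0.2, 0.5, 0.08), c(0, 1, 1, 0))
  expect_equal(out[, c("tp", "fn", "tn", "fp")],
               tibble::tibble(tp = 2L, fn = 0L, tn = 2L, fp = 0L),
               ignore_attr = TRUE)
  expect_equal(out$sens, 1)
  expect_equal(out$spec, 1)

  high <- confusion_at_threshold(runif(20, 0.2, 0.9), rbinom(20, 1, 0.3))
  expect_equal(high$spec, 0)
  expect_equal(high$low_risk_frac, 0)

  set.seed(8)
  risks <- runif(20)
  outcomes <- rbinom(20, 1, 0.4)
  got <- confusion_at_threshold(risks, outcomes, 0.3)
  # enumeration oracle
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(risks)) {
    low <- risks[i] <= 0.3
    if (outcomes[i] == 1 && !low) tp <- tp + 1
    if (outcomes[i] == 1 && low) fn <- fn + 1
    if (outcomes[i] == 0 && low) tn <- tn + 1
    if (outcomes[i] == 0 && !low) fp <- fp + 1
  }
  expect_equal(unlist(got[, c("tp", "fn", "tn", "fp")]),
               c(tp = tp, fn = fn, tn = tn, fp = fp))
  expect_equal(got$tp + got$fn, sum(outcomes))
  expect_equal(got$tn + got$fp, sum(1 - outcomes))
})

test_that("calibration bins match a direct per-bin recomputation", {
  set.seed(12)
  risks <- runif(100)
  outcomes <- rbinom(100, 1, risks)
  bins <- calibration_plot_data(risks, outcomes, bins = 5)
  expect_equal(sum(bins$n), 100)
  breaks <- unique(quantile(risks, seq(0, 1, length.out = 6)))
  ids <- as.integer(cut(risks, breaks, include.lowest = TRUE))
  expect_equal(bins$mean_pred,
               as.vector(tapply(risks, ids, mean)), ignore_attr = TRUE)
  expect_equal(bins$obs_prop,
               as.vector(tapply(outcomes, ids, mean)), ignore_attr = TRUE)
  expect_true(all(bins$obs_prop >= 0 & bins$obs_prop <= 1))
})

test_that("constant risks collapse to a single calibration bin", {
  bins <- calibration_plot_data(rep(0.2, 50), rbinom(50, 1, 0.2), bins = 10)
  expect_equal(nrow(bins), 1)
  expect_equal(bins$n, 50)
})

test_that("a well-calibrated simulation sits on the diagonal", {
  set.seed(31)
  risks <- runif(20000, 0.05, 0.6)
  outcomes <- rbinom(length(risks), 1, risks)
  bins <- calibration_plot_data(risks, outcomes, bins = 10)
  expect_true(all(abs(bins$mean_pred - bins$obs_prop) < 0.04))
})
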