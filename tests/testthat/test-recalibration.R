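test_that("strategy A pools derivation intercepts and leaves betas untouched", {
  m <- quiet_model()
  same <- tibble::tibble(estimate = rep(-1.2, 3), variance = rep(0.01, 3))
  rec <- recalibrate(small_cohort(), m, "a", derivation_intercepts = same)
  expect_equal(rec$models$global$intercept, -1.2)

  di <- tibble::tibble(estimate = c(-1.0, -1.4, -1.2),
                       variance = rep(0.01, 3))
  rec2 <- recalibrate(small_cohort(), m, "a", derivation_intercepts = di)
  oracle <- reml_grid_oracle(di$estimate, di$variance)
  expect_equal(rec2$models$global$intercept, oracle$mu, tolerance = 1e-4)
  expect_identical(rec2$models$global$tumour_coeffs, m$tumour_coeffs)
  expect_identical(rec2$models$global$temp_coeff, m$temp_coeff)

  one <- tibble::tibble(estimate = -1.1, se = 0.2)
  expect_warning(
    rec3 <- recalibrate(small_cohort(), m, "a", derivation_intercepts = one),
    class = "picnicc_recal_single_intercept"
  )
  expect_equal(rec3$models$global$intercept, -1.1)
  expect_error(recalibrate(small_cohort(), m, "a"),
               class = "picnicc_recal_error")
})

test_that("strategy B drives every study's E/O to exactly 1", {
  m <- quiet_model()
  coh <- small_cohort()
  rec <- suppressMessages(recalibrate(coh, m, "b"))
  rescored <- apply_recalibration(coh, rec)
  for (sid in unique(rescored$study_id)) {
    d <- rescored[rescored$study_id == sid & !is.na(rescored$lp), ]
    expect_equal(sum(d$risk) / sum(d$mdi), 1, tolerance = 1e-6)
  }
  # betas unchanged
  expect_identical(rec$models[[1]]$tumour_coeffs, m$tumour_coeffs)
})

test_that("strategy B matches an independent bisection oracle", {
  m <- quiet_model()
  coh <- small_cohort()
  rec <- suppressMessages(recalibrate(coh, m, "b"))
  scored <- suppressWarnings(suppressMessages(score_episodes(coh, m)))
  for (sid in rec$adjustments$study_id[1:3]) {
    d <- scored[scored$study_id == sid & !is.na(scored$lp), ]
    lp0 <- d$lp - m$intercept
    rate <- mean(d$mdi)
    lo <- -30; hi <- 30
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (mean(plogis(mid + lp0)) < rate) lo <- mid else hi <- mid
    }
    expect_equal(
      rec$adjustments$intercept[rec$adjustments$study_id == sid],
      (lo + hi) / 2, tolerance = 1e-6
    )
  }
})

test_that("the shortcut intercept tracks the exact root when LP spread is modest", {
  m <- quiet_model()
  # leukaemia-only case mix avoids the extreme tumour coefficients, so the
  # LP distribution is tight and the crude logit(rate) - mean(LP0) update
  # should be close to the exact prevalence-matching root
  cfg <- synthetic_config(
    study_ids = "tight", n_episodes = 400L, n_patients = 200L,
    mdi_targets = 0.25, group_mix = c(1, 0, 0, 0), seed = 15
  )
  coh <- generate_cohorts(cfg, model = m)
  exact <- suppressMessages(recalibrate(coh, m, "b"))
  shortcut <- suppressMessages(recalibrate(coh, m, "b",
                                           b_method = "shortcut"))
  gap <- abs(exact$adjustments$intercept - shortcut$adjustments$intercept)
  expect_lt(gap, 0.3)
  expect_gt(gap, 1e-8) # genuinely different solvers

  # with the full case mix (heavy left LP tail) the shortcut is visibly
  # cruder, which is why the exact root is the default
  wide_exact <- suppressMessages(recalibrate(small_cohort(), m, "b"))
  wide_short <- suppressMessages(
    recalibrate(small_cohort(), m, "b", b_method = "shortcut")
  )
  expect_gt(
    max(abs(wide_exact$adjustments$intercept -
              wide_short$adjustments$intercept)),
    gap
  )
})

test_that("a perfectly calibrated cohort is a fixed point of strategy B", {
  m <- quiet_model()
  coh <- generate_cohorts(correct_spec_config(n = 8000, seed = 33), model = m)
  rec <- suppressMessages(recalibrate(coh, m, "b"))
  expect_equal(rec$adjustments$intercept, m$intercept, tolerance = 0.1)
})

test_that("strategy C interpolates intercepts from the meta-regression line", {
  m <- quiet_model()
  coh <- small_cohort()
  rec <- suppressWarnings(suppressMessages(recalibrate(coh, m, "c")))
  expect_equal(nrow(rec$adjustments), 7)
  reg <- rec$meta_regression
  expect_equal(
    rec$adjustments$intercept,
    reg$intercept + reg$slope * rec$adjustments$proportion,
    tolerance = 1e-10
  )
  expect_identical(rec$models[[1]]$hb_coeff, m$hb_coeff)
})

test_that("strategies B and C nearly coincide on the default simulation", {
  m <- quiet_model()
  coh <- default_cohort()
  b <- suppressMessages(recalibrate(coh, m, "b"))
  c_ <- suppressWarnings(suppressMessages(recalibrate(coh, m, "c")))
  merged <- merge(b$adjustments, c_$adjustments, by = "study_id")
  expect_lt(mean(abs(merged$intercept.x - merged$intercept.y)), 0.3)
})

test_that("strategy D rescales betas by the study slope and pools the intercept", {
  m <- quiet_model()
  coh <- default_cohort()
  rec <- suppressWarnings(suppressMessages(recalibrate(coh, m, "d")))
  adj <- rec$adjustments
  for (sid in adj$study_id) {
    mult <- adj$slope_multiplier[adj$study_id == sid]
    ms <- rec$models[[sid]]
    expect_equal(ms$temp_coeff, m$temp_coeff * mult)
    expect_equal(ms$tumour_coeffs, m$tumour_coeffs * mult)
    expect_equal(ms$intercept, rec$shared_intercept + mult * m$intercept)
  }
  # shared intercept is the REML pool of the per-study joint-fit intercepts
  fits <- rec$slope_fits[is.finite(rec$slope_fits$a), ]
  oracle <- reml_grid_oracle(fits$a, fits$a_se^2)
  expect_equal(rec$shared_intercept, oracle$mu, tolerance = 1e-3)
})

test_that("refitting after strategy D returns slope 1 and preserves ranking", {
  m <- quiet_model()
  coh <- default_cohort()
  rec <- suppressWarnings(suppressMessages(recalibrate(coh, m, "d")))
  rescored <- apply_recalibration(coh, rec)
  scored0 <- suppressWarnings(suppressMessages(score_episodes(coh, m)))
  for (sid in rec$adjustments$study_id) {
    d1 <- rescored[rescored$study_id == sid & !is.na(rescored$lp), ]
    refit <- calibration_fit(d1$lp, d1$mdi)
    expect_equal(refit$slope, 1, tolerance = 1e-4)
    mult <- rec$adjustments$slope_multiplier[rec$adjustments$study_id == sid]
    if (mult > 0) {
      d0 <- scored0[scored0$study_id == sid & !is.na(scored0$lp), ]
      expect_equal(
        c_statistic(d1$risk, d1$mdi),
        c_statistic(d0$risk, d0$mdi),
        tolerance = 1e-12
      )
    }
  }
})

test_that("re-estimated coefficients recover the generator at scale", {
  m <- quiet_model()
  coh <- generate_cohorts(correct_spec_config(n = 20000, seed = 44),
                          model = m)
  cmp <- suppressWarnings(reestimate_coefficients(coh, m))
  expect_equal(nrow(cmp), 22)
  cont <- cmp[cmp$n_episodes == max(cmp$n_episodes), ]
  expect_equal(nrow(cont), 5)
  z <- abs(cont$validation_estimate - cont$derivation_estimate) /
    cont$validation_se
  expect_true(all(z < 3))
  aml <- cmp[cmp$term == "Acute myeloid leukaemia", ]
  expect_true(abs(aml$validation_estimate - 0.65) < 3 * aml$validation_se)
  # episode counts column tallies the input categories exactly
  cc <- complete_cases(coh, quiet = TRUE)
  for (term in c("Acute myeloid leukaemia", "Wilms tumour", "Osteosarcoma")) {
    expect_equal(
      cmp$n_episodes[cmp$term == term],
      sum(cc$tumour_type == term)
    )
  }
})

test_that("separated categories are reported as-is with huge SEs", {
  m <- quiet_model()
  set.seed(61)
  coh <- generate_cohorts(correct_spec_config(n = 1500, seed = 61), model = m)
  # force complete separation: a small category with only events
  idx <- which(coh$tumour_type == "Hepatoblastoma")
  if (length(idx) < 2) idx <- sample(nrow(coh), 4)
  coh$tumour_type[idx] <- "Hepatoblastoma"
  coh$mdi[idx] <- 1
  cmp <- suppressWarnings(reestimate_coefficients(coh, m))
  hep <- cmp[cmp$term == "Hepatoblastoma", ]
  expect_equal(hep$flag, "separation")
  expect_gt(hep$validation_se, 50)
  # an unpopulated category is reported absent
  gone <- coh[coh$tumour_type != "Retinoblastoma", ]
  cmp2 <- suppressWarnings(reestimate_coefficients(gone, m))
  ret <- cmp2[cmp2$term == "Retinoblastoma", ]
  expect_equal(ret$flag, "absent")
  expect_true(is.na(ret$validation_estimate))
  expect_equal(ret$n_episodes, 0L)
})
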