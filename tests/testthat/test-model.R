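test_that("packaged default carries the published derivation coefficients", {
  m <- quiet_model()
  expect_equal(m$tumour_coeffs[["Acute myeloid leukaemia"]], 0.65)
  expect_equal(m$tumour_coeffs[["Low-grade brain tumour"]], -14.16)
  expect_equal(m$tumour_coeffs[["Langerhans cell histiocytosis"]], -14.1)
  expect_equal(m$temp_coeff, 0.57)
  expect_equal(m$unwell_coeff, 0.79)
  expect_equal(m$hb_coeff, 0.18)
  expect_equal(m$ln_wcc_coeff, -0.3)
  expect_equal(m$ln_amc_coeff, -0.21)
  expect_length(tumour_categories(m), 18)
  expect_equal(unname(m$tumour_coeffs[m$reference]), 0)
  expect_false(m$intercept_published)
})

test_that("placeholder intercept is announced, explicit intercept is not", {
  rlang::reset_message_verbosity("picnicc_placeholder_intercept")
  expect_message(picnicc_model(), class = "picnicc_placeholder_intercept")
  expect_no_message(picnicc_model(intercept = -4))
})

test_that("linear predictor is additive term by term", {
  m <- quiet_model(intercept = -4)
  base <- tibble::tibble(
    study_id = "s", tumour_type = m$reference, temperature = 37,
    severely_unwell = 0, haemoglobin = 10, wcc = 1.5, amc = 0.2, mdi = 0
  )
  lp_of <- function(d) score_episodes(d, m)$lp

  aml <- dplyr::mutate(base, tumour_type = "Acute myeloid leukaemia")
  expect_equal(lp_of(aml) - lp_of(base), 0.65)

  hot <- dplyr::mutate(base, temperature = 39)
  expect_equal(lp_of(hot) - lp_of(base), 2 * 0.57)

  unwell <- dplyr::mutate(base, severely_unwell = 1)
  expect_equal(lp_of(unwell) - lp_of(base), 0.79)

  anaemic <- dplyr::mutate(base, haemoglobin = 7)
  expect_equal(lp_of(anaemic) - lp_of(base), 0.18 * (7 - 10))

  wcc2 <- dplyr::mutate(base, wcc = 3)
  expect_equal(lp_of(wcc2) - lp_of(base), -0.3 * (log(3) - log(1.5)))

  amc2 <- dplyr::mutate(base, amc = 0.4)
  expect_equal(lp_of(amc2) - lp_of(base), -0.21 * (log(0.4) - log(0.2)))
})

test_that("all covariate terms vanish at the reference point", {
  m <- quiet_model(intercept = -2.5)
  d <- tibble::tibble(
    tumour_type = m$reference, temperature = 37, severely_unwell = 0,
    haemoglobin = 0, wcc = 1, amc = 1
  )
  expect_equal(score_episodes(d, m)$lp, -2.5)
})

test_that("a full episode matches a hand-summed linear predictor", {
  m <- quiet_model(intercept = -4.26)
  d <- tibble::tibble(
    tumour_type = "Acute myeloid leukaemia", temperature = 39.0,
    severely_unwell = 1, haemoglobin = 10, wcc = 0.8, amc = 0.1
  )
  by_hand <- -4.26 + 0.65 + 0.57 * (39 - 37) + 0.79 * 1 + 0.18 * 10 +
    (-0.3) * log(0.8) + (-0.21) * log(0.1)
  expect_equal(score_episodes(d, m)$lp, by_hand, tolerance = 1e-12)
})

test_that("predicted risk is in (0,1), monotone in LP, and tiny for the extreme category", {
  m <- quiet_model(intercept = -4.26)
  scored <- suppressWarnings(suppressMessages(
    score_episodes(small_cohort(), m)
  ))
  scored <- scored[!is.na(scored$lp), ]
  expect_true(all(scored$risk > 0 & scored$risk < 1))
  ord <- order(scored$lp)
  expect_true(all(diff(scored$risk[ord]) >= 0))
  lg <- tibble::tibble(
    tumour_type = "Low-grade brain tumour", temperature = 38.5,
    severely_unwell = 0, haemoglobin = 9, wcc = 1, amc = 0.1
  )
  expect_lt(score_episodes(lg, m)$risk, 1e-5)
})

test_that("low-risk classification includes the boundary", {
  expect_true(classify_low_risk(0.10, 0.10))
  expect_false(classify_low_risk(0.100001, 0.10))
  expect_true(classify_low_risk(0, 0.10))
  expect_error(classify_low_risk(0.5, 0))
  expect_error(classify_low_risk(0.5, 1))
})

test_that("zero counts are floored with a warning; negative counts error", {
  m <- quiet_model(intercept = -4)
  d <- tibble::tibble(
    tumour_type = m$reference, temperature = 38, severely_unwell = 0,
    haemoglobin = 9, wcc = 0, amc = 0.1
  )
  expect_warning(s <- score_episodes(d, m), class = "picnicc_zero_count")
  expect_true(is.finite(s$lp))
  by_hand <- -4 + 0.57 + 0.18 * 9 - 0.3 * log(0.005) - 0.21 * log(0.1)
  expect_equal(s$lp, by_hand)
  d$wcc <- -1
  expect_error(score_episodes(d, m), class = "picnicc_domain_error")
})

test_that("scoring is order-independent and idempotent", {
  m <- quiet_model(intercept = -4.26)
  d <- toy_episodes()
  s1 <- score_episodes(d, m)
  perm <- c(4, 2, 6, 1, 5, 3)
  s2 <- score_episodes(d[perm, ], m)
  expect_equal(s2$lp, s1$lp[perm])
  expect_equal(score_episodes(s1, m)$lp, s1$lp)
})

test_that("model specs round-trip through YAML and JSON", {
  m <- quiet_model(intercept = -4.1, name = "roundtrip")
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_model_spec(m, path)
    m2 <- load_model_spec(path)
    expect_equal(m2$intercept, m$intercept)
    expect_equal(m2$tumour_coeffs, m$tumour_coeffs)
    expect_equal(m2$temp_coeff, m$temp_coeff)
    unlink(path)
  }
})

test_that("spec loading errors name the offending field", {
  m <- quiet_model(intercept = -4.1)
  path <- tempfile(fileext = ".yaml")
  write_model_spec(m, path)
  spec <- yaml::read_yaml(path)
  unlink(path)

  no_hb <- spec[setdiff(names(spec), "Haemoglobin (per g/dL)")]
  expect_error(load_model_spec(no_hb), "hb_coeff",
               class = "picnicc_spec_error")

  bad_cat <- spec
  bad_cat[["Imaginary tumour"]] <- 1
  expect_error(load_model_spec(bad_cat), "Imaginary tumour",
               class = "picnicc_spec_error")

  non_finite <- spec
  non_finite[["intercept"]] <- "not-a-number"
  expect_error(load_model_spec(non_finite), "intercept",
               class = "picnicc_spec_error")
})

test_that("model constructor rejects invalid coefficient sets", {
  expect_error(
    picnicc_model(intercept = 0, tumour_coeffs = c(0.2, 0.3)),
    "named"
  )
  expect_error(
    picnicc_model(intercept = 0,
                  tumour_coeffs = c("Sarcoma" = Inf)),
    class = "picnicc_model_error"
  )
  expect_error(
    suppressMessages(picnicc_model(temp_coeff = NA_real_)),
    class = "picnicc_model_error"
  )
})
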