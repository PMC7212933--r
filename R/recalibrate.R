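# Recalibration of the model to new validation data: four strategies
# (A: pooled derivation intercept; B: intercept matched to the observed
# event rate; C: intercept interpolated from meta-regression on the event
# rate; D: betas rescaled by the study calibration slope with a shared
# pooled intercept), plus exploratory re-estimation of the coefficients.

#' Recalibrate the model on validation cohorts
#'
#' Implements four recalibration strategies. The first three update only
#' the intercept and leave every beta coefficient untouched:
#'
#' * **A** - a random-effects (REML) weighted average of study-level
#'   intercepts from the derivation data (supplied as
#'   `derivation_intercepts`, since they are not recoverable from the
#'   validation data); one global recalibrated model.
#' * **B** - per study, the intercept is set so the mean predicted risk
#'   equals the observed MDI proportion, by bracketed root finding on the
#'   monotone mean-risk function (tolerance 1e-10); this makes each
#'   study's E/O exactly 1 by construction. `b_method = "shortcut"` uses
#'   the cruder `logit(rate) - mean(LP0)` approximation instead.
#' * **C** - per-study calibration-in-the-large intercepts are regressed
#'   on the study MDI proportion by random-effects meta-regression
#'   ([meta_regress()]); each study receives the interpolated intercept
#'   at its own proportion.
#' * **D** - per study, every beta coefficient is multiplied by the
#'   study's observed calibration slope, and all studies share the
#'   REML-pooled calibration intercept (`d_intercept = "unweighted"` for
#'   a plain mean; `d_slope = "pooled"` rescales all studies by the
#'   pooled slope instead of per-study slopes). Rescaling by a positive
#'   slope preserves the risk ranking, so the C-statistic is unchanged
#'   and the refitted calibration slope is 1 by design.
#'
#' @param data Episode data (all validation studies, `study_id` column).
#' @param model The [picnicc_model()] being recalibrated.
#' @param strategy One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param derivation_intercepts For strategy A: data frame with columns
#'   `estimate` and `variance` (or `se`), one row per derivation study.
#' @param b_method Strategy-B solver: exact `"root"` (default) or
#'   `"shortcut"`.
#' @param d_slope Strategy-D slope source: `"per_study"` (default) or
#'   `"pooled"`.
#' @param d_intercept Strategy-D shared intercept: `"reml"`-pooled
#'   (default) or `"unweighted"` mean.
#' @return A `picnicc_recalibration` object: `adjustments` tibble
#'   (per-study intercepts/slope multipliers), recalibrated model(s), and
#'   provenance notes. Use [apply_recalibration()] to score data with it.
#' @examples
#' cohort <- generate_cohorts(synthetic_config(seed = 1))
#' rec <- recalibrate(cohort, picnicc_model(intercept = -4.3), "b")
#' rec$adjustments
#' @export
recalibrate <- function(data, model = picnicc_model(),
                        strategy = c("a", "b", "c", "d"),
                        derivation_intercepts = NULL,
                        b_method = c("root", "shortcut"),
                        d_slope = c("per_study", "pooled"),
                        d_intercept = c("reml", "unweighted")) {
  strategy <- match.arg(strategy)
  b_method <- match.arg(b_method)
  d_slope <- match.arg(d_slope)
  d_intercept <- match.arg(d_intercept)
  notes <- character()
  if (strategy == "a") {
    return(recalibrate_a(model, derivation_intercepts))
  }
  scored <- suppressMessages(score_episodes(data, model = model))
  per_study <- scored %>%
    group_by(.data$study_id) %>%
    group_split() %>%
    map(function(d) suppressMessages(complete_cases(d, quiet = TRUE))) %>%
    map(function(d) filter(d, !is.na(.data$lp)))
  sids <- map(per_study, function(d) unique(d$study_id)[1])
  keep <- lengths(sids) == 1
  per_study <- per_study[keep]
  sids <- unlist(sids[keep])

  switch(strategy,
    b = recalibrate_b(model, per_study, sids, b_method),
    c = recalibrate_c(model, per_study, sids),
    d = recalibrate_d(model, per_study, sids, d_slope, d_intercept)
  )
}

new_recalibration <- function(strategy, scope, base_model, adjustments,
                              models, notes = character()) {
  structure(
    list(
      strategy = strategy, scope = scope, base_model = base_model,
      adjustments = adjustments, models = models, notes = notes
    ),
    class = "picnicc_recalibration"
  )
}

#' @export
print.picnicc_recalibration <- function(x, ...) {
  cat("<picnicc_recalibration> strategy ", toupper(x$strategy),
      " (", x$scope, ")\n", sep = "")
  print(x$adjustments)
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}

with_intercept <- function(model, intercept, name_suffix) {
  out <- model
  out$intercept <- intercept
  out$intercept_published <- FALSE
  out$name <- paste0(model$name, " + ", name_suffix)
  out
}

recalibrate_a <- function(model, derivation_intercepts) {
  di <- derivation_intercepts
  if (is.null(di)) {
    abort(
      "Strategy A needs `derivation_intercepts` (estimate + variance/se per derivation study).",
      class = "picnicc_recal_error"
    )
  }
  di <- as_tibble(di)
  if (!"variance" %in% names(di) && "se" %in% names(di)) {
    di$variance <- di$se^2
  }
  if (!all(c("estimate", "variance") %in% names(di))) {
    abort("`derivation_intercepts` needs columns `estimate` and `variance` (or `se`).",
          class = "picnicc_recal_error")
  }
  notes <- character()
  if (nrow(di) == 1) {
    warn("Single derivation intercept supplied; used directly.",
         class = "picnicc_recal_single_intercept")
    pooled_int <- di$estimate[1]
    notes <- "single derivation intercept used directly"
  } else {
    pooled <- pool_metric(
      di$estimate, di$variance,
      labels = if ("study_id" %in% names(di)) di$study_id
               else paste0("derivation_", seq_len(nrow(di))),
      metric = "derivation_intercept", scale = "identity"
    )
    pooled_int <- pooled$estimate
  }
  adjustments <- tibble(
    study_id = "(all)", intercept = pooled_int, slope_multiplier = 1
  )
  new_recalibration(
    "a", "global", model, adjustments,
    models = list(global = with_intercept(model, pooled_int, "strategy A")),
    notes = notes
  )
}

# Exact prevalence-matching intercept: solve mean(plogis(a + lp0)) = rate.
solve_intercept_for_rate <- function(lp0, rate, tol = 1e-10) {
  uniroot(
    function(a) mean(plogis(a + lp0)) - rate,
    interval = c(-40, 40), tol = tol
  )$root
}

recalibrate_b <- function(model, per_study, sids, b_method) {
  notes <- character()
  rows <- list()
  models <- list()
  for (i in seq_along(per_study)) {
    d <- per_study[[i]]
    sid <- sids[i]
    rate <- mean(d$mdi)
    lp0 <- d$lp - model$intercept
    if (nrow(d) == 0 || rate == 0 || rate == 1) {
      warn(
        paste0("Study ", sid,
               ": no finite prevalence-matching intercept (event rate ",
               rate, "); flagged."),
        class = "picnicc_recal_flagged"
      )
      rows[[i]] <- tibble(study_id = sid, intercept = NA_real_,
                          slope_multiplier = 1)
      next
    }
    a_star <- if (b_method == "root") {
      solve_intercept_for_rate(lp0, rate)
    } else {
      qlogis(rate) - mean(lp0)
    }
    rows[[i]] <- tibble(study_id = sid, intercept = a_star,
                        slope_multiplier = 1)
    models[[sid]] <- with_intercept(model, a_star, paste0("strategy B [", sid, "]"))
  }
  if (b_method == "shortcut") {
    notes <- "shortcut intercept (logit rate minus mean intercept-free LP)"
  }
  new_recalibration("b", "per_study", model, bind_rows(rows), models, notes)
}

# Per-study calibration-in-the-large intercepts on the absolute scale
# (original intercept plus the offset-fit update) with their SEs.
study_citl_intercepts <- function(model, per_study, sids) {
  map2(per_study, sids, function(d, sid) {
    if (nrow(d) == 0 || length(unique(d$mdi)) < 2) {
      return(tibble(study_id = sid, intercept = NA_real_, se = NA_real_,
                    proportion = if (nrow(d)) mean(d$mdi) else NA_real_))
    }
    ci <- citl_fit(d$lp, d$mdi)
    tibble(
      study_id = sid,
      intercept = model$intercept + ci[1],
      se = ci[2],
      proportion = mean(d$mdi)
    )
  }) %>% bind_rows()
}

recalibrate_c <- function(model, per_study, sids) {
  if (length(per_study) < 3) {
    abort("Strategy C needs at least 3 studies.", class = "picnicc_recal_error")
  }
  est <- study_citl_intercepts(model, per_study, sids)
  reg <- meta_regress(
    est$intercept, est$se^2, est$proportion, labels = est$study_id
  )
  interpolated <- reg$interpolate(est$proportion)
  adjustments <- tibble(
    study_id = est$study_id,
    intercept = interpolated,
    slope_multiplier = 1,
    proportion = est$proportion
  )
  models <- setNames(
    map2(
      adjustments$intercept, adjustments$study_id,
      function(a, sid) with_intercept(model, a, paste0("strategy C [", sid, "]"))
    ),
    adjustments$study_id
  )
  out <- new_recalibration("c", "per_study", model, adjustments, models)
  out$meta_regression <- reg
  out
}

recalibrate_d <- function(model, per_study, sids, d_slope, d_intercept) {
  fits <- map2(per_study, sids, function(d, sid) {
    cal <- suppressWarnings(calibration_fit(d$lp, d$mdi))
    tibble(study_id = sid, a = cal$intercept, a_se = cal$intercept_se,
           b = cal$slope, b_se = cal$slope_se)
  }) %>% bind_rows()
  usable <- filter(fits, is.finite(.data$a), is.finite(.data$b))
  if (nrow(usable) < 2) {
    abort("Strategy D needs estimable calibration slopes in at least 2 studies.",
          class = "picnicc_recal_error")
  }
  notes <- character()
  if (any(usable$b < 0)) {
    warn(
      "Negative estimated calibration slope: the recalibrated model inverts the risk ranking (discrimination is not preserved).",
      class = "picnicc_recal_negative_slope"
    )
    notes <- c(notes, "negative slope in at least one study")
  }
  shared_a <- if (d_intercept == "reml") {
    pool_metric(usable$a, usable$a_se^2, labels = usable$study_id,
                metric = "calib_intercept", scale = "identity")$estimate
  } else {
    mean(usable$a)
  }
  slope_use <- if (d_slope == "pooled") {
    pooled_b <- pool_metric(usable$b, usable$b_se^2, labels = usable$study_id,
                            metric = "calib_slope", scale = "identity")$estimate
    rep(pooled_b, nrow(usable))
  } else {
    usable$b
  }
  adjustments <- tibble(
    study_id = usable$study_id,
    intercept = shared_a + slope_use * model$intercept,
    slope_multiplier = slope_use
  )
  models <- setNames(
    pmap(adjustments, function(study_id, intercept, slope_multiplier) {
      out <- model
      out$intercept <- intercept
      out$intercept_published <- FALSE
      out$tumour_coeffs <- model$tumour_coeffs * slope_multiplier
      out$temp_coeff <- model$temp_coeff * slope_multiplier
      out$unwell_coeff <- model$unwell_coeff * slope_multiplier
      out$hb_coeff <- model$hb_coeff * slope_multiplier
      out$ln_wcc_coeff <- model$ln_wcc_coeff * slope_multiplier
      out$ln_amc_coeff <- model$ln_amc_coeff * slope_multiplier
      out$name <- paste0(model$name, " + strategy D [", study_id, "]")
      out
    }),
    adjustments$study_id
  )
  out <- new_recalibration("d", "per_study", model, adjustments, models, notes)
  out$shared_intercept <- shared_a
  out$slope_fits <- fits
  out
}

#' Score episodes with a recalibrated model
#'
#' Re-scores episode data using the study-specific (or global)
#' recalibrated model from [recalibrate()], replacing the `lp`, `risk`
#' and `low_risk` columns.
#'
#' @param data Episode data covering only studies present in the
#'   recalibration (global strategies cover every study).
#' @param recal A `picnicc_recalibration`.
#' @param threshold Risk threshold for the low-risk call.
#' @return Scored tibble.
#' @export
apply_recalibration <- function(data, recal, threshold = 0.10) {
  stopifnot(inherits(recal, "picnicc_recalibration"))
  data <- as_tibble(data)
  if (recal$scope == "global") {
    return(suppressMessages(
      score_episodes(data, model = recal$models$global, threshold = threshold)
    ))
  }
  unseen <- setdiff(unique(data$study_id), names(recal$models))
  if (length(unseen) > 0) {
    abort(
      paste0(
        "No recalibrated model for study(ies): ",
        paste(unseen, collapse = ", ")
      ),
      class = "picnicc_recal_error"
    )
  }
  data %>%
    group_by(.data$study_id) %>%
    group_split() %>%
    map(function(d) {
      m <- recal$models[[unique(d$study_id)[1]]]
      suppressMessages(score_episodes(d, model = m, threshold = threshold))
    }) %>%
    bind_rows()
}

#' Re-estimate the model coefficients in validation data
#'
#' Exploratory analysis: fits the full model covariate set (tumour type,
#' temperature above 37, severely unwell, haemoglobin, log white cell and
#' monocyte counts) to MDI by maximum-likelihood logistic regression on
#' the stacked complete cases of all validation studies, and tabulates
#' the re-estimated coefficients next to the derivation values. Empty
#' tumour categories are reported as absent; separated categories (a
#' cell with no events or all events, typically 2-5 episodes) keep their
#' extreme estimate and huge SE, flagged as separation.
#'
#' @param data Episode data (all studies).
#' @param model The reference [picnicc_model()] (supplies the category
#'   list and derivation values).
#' @return Tibble: `term`, `derivation_estimate`, `derivation_se`,
#'   `validation_estimate`, `validation_se`, `n_episodes`, `flag`.
#' @export
reestimate_coefficients <- function(data, model = picnicc_model()) {
  cohort <- suppressMessages(complete_cases(as_tibble(data), quiet = TRUE))
  if (nrow(cohort) == 0) {
    abort("No complete cases to re-estimate from.",
          class = "picnicc_recal_error")
  }
  cats <- tumour_categories(model)
  cohort$tumour_type <- factor(
    cohort$tumour_type,
    levels = c(model$reference, setdiff(cats, model$reference))
  )
  cohort$tumour_type <- droplevels(cohort$tumour_type)
  fit <- suppressWarnings(glm(
    mdi ~ tumour_type + I(temperature - 37) + severely_unwell +
      haemoglobin + log(wcc) + log(amc),
    data = cohort, family = binomial()
  ))
  sm <- summary(fit)$coefficients
  counts <- count(cohort, .data$tumour_type)
  n_total <- nrow(cohort)
  tumour_terms <- setdiff(cats, model$reference)
  term_rows <- lapply(tumour_terms, function(tt) {
    coef_name <- paste0("tumour_type", tt)
    present <- coef_name %in% rownames(sm)
    n_cat <- counts$n[match(tt, as.character(counts$tumour_type))]
    n_cat <- if (is.na(n_cat)) 0L else n_cat
    est <- if (present) sm[coef_name, "Estimate"] else NA_real_
    se <- if (present) sm[coef_name, "Std. Error"] else NA_real_
    flag <- if (!present || n_cat == 0) {
      "absent"
    } else if (is.finite(se) && (se > 10 || abs(est) > 10)) {
      "separation"
    } else {
      NA_character_
    }
    tibble(
      term = tt,
      derivation_estimate = unname(PICNICC_TUMOUR_COEFFS[tt]),
      derivation_se = unname(PICNICC_TUMOUR_SES[tt]),
      validation_estimate = est,
      validation_se = se,
      n_episodes = n_cat,
      flag = flag
    )
  })
  cont_names <- c(
    temp_coeff = "I(temperature - 37)",
    unwell_coeff = "severely_unwell",
    hb_coeff = "haemoglobin",
    ln_wcc_coeff = "log(wcc)",
    ln_amc_coeff = "log(amc)"
  )
  cont_rows <- lapply(names(cont_names), function(key) {
    coef_name <- cont_names[[key]]
    tibble(
      term = unname(PICNICC_TERM_LABELS[key]),
      derivation_estimate = unname(PICNICC_CONTINUOUS_COEFFS[key]),
      derivation_se = unname(PICNICC_CONTINUOUS_SES[key]),
      validation_estimate = sm[coef_name, "Estimate"],
      validation_se = sm[coef_name, "Std. Error"],
      n_episodes = n_total,
      flag = NA_character_
    )
  })
  bind_rows(c(term_rows, cont_rows))
}
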