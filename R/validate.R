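# Per-study external validation: complete-case filtering, discrimination,
# calibration, threshold classification and uncertainty, one row per study.

study_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
}

#' Validate model performance study by study
#'
#' For each study (grouped by `study_id`) restricts to complete cases and
#' computes the discrimination and calibration of the model's predictions:
#' C-statistic, E/O ratio, calibration slope and intercepts, and the 2x2
#' classification counts at the risk threshold. Standard errors are
#' computed on the scales used for pooling (logit for C, natural log for
#' E/O, identity for the slope), by default from a per-study bootstrap
#' with replacement; `se_method = "analytic"` uses closed-form SEs
#' (Hanley-McNeil for C, a delta-method binomial SE for ln E/O, the
#' model-based SE for the slope), which is faster for simulation studies.
#'
#' Studies where a metric is undefined (a single outcome class, zero
#' events, constant linear predictor) stay in the output with `NA` for
#' that metric and a note; fully unusable studies are listed in the
#' `"exclusions"` attribute. Per-study calibration-plot bins are attached
#' as the `"calibration"` attribute.
#'
#' @param data Episode data. If `model` is supplied the data is scored
#'   first; if `model = NULL` the data must already carry `lp` and `risk`
#'   columns (e.g. after [apply_recalibration()]).
#' @param model A [picnicc_model()], or `NULL` to use existing scores.
#' @param threshold Risk threshold for the low/high-risk dichotomy.
#' @param draws Bootstrap draws per study (validation default 2000).
#' @param seed Integer seed; per-study bootstrap seeds are derived from it
#'   deterministically.
#' @param se_method `"bootstrap"` (default) or `"analytic"`.
#' @param bins Calibration-plot bins per study.
#' @return A `picnicc_performance` tibble, one row per study.
#' @examples
#' cohort <- generate_cohorts(synthetic_config(seed = 1))
#' perf <- validate_studies(cohort, picnicc_model(intercept = -4.3),
#'                          draws = 200, seed = 1)
#' perf[, c("study_id", "n", "n_events", "c_stat", "eo", "slope")]
#' @export
validate_studies <- function(data, model = picnicc_model(), threshold = 0.10,
                             draws = 2000, seed = 1,
                             se_method = c("bootstrap", "analytic"),
                             bins = 10) {
  se_method <- match.arg(se_method)
  data <- as_tibble(data)
  if (!is.null(model)) {
    data <- suppressMessages(
      score_episodes(data, model = model, threshold = threshold)
    )
  }
  if (!all(c("lp", "risk") %in% names(data))) {
    abort("Data must carry `lp` and `risk` columns when `model = NULL`.")
  }
  if (!"study_id" %in% names(data)) {
    abort("Episode data must have a `study_id` column.")
  }
  studies <- unique(data$study_id)
  rows <- vector("list", length(studies))
  calib <- list()
  exclusions <- list()
  for (i in seq_along(studies)) {
    sid <- studies[[i]]
    cohort <- suppressMessages(
      complete_cases(filter(data, .data$study_id == sid), quiet = TRUE)
    )
    cohort <- filter(cohort, !is.na(.data$lp))
    res <- validate_one_study(
      cohort,
      study_id = sid, threshold = threshold, draws = draws,
      seed = study_seed(seed, i), se_method = se_method, bins = bins
    )
    rows[[i]] <- res$row
    if (!is.null(res$calibration)) calib[[length(calib) + 1]] <- res$calibration
    if (!is.null(res$exclusion)) {
      exclusions[[length(exclusions) + 1]] <- res$exclusion
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("picnicc_performance", class(out))
  attr(out, "calibration") <- if (length(calib)) bind_rows(calib) else
    tibble(study_id = character(), bin = integer(), mean_pred = double(),
           obs_prop = double(), n = integer())
  attr(out, "exclusions") <- if (length(exclusions)) bind_rows(exclusions) else
    tibble(study_id = character(), reason = character())
  attr(out, "threshold") <- threshold
  attr(out, "se_method") <- se_method
  out
}

validate_one_study <- function(cohort, study_id, threshold, draws, seed,
                               se_method, bins) {
  n <- nrow(cohort)
  base <- tibble(
    study_id = study_id, n = n,
    n_events = if (n > 0) sum(cohort$mdi) else 0L,
    c_stat = NA_real_, c_se_logit = NA_real_,
    c_ci_lower = NA_real_, c_ci_upper = NA_real_,
    eo = NA_real_, log_eo_se = NA_real_,
    eo_ci_lower = NA_real_, eo_ci_upper = NA_real_,
    slope = NA_real_, slope_se = NA_real_,
    slope_ci_lower = NA_real_, slope_ci_upper = NA_real_,
    calib_intercept = NA_real_, calib_intercept_se = NA_real_,
    citl = NA_real_, citl_se = NA_real_,
    tp = NA_integer_, fn = NA_integer_, tn = NA_integer_, fp = NA_integer_,
    sens = NA_real_, spec = NA_real_, low_risk_frac = NA_real_,
    boot_draws = if (se_method == "bootstrap") as.integer(draws) else NA_integer_,
    usable = FALSE, note = NA_character_
  )
  if (n == 0) {
    return(list(
      row = base %>% mutate(note = "no complete cases"),
      exclusion = tibble(study_id = study_id, reason = "no complete cases")
    ))
  }
  y <- cohort$mdi
  risk <- cohort$risk
  lp <- cohort$lp
  conf <- confusion_at_threshold(risk, y, threshold)
  base$tp <- conf$tp; base$fn <- conf$fn
  base$tn <- conf$tn; base$fp <- conf$fp
  base$sens <- conf$sens; base$spec <- conf$spec
  base$low_risk_frac <- conf$low_risk_frac
  one_class <- sum(y) == 0 || sum(y) == n
  if (one_class) {
    return(list(
      row = base %>% mutate(note = "single outcome class"),
      exclusion = tibble(
        study_id = study_id,
        reason = "single outcome class: C, E/O and slope undefined"
      )
    ))
  }
  base$usable <- TRUE
  base$c_stat <- c_statistic(risk, y)
  base$eo <- e_o_ratio(risk, y)
  cal <- calibration_fit(lp, y)
  base$slope <- cal$slope
  base$calib_intercept <- cal$intercept
  base$citl <- cal$citl
  base$citl_se <- cal$citl_se
  if (!isTRUE(cal$converged)) {
    base$note <- "calibration fit did not converge (possible separation)"
  }
  if (se_method == "bootstrap") {
    bs <- boot_study_metrics(lp, risk, y, draws = draws, seed = seed)
    base$c_se_logit <- bs$logit_c$se
    base$c_ci_lower <- plogis(bs$logit_c$lo)
    base$c_ci_upper <- plogis(bs$logit_c$hi)
    base$log_eo_se <- bs$log_eo$se
    base$eo_ci_lower <- exp(bs$log_eo$lo)
    base$eo_ci_upper <- exp(bs$log_eo$hi)
    base$slope_se <- bs$slope$se
    base$slope_ci_lower <- bs$slope$lo
    base$slope_ci_upper <- bs$slope$hi
    base$slope_se <- bs$slope$se
    n_fail <- bs$logit_c$n_failed
    if (is.finite(n_fail) && n_fail > draws / 2) {
      base$note <- paste(
        na.omit(c(base$note, "unstable bootstrap (>50% draws undefined)")),
        collapse = "; "
      )
    }
  } else {
    cs <- base$c_stat
    se_c <- hanley_mcneil_se(cs, sum(y), n - sum(y))
    base$c_se_logit <- se_c / (cs * (1 - cs))
    base$c_ci_lower <- plogis(qlogis(cs) - 1.96 * base$c_se_logit)
    base$c_ci_upper <- plogis(qlogis(cs) + 1.96 * base$c_se_logit)
    o <- sum(y)
    base$log_eo_se <- sqrt(sum(risk * (1 - risk))) / o
    base$eo_ci_lower <- exp(log(base$eo) - 1.96 * base$log_eo_se)
    base$eo_ci_upper <- exp(log(base$eo) + 1.96 * base$log_eo_se)
    base$slope_se <- cal$slope_se
    base$slope_ci_lower <- cal$slope - 1.96 * cal$slope_se
    base$slope_ci_upper <- cal$slope + 1.96 * cal$slope_se
    base$calib_intercept_se <- cal$intercept_se
  }
  if (se_method == "bootstrap") base$calib_intercept_se <- cal$intercept_se
  calibration <- NULL
  if (n >= bins) {
    calibration <- suppressMessages(
      calibration_plot_data(risk, y, bins = bins)
    ) %>%
      mutate(study_id = study_id, .before = 1)
  }
  list(row = base, calibration = calibration, exclusion = NULL)
}

#' @export
print.picnicc_performance <- function(x, ...) {
  cat(
    "<picnicc_performance> ", nrow(x), " studies, threshold ",
    attr(x, "threshold") %||% NA, ", SE method: ",
    attr(x, "se_method") %||% "?", "\n",
    sep = ""
  )
  NextMethod()
}
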