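# Per-study validation metrics: discrimination (C-statistic), calibration
# (E/O ratio, logistic recalibration fits), threshold classification and
# calibration-plot binning, plus bootstrap uncertainty.

#' Concordance (C) statistic / AUROC
#'
#' Probability that a randomly chosen event carries a higher predicted risk
#' than a randomly chosen non-event, with ties credited one half
#' (Mann-Whitney formulation, computed from average ranks).
#'
#' @param risks Predicted probabilities (any monotone score works).
#' @param outcomes Binary outcomes (0/1).
#' @return C-statistic in \[0, 1\]; `NA` with a classed warning when only
#'   one outcome class is present (the study is then excluded from C
#'   pooling).
#' @export
c_statistic <- function(risks, outcomes) {
  stopifnot(length(risks) == length(outcomes))
  keep <- !is.na(risks) & !is.na(outcomes)
  risks <- risks[keep]
  outcomes <- outcomes[keep]
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) {
    warn(
      "C-statistic undefined: only one outcome class present.",
      class = "picnicc_undefined_metric"
    )
    return(NA_real_)
  }
  r <- rank(risks, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Expected/observed (E/O) ratio
#'
#' Sum of predicted risks divided by the observed event count; the ideal
#' value is 1, values above 1 indicate systematic risk overestimation.
#'
#' @inheritParams c_statistic
#' @return Positive real; `NA` with a classed warning when no events are
#'   observed.
#' @export
e_o_ratio <- function(risks, outcomes) {
  stopifnot(length(risks) == length(outcomes))
  keep <- !is.na(risks) & !is.na(outcomes)
  risks <- risks[keep]
  outcomes <- outcomes[keep]
  o <- sum(outcomes)
  if (o == 0) {
    warn(
      "E/O undefined: no observed events.",
      class = "picnicc_undefined_metric"
    )
    return(NA_real_)
  }
  sum(risks) / o
}

# Hanley-McNeil large-sample SE of the C-statistic; used by the analytic
# SE mode (and as a sanity anchor for the bootstrap).
hanley_mcneil_se <- function(c_stat, n_events, n_nonevents) {
  q1 <- c_stat / (2 - c_stat)
  q2 <- 2 * c_stat^2 / (1 + c_stat)
  sqrt(
    (c_stat * (1 - c_stat) +
       (n_events - 1) * (q1 - c_stat^2) +
       (n_nonevents - 1) * (q2 - c_stat^2)) /
      (n_events * n_nonevents)
  )
}

#' Logistic recalibration fit (calibration slope and intercept)
#'
#' Maximum-likelihood fit of `logit P(y = 1) = a + b * LP`. The slope `b`
#' is the calibration slope (ideal 1); `a` is the joint-fit intercept. The
#' calibration-in-the-large intercept (`citl`), estimated with the slope
#' fixed at 1 by an intercept-only fit with `LP` as offset, is returned
#' alongside since conventions differ on which to report.
#'
#' @param lp Linear predictors (log-odds scale).
#' @param outcomes Binary outcomes (0/1).
#' @return One-row tibble with `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `citl`, `citl_se` and a `converged` flag. Constant
#'   `lp` or a single outcome class give `NA` estimates with a classed
#'   warning; separation is reported as-is with `converged = FALSE`.
#' @export
calibration_fit <- function(lp, outcomes) {
  stopifnot(length(lp) == length(outcomes))
  keep <- !is.na(lp) & !is.na(outcomes)
  lp <- lp[keep]
  y <- outcomes[keep]
  empty <- tibble(
    slope = NA_real_, slope_se = NA_real_,
    intercept = NA_real_, intercept_se = NA_real_,
    citl = NA_real_, citl_se = NA_real_,
    converged = FALSE
  )
  if (length(unique(y)) < 2) {
    warn(
      "Calibration fit undefined: only one outcome class present.",
      class = "picnicc_undefined_metric"
    )
    return(empty)
  }
  if (isTRUE(all.equal(var(lp), 0)) || var(lp) == 0) {
    warn(
      "Calibration slope undefined: linear predictor is constant.",
      class = "picnicc_undefined_metric"
    )
    citl <- citl_fit(lp, y)
    empty$citl <- citl[1]
    empty$citl_se <- citl[2]
    return(empty)
  }
  fit <- suppressWarnings(glm(y ~ lp, family = binomial()))
  sm <- summary(fit)$coefficients
  citl <- citl_fit(lp, y)
  tibble(
    slope = unname(coef(fit)[2]),
    slope_se = sm["lp", "Std. Error"],
    intercept = unname(coef(fit)[1]),
    intercept_se = sm["(Intercept)", "Std. Error"],
    citl = citl[1],
    citl_se = citl[2],
    converged = fit$converged && all(abs(coef(fit)) < 20)
  )
}

# Intercept-only logistic fit with lp as offset: slope fixed at 1.
# Its MLE satisfies mean(fitted) = mean(y) (calibration in the large).
citl_fit <- function(lp, y) {
  fit <- suppressWarnings(glm(y ~ 1 + offset(lp), family = binomial()))
  c(unname(coef(fit)[1]), summary(fit)$coefficients[1, "Std. Error"])
}

#' Classification counts at a risk threshold
#'
#' Dichotomises predicted risks at the threshold (inclusive: risk at or
#' below the threshold is the low-risk call; high risk is the positive
#' call for MDI) and tabulates the 2x2 confusion counts with sensitivity,
#' specificity and the low-risk fraction.
#'
#' @inheritParams c_statistic
#' @param threshold Risk threshold (default 0.10).
#' @return One-row tibble `tp`, `fn`, `tn`, `fp`, `sens`, `spec`,
#'   `low_risk_frac`, `n`. A zero denominator leaves the affected rate
#'   `NA` (counts are still returned).
#' @export
confusion_at_threshold <- function(risks, outcomes, threshold = 0.10) {
  stopifnot(length(risks) == length(outcomes))
  keep <- !is.na(risks) & !is.na(outcomes)
  risks <- risks[keep]
  outcomes <- outcomes[keep]
  low <- classify_low_risk(risks, threshold)
  tp <- sum(!low & outcomes == 1)
  fn <- sum(low & outcomes == 1)
  tn <- sum(low & outcomes == 0)
  fp <- sum(!low & outcomes == 0)
  tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    low_risk_frac = if (length(low) > 0) mean(low) else NA_real_,
    n = length(low)
  )
}

#' Calibration plot data (quantile bins)
#'
#' Splits episodes into (approximately) equal-count bins of predicted risk
#' and returns per-bin mean predicted risk against the observed event
#' proportion; on a well-calibrated model the points sit on the diagonal.
#' Heavy ties collapse bins (quantile breaks coincide); collapsed bins are
#' merged and reported.
#'
#' @inheritParams c_statistic
#' @param bins Target number of bins (default 10).
#' @return Tibble with `bin`, `mean_pred`, `obs_prop`, `n`.
#' @export
calibration_plot_data <- function(risks, outcomes, bins = 10) {
  stopifnot(length(risks) == length(outcomes))
  keep <- !is.na(risks) & !is.na(outcomes)
  risks <- risks[keep]
  outcomes <- outcomes[keep]
  if (length(risks) < bins) {
    abort("Need at least as many episodes as bins.")
  }
  breaks <- unique(quantile(risks, probs = seq(0, 1, length.out = bins + 1)))
  if (length(breaks) < 2) {
    # constant risks: a single bin
    bin_id <- rep(1L, length(risks))
  } else {
    if (length(breaks) < bins + 1) {
      inform(
        paste0(
          "Tied risks collapsed ", bins + 1 - length(breaks),
          " bin boundary(ies); bins merged."
        ),
        class = "picnicc_bins_merged"
      )
    }
    bin_id <- as.integer(cut(risks, breaks, include.lowest = TRUE))
  }
  tibble(risk = risks, y = outcomes, bin = bin_id) %>%
    group_by(.data$bin) %>%
    summarise(
      mean_pred = mean(.data$risk),
      obs_prop = mean(.data$y),
      n = n(),
      .groups = "drop"
    ) %>%
    arrange(.data$bin)
}

#' Bootstrap standard error of a statistic
#'
#' Resamples episode rows with replacement, recomputes the statistic on
#' each resample, and returns the standard deviation across successful
#' draws plus percentile limits. Draws where the statistic is undefined
#' (NA/non-finite, e.g. a resample with no events) are dropped and
#' counted; if more than half fail the estimate is flagged unstable.
#'
#' @param data Data frame of episodes (rows are the resampling unit).
#' @param statistic Function mapping a resampled data frame to one number.
#' @param draws Number of bootstrap draws (the validation default is 2000).
#' @param seed Integer seed; the same seed, data and draws give identical
#'   results.
#' @param conf Coverage for the percentile interval.
#' @return List with `se`, `ci_lower`, `ci_upper`, `n_ok`, `n_failed`,
#'   `unstable`.
#' @export
bootstrap_se <- function(data, statistic, draws = 2000, seed = 1,
                         conf = 0.95) {
  n <- nrow(data)
  stopifnot(n > 0, draws >= 2)
  set.seed(seed)
  vals <- vapply(seq_len(draws), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    out <- tryCatch(
      suppressWarnings(statistic(data[idx, , drop = FALSE])),
      error = function(e) NA_real_
    )
    if (length(out) != 1 || !is.finite(out)) NA_real_ else out
  }, numeric(1))
  ok <- vals[is.finite(vals)]
  unstable <- length(ok) < draws / 2
  if (unstable) {
    warn(
      paste0(
        "Bootstrap unstable: ", draws - length(ok), "/", draws,
        " draws undefined."
      ),
      class = "picnicc_unstable_bootstrap"
    )
  }
  alpha <- (1 - conf) / 2
  list(
    se = if (length(ok) >= 2) sd(ok) else NA_real_,
    ci_lower = if (length(ok) >= 2) unname(quantile(ok, alpha)) else NA_real_,
    ci_upper = if (length(ok) >= 2) unname(quantile(ok, 1 - alpha)) else NA_real_,
    n_ok = length(ok),
    n_failed = draws - length(ok),
    unstable = unstable
  )
}

# Joint bootstrap of the three pooled metrics on their analysis scales
# (logit C, ln E/O, identity slope) in a single resampling pass.
boot_study_metrics <- function(lp, risk, y, draws, seed, conf = 0.95) {
  n <- length(y)
  set.seed(seed)
  out <- matrix(NA_real_, nrow = draws, ncol = 3,
                dimnames = list(NULL, c("logit_c", "log_eo", "slope")))
  for (i in seq_len(draws)) {
    idx <- sample.int(n, n, replace = TRUE)
    yi <- y[idx]
    if (sum(yi) == 0 || sum(yi) == n) next
    ri <- risk[idx]
    li <- lp[idx]
    ci <- suppressWarnings(c_statistic(ri, yi))
    if (is.finite(ci) && ci > 0 && ci < 1) out[i, 1] <- qlogis(ci)
    out[i, 2] <- log(sum(ri) / sum(yi))
    if (var(li) > 0) {
      sl <- tryCatch(
        suppressWarnings(
          glm.fit(cbind(1, li), yi, family = binomial())$coefficients[2]
        ),
        error = function(e) NA_real_
      )
      if (is.finite(sl)) out[i, 3] <- sl
    }
  }
  alpha <- (1 - conf) / 2
  summarise_col <- function(v) {
    ok <- v[is.finite(v)]
    list(
      se = if (length(ok) >= 2) sd(ok) else NA_real_,
      lo = if (length(ok) >= 2) unname(quantile(ok, alpha)) else NA_real_,
      hi = if (length(ok) >= 2) unname(quantile(ok, 1 - alpha)) else NA_real_,
      n_failed = length(v) - length(ok)
    )
  }
  lapply(
    list(logit_c = out[, 1], log_eo = out[, 2], slope = out[, 3]),
    summarise_col
  )
}
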