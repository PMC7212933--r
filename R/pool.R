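# Random-effects pooling of per-study performance: REML inverse-variance
# meta-analysis with 95% CIs and prediction intervals, tau^2, and
# meta-regression of intercepts on event proportion.

back_transform <- function(x, scale) {
  switch(scale,
    identity = x,
    logit = plogis(x),
    log = exp(x),
    abort(paste0("Unknown analysis scale: ", scale))
  )
}

#' Random-effects pooling of study estimates (REML)
#'
#' Pools per-study estimates with inverse-variance weights under a
#' random-effects model, estimating the between-study variance tau^2 by
#' restricted maximum likelihood (DerSimonian-Laird fallback with a
#' warning if REML fails to converge). The 95% CI is normal-based on the
#' analysis scale (a Hartung-Knapp t-based adjustment is available); the
#' 95% prediction interval, reported when at least three studies
#' contribute, uses the t_(k-2) form `est +/- t * sqrt(tau^2 + SE^2)` and
#' describes expected performance in a new setting.
#'
#' @param estimates Per-study estimates on the analysis scale.
#' @param variances Per-study squared standard errors (same scale).
#' @param labels Optional study labels.
#' @param metric Name of the pooled metric (bookkeeping).
#' @param scale Analysis scale: `"identity"`, `"logit"` or `"log"`;
#'   back-transformed summaries are reported alongside.
#' @param hartung_knapp Use the Hartung-Knapp-Sidik-Jonkman CI adjustment.
#' @param method tau^2 estimator passed to [metafor::rma.uni()].
#' @return A `picnicc_pooled` object; see [tidy()] and [glance()] methods.
#' @examples
#' p <- pool_metric(c(0.2, 0.5, 0.9), c(0.04, 0.04, 0.04))
#' tidy(p)
#' @export
pool_metric <- function(estimates, variances, labels = NULL,
                        metric = "metric", scale = "identity",
                        hartung_knapp = FALSE, method = "REML") {
  keep <- is.finite(estimates) & is.finite(variances)
  estimates <- estimates[keep]
  variances <- variances[keep]
  labels <- (labels %||% paste0("study_", seq_along(keep)))[keep]
  k <- length(estimates)
  if (k < 2) {
    abort("Pooling needs at least 2 studies with finite estimate and variance.",
          class = "picnicc_pool_error")
  }
  if (any(variances <= 0)) {
    abort("All variances must be positive.", class = "picnicc_pool_error")
  }
  test <- if (hartung_knapp) "knha" else "z"
  fit <- tryCatch(
    suppressWarnings(metafor::rma.uni(
      yi = estimates, vi = variances, method = method, test = test,
      control = list(maxiter = 100, threshold = 1e-8)
    )),
    error = function(e) NULL
  )
  method_used <- method
  if (is.null(fit)) {
    warn(
      "REML did not converge; falling back to DerSimonian-Laird.",
      class = "picnicc_reml_fallback"
    )
    fit <- suppressWarnings(metafor::rma.uni(
      yi = estimates, vi = variances, method = "DL", test = test
    ))
    method_used <- "DL"
  }
  est <- as.numeric(fit$beta)
  se <- fit$se
  tau2 <- max(0, fit$tau2)
  ci <- c(fit$ci.lb, fit$ci.ub)
  if (k >= 3) {
    half <- qt(0.975, df = k - 2) * sqrt(tau2 + se^2)
    pri <- c(est - half, est + half)
  } else {
    pri <- c(NA_real_, NA_real_)
  }
  w <- 1 / (variances + tau2)
  structure(
    list(
      metric = metric,
      scale = scale,
      k = k,
      estimate = est,
      se = se,
      ci_lower = ci[1], ci_upper = ci[2],
      pri_lower = pri[1], pri_upper = pri[2],
      tau2 = tau2,
      method = method_used,
      hartung_knapp = hartung_knapp,
      studies = tibble(
        label = labels,
        yi = estimates,
        vi = variances,
        weight = w / sum(w)
      )
    ),
    class = "picnicc_pooled"
  )
}

#' 95% prediction interval of a pooled result
#'
#' @param pooled A `picnicc_pooled` object from [pool_metric()].
#' @return One-row tibble with the interval on the analysis scale and
#'   back-transformed; `NA` with a flag when fewer than 3 studies
#'   contributed.
#' @export
prediction_interval <- function(pooled) {
  stopifnot(inherits(pooled, "picnicc_pooled"))
  available <- pooled$k >= 3 && is.finite(pooled$pri_lower)
  if (!available) {
    warn("Prediction interval requires at least 3 studies; omitted.",
         class = "picnicc_pri_omitted")
  }
  tibble(
    metric = pooled$metric,
    pri_lower = pooled$pri_lower,
    pri_upper = pooled$pri_upper,
    pri_lower_natural = back_transform(pooled$pri_lower, pooled$scale),
    pri_upper_natural = back_transform(pooled$pri_upper, pooled$scale),
    available = available
  )
}

#' @export
print.picnicc_pooled <- function(x, ...) {
  cat("<picnicc_pooled> ", x$metric, " (", x$scale, " scale, ",
      x$method, ", k = ", x$k, ")\n", sep = "")
  nat <- back_transform(
    c(x$estimate, x$ci_lower, x$ci_upper, x$pri_lower, x$pri_upper), x$scale
  )
  cat(sprintf(
    "  pooled %.3f (95%% CI %.3f to %.3f; 95%% PrI %.3f to %.3f), tau^2 = %.3g\n",
    nat[1], nat[2], nat[3], nat[4], nat[5], x$tau2
  ))
  invisible(x)
}

# Metric -> (column, variance column, analysis scale, transform of estimate)
POOLABLE_METRICS <- list(
  c_statistic = list(
    est = "c_stat", se = "c_se_logit", scale = "logit",
    fw = function(x) qlogis(x)
  ),
  e_o_ratio = list(
    est = "eo", se = "log_eo_se", scale = "log",
    fw = function(x) log(x)
  ),
  calib_slope = list(
    est = "slope", se = "slope_se", scale = "identity",
    fw = identity
  ),
  calib_intercept = list(
    est = "calib_intercept", se = "calib_intercept_se", scale = "identity",
    fw = identity
  ),
  citl = list(
    est = "citl", se = "citl_se", scale = "identity",
    fw = identity
  )
)

#' Pool a performance table across studies
#'
#' Runs [pool_metric()] for each requested metric of a
#' [validate_studies()] table on its standard analysis scale (logit for
#' the C-statistic, natural log for E/O, identity for the calibration
#' slope and intercepts); `scale = "identity"` forces identity-scale
#' pooling of all metrics as a sensitivity analysis.
#'
#' @param perf A `picnicc_performance` tibble.
#' @param metrics Metrics to pool, subset of
#'   `c("c_statistic", "e_o_ratio", "calib_slope", "calib_intercept",
#'   "citl")`.
#' @param scale `"standard"` (per-metric scales) or `"identity"`.
#' @param hartung_knapp Passed to [pool_metric()].
#' @return Named list of `picnicc_pooled` objects, class
#'   `picnicc_pooled_set`.
#' @export
pool_performance <- function(perf,
                             metrics = c("c_statistic", "e_o_ratio",
                                         "calib_slope"),
                             scale = c("standard", "identity"),
                             hartung_knapp = FALSE) {
  scale <- match.arg(scale)
  metrics <- match.arg(metrics, names(POOLABLE_METRICS), several.ok = TRUE)
  out <- lapply(metrics, function(m) {
    def <- POOLABLE_METRICS[[m]]
    est <- perf[[def$est]]
    se <- perf[[def$se]]
    use_scale <- if (scale == "identity") "identity" else def$scale
    yi <- if (use_scale == "identity") est else def$fw(est)
    vi <- if (use_scale == "identity" && def$scale != "identity") {
      # delta-method variance back onto the identity scale
      if (def$scale == "logit") (se * est * (1 - est))^2 else (se * est)^2
    } else {
      se^2
    }
    pool_metric(
      yi, vi, labels = perf$study_id, metric = m, scale = use_scale,
      hartung_knapp = hartung_knapp
    )
  })
  names(out) <- metrics
  structure(out, class = "picnicc_pooled_set")
}

#' @export
print.picnicc_pooled_set <- function(x, ...) {
  for (p in x) print(p)
  invisible(x)
}

#' Random-effects meta-regression of intercepts on event proportion
#'
#' Regresses per-study calibration intercepts on the study MDI proportion
#' under a random-effects model (REML residual heterogeneity), and exposes
#' interpolation of the intercept at a given proportion. A constant
#' covariate degenerates to plain pooling (slope undefined, flagged).
#'
#' @param estimates Per-study intercept estimates.
#' @param variances Their squared standard errors.
#' @param covariate Per-study MDI proportions.
#' @param labels Optional study labels.
#' @return A `picnicc_metareg` object with elements `intercept`, `slope`,
#'   `tau2`, `degenerate` and the function `interpolate(proportion)`
#'   (warns when extrapolating beyond the observed proportion range).
#' @export
meta_regress <- function(estimates, variances, covariate, labels = NULL) {
  keep <- is.finite(estimates) & is.finite(variances) & is.finite(covariate)
  estimates <- estimates[keep]
  variances <- variances[keep]
  covariate <- covariate[keep]
  labels <- (labels %||% paste0("study_", seq_along(keep)))[keep]
  k <- length(estimates)
  if (k < 3) {
    abort(
      "Meta-regression needs at least 3 studies; use the event-rate strategy (B) instead.",
      class = "picnicc_pool_error"
    )
  }
  rng <- range(covariate)
  degenerate <- diff(rng) < sqrt(.Machine$double.eps)
  if (degenerate) {
    warn(
      "Constant covariate: slope undefined, reducing to plain random-effects pooling.",
      class = "picnicc_metareg_degenerate"
    )
    pooled <- pool_metric(estimates, variances, labels = labels,
                          metric = "intercept", scale = "identity")
    obj <- list(
      intercept = pooled$estimate, slope = NA_real_,
      intercept_se = pooled$se, slope_se = NA_real_,
      tau2 = pooled$tau2, k = k, degenerate = TRUE,
      covariate_range = rng,
      studies = tibble(label = labels, yi = estimates, vi = variances,
                       covariate = covariate)
    )
    obj$interpolate <- function(proportion) {
      rep(pooled$estimate, length(proportion))
    }
    return(structure(obj, class = "picnicc_metareg"))
  }
  fit <- suppressWarnings(metafor::rma.uni(
    yi = estimates, vi = variances, mods = ~covariate, method = "REML",
    control = list(maxiter = 100, threshold = 1e-8)
  ))
  b <- as.numeric(fit$beta)
  se <- fit$se
  obj <- list(
    intercept = b[1], slope = b[2],
    intercept_se = se[1], slope_se = se[2],
    tau2 = max(0, fit$tau2), k = k, degenerate = FALSE,
    covariate_range = rng,
    studies = tibble(label = labels, yi = estimates, vi = variances,
                     covariate = covariate)
  )
  obj$interpolate <- function(proportion) {
    out_of_range <- proportion < rng[1] | proportion > rng[2]
    if (any(out_of_range)) {
      warn(
        "Interpolating outside the observed MDI proportion range.",
        class = "picnicc_metareg_extrapolation"
      )
    }
    b[1] + b[2] * proportion
  }
  structure(obj, class = "picnicc_metareg")
}

#' @export
print.picnicc_metareg <- function(x, ...) {
  cat("<picnicc_metareg> k = ", x$k, "\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate (constant covariate): pooled intercept ",
        format(x$intercept), "\n", sep = "")
  } else {
    cat(sprintf("  intercept = %.4f (SE %.4f), slope = %.4f (SE %.4f), tau^2 = %.3g\n",
                x$intercept, x$intercept_se, x$slope, x$slope_se, x$tau2))
  }
  invisible(x)
}
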