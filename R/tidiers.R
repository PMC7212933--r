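# broom-style tidiers for the fitted result objects.

#' @export
tidy.picnicc_pooled <- function(x, ...) {
  tibble(
    metric = x$metric,
    estimate = back_transform(x$estimate, x$scale),
    ci_lower = back_transform(x$ci_lower, x$scale),
    ci_upper = back_transform(x$ci_upper, x$scale),
    pri_lower = back_transform(x$pri_lower, x$scale),
    pri_upper = back_transform(x$pri_upper, x$scale),
    scale = x$scale,
    estimate_analysis = x$estimate,
    se_analysis = x$se,
    tau2 = x$tau2,
    k = x$k
  )
}

#' @export
glance.picnicc_pooled <- function(x, ...) {
  tibble(
    metric = x$metric, k = x$k, tau2 = x$tau2,
    method = x$method, scale = x$scale,
    hartung_knapp = x$hartung_knapp
  )
}

#' @export
tidy.picnicc_pooled_set <- function(x, ...) {
  bind_rows(lapply(x, tidy))
}

#' @export
tidy.picnicc_bivariate <- function(x, ...) {
  tibble(
    measure = c("sensitivity", "specificity"),
    estimate = c(x$sens, x$spec),
    ci_lower = c(x$sens_ci[1], x$spec_ci[1]),
    ci_upper = c(x$sens_ci[2], x$spec_ci[2]),
    estimate_logit = c(x$logit_sens, x$logit_spec),
    se_logit = sqrt(diag(x$vcov_fixed)),
    tau2 = diag(x$Psi)
  )
}

#' @export
glance.picnicc_bivariate <- function(x, ...) {
  tibble(
    k = x$k,
    between_study_corr = if (anyNA(x$Psi)) NA_real_ else {
      denom <- sqrt(prod(diag(x$Psi)))
      if (denom > 0) x$Psi[1, 2] / denom else NA_real_
    },
    converged = x$converged,
    n_corrected = x$n_corrected
  )
}

#' @export
tidy.picnicc_metareg <- function(x, ...) {
  tibble(
    term = c("intercept", "covariate"),
    estimate = c(x$intercept, x$slope),
    std_error = c(x$intercept_se, x$slope_se)
  )
}

#' @export
glance.picnicc_metareg <- function(x, ...) {
  tibble(k = x$k, tau2 = x$tau2, degenerate = x$degenerate)
}

#' @export
tidy.picnicc_recalibration <- function(x, ...) {
  x$adjustments %>% mutate(strategy = x$strategy, .before = 1)
}
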