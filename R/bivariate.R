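# Bivariate random-effects meta-analysis of sensitivity and specificity
# (Reitsma-style linear mixed model on the logit scale with approximate
# normal within-study errors), plus ROC-space ellipse generation.

#' Bivariate meta-analysis of sensitivity and specificity
#'
#' Jointly pools per-study sensitivity and specificity at the risk
#' threshold under a bivariate random-effects model: per-study logit
#' proportions with binomial within-study variances, and an unstructured
#' 2x2 between-study covariance estimated by REML
#' ([metafor::rma.mv()]). Studies with a zero cell in the relevant margin
#' get a +0.5 continuity correction to all four cells (logged). If the
#' bivariate fit fails, independent univariate pooling is used and the
#' between-study correlation reported as unavailable.
#'
#' @param perf A `picnicc_performance` tibble (needs `tp`, `fn`, `tn`,
#'   `fp`), or any data frame with those columns plus `study_id`.
#' @return A `picnicc_bivariate` object: pooled `sens`/`spec` with 95%
#'   CIs, the pooled logit estimates with their fixed-effect covariance,
#'   the between-study covariance matrix `Psi`, and the per-study input.
#' @examples
#' counts <- tibble::tibble(
#'   study_id = c("a", "b", "c"),
#'   tp = c(18, 40, 25), fn = c(2, 5, 2),
#'   tn = c(10, 20, 12), fp = c(70, 150, 80)
#' )
#' b <- pool_sens_spec(counts)
#' tidy(b)
#' @export
pool_sens_spec <- function(perf) {
  counts <- as_tibble(perf) %>%
    select("study_id", "tp", "fn", "tn", "fp") %>%
    filter(
      is.finite(.data$tp), is.finite(.data$fn),
      is.finite(.data$tn), is.finite(.data$fp),
      .data$tp + .data$fn > 0 | .data$tn + .data$fp > 0
    )
  k <- nrow(counts)
  if (k < 3) {
    abort("Bivariate pooling needs at least 3 usable studies.",
          class = "picnicc_pool_error")
  }
  zero_cell <- with(counts, tp == 0 | fn == 0 | tn == 0 | fp == 0)
  if (any(zero_cell)) {
    inform(
      paste0(
        sum(zero_cell),
        " study(ies) with a zero cell: +0.5 continuity correction applied."
      ),
      class = "picnicc_continuity_correction"
    )
  }
  corr <- counts %>%
    mutate(
      adj = ifelse(zero_cell, 0.5, 0),
      tp = .data$tp + .data$adj, fn = .data$fn + .data$adj,
      tn = .data$tn + .data$adj, fp = .data$fp + .data$adj,
      logit_sens = qlogis(.data$tp / (.data$tp + .data$fn)),
      v_sens = 1 / .data$tp + 1 / .data$fn,
      logit_spec = qlogis(.data$tn / (.data$tn + .data$fp)),
      v_spec = 1 / .data$tn + 1 / .data$fp
    )
  long <- tibble(
    study = rep(corr$study_id, each = 2),
    measure = factor(rep(c("sens", "spec"), k), levels = c("sens", "spec")),
    yi = as.vector(rbind(corr$logit_sens, corr$logit_spec)),
    vi = as.vector(rbind(corr$v_sens, corr$v_spec))
  )
  fit <- tryCatch(
    suppressWarnings(metafor::rma.mv(
      yi, V = vi, mods = ~ measure - 1, random = ~ measure | study,
      struct = "UN", data = long, method = "REML",
      control = list(iter.max = 200)
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    b <- as.numeric(fit$b)
    names(b) <- c("sens", "spec")
    vb <- matrix(as.numeric(vcov(fit)), 2, 2,
                 dimnames = list(c("sens", "spec"), c("sens", "spec")))
    tau2 <- fit$tau2
    rho <- fit$rho
    off <- rho * sqrt(prod(tau2))
    psi <- matrix(c(tau2[1], off, off, tau2[2]), 2, 2,
                  dimnames = dimnames(vb))
    converged <- TRUE
  } else {
    warn(
      "Bivariate fit did not converge; falling back to independent univariate pooling (between-study correlation unavailable).",
      class = "picnicc_bivariate_fallback"
    )
    p_sens <- pool_metric(corr$logit_sens, corr$v_sens,
                          labels = corr$study_id, metric = "sens",
                          scale = "logit")
    p_spec <- pool_metric(corr$logit_spec, corr$v_spec,
                          labels = corr$study_id, metric = "spec",
                          scale = "logit")
    b <- c(sens = p_sens$estimate, spec = p_spec$estimate)
    vb <- diag(c(p_sens$se^2, p_spec$se^2))
    dimnames(vb) <- list(c("sens", "spec"), c("sens", "spec"))
    psi <- diag(c(p_sens$tau2, p_spec$tau2))
    dimnames(psi) <- dimnames(vb)
    psi[1, 2] <- psi[2, 1] <- NA_real_
    converged <- FALSE
  }
  se <- sqrt(diag(vb))
  structure(
    list(
      k = k,
      logit_sens = b[["sens"]], logit_spec = b[["spec"]],
      vcov_fixed = vb,
      Psi = psi,
      sens = plogis(b[["sens"]]),
      sens_ci = plogis(b[["sens"]] + c(-1, 1) * 1.96 * se[1]),
      spec = plogis(b[["spec"]]),
      spec_ci = plogis(b[["spec"]] + c(-1, 1) * 1.96 * se[2]),
      converged = converged,
      n_corrected = sum(zero_cell),
      studies = corr %>%
        mutate(
          sens = .data$tp / (.data$tp + .data$fn),
          spec = .data$tn / (.data$tn + .data$fp)
        ) %>%
        select("study_id", "tp", "fn", "tn", "fp", "sens", "spec",
               "logit_sens", "v_sens", "logit_spec", "v_spec")
    ),
    class = "picnicc_bivariate"
  )
}

#' @export
print.picnicc_bivariate <- function(x, ...) {
  cat("<picnicc_bivariate> k = ", x$k,
      if (!x$converged) " (univariate fallback)", "\n", sep = "")
  cat(sprintf(
    "  pooled Sn %.1f%% (95%% CI %.1f to %.1f), Sp %.1f%% (95%% CI %.1f to %.1f)\n",
    100 * x$sens, 100 * x$sens_ci[1], 100 * x$sens_ci[2],
    100 * x$spec, 100 * x$spec_ci[1], 100 * x$spec_ci[2]
  ))
  invisible(x)
}

#' ROC-space ellipse coordinates for a bivariate pooled result
#'
#' Generates the confidence region (uncertainty of the pooled summary) or
#' prediction region (expected study-level scatter; fixed-effect
#' covariance plus between-study covariance) around the pooled
#' (sensitivity, specificity) point, as coordinates for ROC-space
#' plotting.
#'
#' @param biv A `picnicc_bivariate` object.
#' @param type `"confidence"` or `"prediction"`.
#' @param level Coverage level.
#' @param n Number of polygon points.
#' @return Tibble with `type`, `sens`, `spec`, `fpr` (= 1 - spec).
#' @export
roc_ellipse <- function(biv, type = c("confidence", "prediction"),
                        level = 0.95, n = 180) {
  stopifnot(inherits(biv, "picnicc_bivariate"))
  type <- match.arg(type)
  S <- biv$vcov_fixed
  if (type == "prediction") {
    psi <- biv$Psi
    if (anyNA(psi)) {
      psi[is.na(psi)] <- 0
      warn(
        "Between-study correlation unavailable; prediction region assumes independence.",
        class = "picnicc_bivariate_fallback"
      )
    }
    S <- S + psi
  }
  mu <- c(biv$logit_sens, biv$logit_spec)
  r <- sqrt(qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n)
  circle <- rbind(cos(theta), sin(theta))
  ev <- eigen(S, symmetric = TRUE)
  half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  pts <- mu + r * half %*% circle
  tibble(
    type = type,
    sens = plogis(pts[1, ]),
    spec = plogis(pts[2, ]),
    fpr = 1 - plogis(pts[2, ])
  )
}
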