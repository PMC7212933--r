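# End-to-end orchestration: load or simulate cohorts, validate per study,
# pool, recalibrate and re-pool, summarise clinical utility, re-estimate
# coefficients, and export a report bundle.

#' Advisory check of the total event count
#'
#' External validation of a binary-outcome risk model is conventionally
#' expected to rest on at least 100 events in total; this check warns
#' when the stacked cohorts fall below that minimum.
#'
#' @param data Episode data (column `mdi`; missing outcomes ignored).
#' @param minimum Advisory minimum (default 100).
#' @return Tibble `total_events`, `minimum`, `ok` (invisibly); a classed
#'   warning is emitted when below the minimum.
#' @export
check_event_count <- function(data, minimum = 100) {
  total <- if (is.data.frame(data) && "mdi" %in% names(data)) {
    sum(data$mdi, na.rm = TRUE)
  } else {
    0
  }
  ok <- total >= minimum
  if (!ok) {
    warn(
      paste0(
        "Total MDI events (", total, ") below the advisory minimum of ",
        minimum, " for external validation."
      ),
      class = "picnicc_event_count"
    )
  }
  invisible(tibble(total_events = total, minimum = minimum, ok = ok))
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("Config file not found: ", config))
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config %||% list()
}

#' Run the full external-validation pipeline
#'
#' Executes the analysis end to end: score episodes with the model,
#' validate each study on its complete cases, pool the C-statistic, E/O
#' ratio and calibration slope by random-effects meta-analysis, apply the
#' requested recalibration strategies and re-validate and re-pool after
#' each, summarise clinical utility (sensitivity/specificity at the risk
#' threshold) by bivariate meta-analysis for the raw and each
#' recalibrated model, and re-estimate the model coefficients on the
#' stacked data. Any study-level failure becomes an exclusion with a
#' reason rather than aborting; the run aborts only when no usable study
#' remains.
#'
#' @param episodes Episode data frame, or `NULL` to generate synthetic
#'   cohorts from `config`.
#' @param config Optional list or YAML/JSON path with entries `inputs`
#'   (CSV paths), `synthetic` (overrides for [synthetic_config()]),
#'   `model` (path/list for [load_model_spec()]), and defaults for
#'   `seed`, `draws`, `threshold`, `strategies`.
#' @param model A [picnicc_model()]; overrides `config$model`.
#' @param seed Global seed; stage seeds (generation, per-study bootstrap)
#'   derive from it.
#' @param draws Bootstrap draws per study.
#' @param threshold Risk threshold for the low-risk dichotomy.
#' @param strategies Recalibration strategies to apply (subset of
#'   `c("a","b","c","d")`; `"a"` needs `derivation_intercepts`).
#' @param derivation_intercepts Passed to [recalibrate()] for strategy A.
#' @param se_method Per-study SE method, see [validate_studies()].
#' @param out_dir If non-`NULL`, [write_report()] is called on the result.
#' @return A `picnicc_report` list: `meta`, `advisory`, `performance`
#'   (per variant), `pooled` (per variant), `bivariate` (per variant),
#'   `recalibrations`, `coefficients`, `exclusions`.
#' @examples
#' \donttest{
#' rep <- run_validation(seed = 1, draws = 100, strategies = "d")
#' rep$pooled$raw$e_o_ratio
#' }
#' @export
run_validation <- function(episodes = NULL, config = NULL,
                           model = NULL, seed = NULL, draws = NULL,
                           threshold = NULL, strategies = NULL,
                           derivation_intercepts = NULL,
                           se_method = c("bootstrap", "analytic"),
                           out_dir = NULL) {
  se_method <- match.arg(se_method)
  cfg <- read_pipeline_config(config)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  draws <- as.integer(draws %||% cfg$draws %||% 2000L)
  threshold <- threshold %||% cfg$threshold %||% 0.10
  strategies <- strategies %||% cfg$strategies %||% c("b", "c", "d")
  strategies <- match.arg(strategies, c("a", "b", "c", "d"),
                          several.ok = TRUE)
  if (is.null(model)) {
    model <- if (!is.null(cfg$model)) load_model_spec(cfg$model)
             else picnicc_model()
  }
  if (is.null(episodes)) {
    if (!is.null(cfg$inputs)) {
      episodes <- bind_rows(lapply(unlist(cfg$inputs), function(p) {
        read_episodes(p, model = model)
      }))
    } else {
      syn_args <- cfg$synthetic %||% list()
      syn_args$seed <- study_seed(seed, 1)
      config_obj <- do.call(synthetic_config, syn_args)
      episodes <- generate_cohorts(config_obj, model = model)
    }
  } else {
    episodes <- validate_episodes(episodes, model = model)
  }
  advisory <- withCallingHandlers(
    check_event_count(episodes),
    picnicc_event_count = function(w) invokeRestart("muffleWarning")
  )
  warn_ledger <- character()
  if (!advisory$ok) {
    warn_ledger <- c(warn_ledger, paste0(
      "total events ", advisory$total_events,
      " below the advisory minimum of ", advisory$minimum
    ))
  }

  validate_variant <- function(data, model_or_null, seed_offset) {
    suppressMessages(suppressWarnings(validate_studies(
      data, model = model_or_null, threshold = threshold, draws = draws,
      seed = study_seed(seed, seed_offset), se_method = se_method
    )))
  }
  pool_variant <- function(perf) {
    usable <- filter(perf, .data$usable)
    if (nrow(usable) < 2) return(NULL)
    suppressWarnings(pool_performance(usable))
  }
  bivariate_variant <- function(perf) {
    tryCatch(
      suppressMessages(suppressWarnings(pool_sens_spec(perf))),
      error = function(e) NULL
    )
  }

  performance <- list()
  pooled <- list()
  bivariate <- list()
  recalibrations <- list()
  exclusions <- list()

  perf_raw <- validate_variant(episodes, model, 2)
  if (!any(perf_raw$usable)) {
    abort("No usable studies: every study failed validation.",
          class = "picnicc_pipeline_error")
  }
  performance$raw <- perf_raw
  pooled$raw <- pool_variant(perf_raw)
  bivariate$raw <- bivariate_variant(perf_raw)
  exclusions$raw <- attr(perf_raw, "exclusions")

  for (i in seq_along(strategies)) {
    st <- strategies[[i]]
    rec <- tryCatch(
      suppressMessages(suppressWarnings(recalibrate(
        episodes, model = model, strategy = st,
        derivation_intercepts = derivation_intercepts
      ))),
      error = function(e) {
        warn_ledger <<- c(
          warn_ledger,
          paste0("strategy ", toupper(st), " failed: ", conditionMessage(e))
        )
        NULL
      }
    )
    if (is.null(rec)) next
    recalibrations[[st]] <- rec
    rescored <- tryCatch(
      suppressWarnings(apply_recalibration(episodes, rec,
                                           threshold = threshold)),
      error = function(e) NULL
    )
    if (is.null(rescored)) next
    perf_st <- validate_variant(rescored, NULL, 2 + i)
    performance[[st]] <- perf_st
    pooled[[st]] <- pool_variant(perf_st)
    bivariate[[st]] <- bivariate_variant(perf_st)
    exclusions[[st]] <- attr(perf_st, "exclusions")
  }

  coefficients <- tryCatch(
    suppressWarnings(reestimate_coefficients(episodes, model = model)),
    error = function(e) {
      warn_ledger <<- c(
        warn_ledger,
        paste0("coefficient re-estimation failed: ", conditionMessage(e))
      )
      NULL
    }
  )

  report <- structure(
    list(
      meta = list(
        seed = seed, draws = draws, threshold = threshold,
        strategies = strategies, se_method = se_method,
        model = model$name,
        intercept_published = model$intercept_published,
        n_episodes = nrow(episodes),
        created = format(Sys.time(), tz = "UTC")
      ),
      advisory = advisory,
      performance = performance,
      pooled = pooled,
      bivariate = bivariate,
      recalibrations = recalibrations,
      coefficients = coefficients,
      exclusions = exclusions,
      warnings = warn_ledger
    ),
    class = "picnicc_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.picnicc_report <- function(x, ...) {
  cat("<picnicc_report> ", x$meta$n_episodes, " episodes, ",
      nrow(x$performance$raw), " studies, seed ", x$meta$seed, "\n", sep = "")
  cat("variants: ", paste(names(x$performance), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$pooled$raw)) {
    cat("raw pooled:\n")
    print(x$pooled$raw)
  }
  invisible(x)
}

report_body <- function(report) {
  pooled_rows <- imap(report$pooled, function(set, variant) {
    if (is.null(set)) return(NULL)
    bind_rows(lapply(set, tidy)) %>% mutate(variant = variant, .before = 1)
  }) %>% bind_rows()
  biv_rows <- imap(report$bivariate, function(b, variant) {
    if (is.null(b)) return(NULL)
    tidy(b) %>% mutate(variant = variant, .before = 1)
  }) %>% bind_rows()
  perf_rows <- imap(report$performance, function(p, variant) {
    as_tibble(p) %>% mutate(variant = variant, .before = 1)
  }) %>% bind_rows()
  excl_rows <- imap(report$exclusions, function(e, variant) {
    if (is.null(e) || nrow(e) == 0) return(NULL)
    e %>% mutate(variant = variant, .before = 1)
  }) %>% bind_rows()
  recal_rows <- imap(report$recalibrations, function(r, st) {
    r$adjustments %>% mutate(strategy = st, .before = 1)
  }) %>% bind_rows()
  list(
    settings = report$meta[setdiff(names(report$meta), "created")],
    advisory = report$advisory,
    performance = perf_rows,
    pooled = pooled_rows,
    bivariate = biv_rows,
    recalibration = recal_rows,
    coefficients = report$coefficients,
    exclusions = excl_rows,
    warnings = report$warnings
  )
}

#' Export a validation report bundle
#'
#' Writes `report.json` (everything except the timestamp-bearing
#' metadata, so identical runs give byte-identical bodies), forest-plot
#' data per pooled metric (`forest_<metric>.csv`: per-study estimate, CI
#' and weight plus pooled and prediction-interval rows), calibration-plot
#' data (`calibration.csv`), ROC-space data (`rocspace.csv`: per-study
#' crosshairs, pooled point, confidence and prediction ellipse
#' coordinates) and the coefficient comparison (`coefficients.csv`).
#'
#' @param report A `picnicc_report` from [run_validation()].
#' @param dir Output directory (created if needed).
#' @return Invisible vector of written paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "picnicc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  body <- report_body(report)
  p_json <- file.path(dir, "report.json")
  jsonlite::write_json(
    c(list(created = report$meta$created), body),
    p_json, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  paths <- c(paths, p_json)
  if (!is.null(report$pooled$raw)) {
    for (m in names(report$pooled$raw)) {
      pm <- report$pooled$raw[[m]]
      fp <- forest_data(pm)
      p_csv <- file.path(dir, paste0("forest_", m, ".csv"))
      readr::write_csv(fp, p_csv, na = "")
      paths <- c(paths, p_csv)
    }
  }
  calib <- attr(report$performance$raw, "calibration")
  if (!is.null(calib) && nrow(calib) > 0) {
    p_cal <- file.path(dir, "calibration.csv")
    readr::write_csv(calib, p_cal, na = "")
    paths <- c(paths, p_cal)
  }
  if (!is.null(report$bivariate$raw)) {
    p_roc <- file.path(dir, "rocspace.csv")
    readr::write_csv(rocspace_data(report$bivariate$raw), p_roc, na = "")
    paths <- c(paths, p_roc)
  }
  if (!is.null(report$coefficients)) {
    p_coef <- file.path(dir, "coefficients.csv")
    readr::write_csv(report$coefficients, p_coef, na = "")
    paths <- c(paths, p_coef)
  }
  invisible(paths)
}

#' Forest-plot data for a pooled result
#'
#' @param pooled A `picnicc_pooled`.
#' @return Tibble of per-study rows (natural-scale estimate, 95% CI,
#'   weight) followed by the pooled row and, when available, the 95%
#'   prediction-interval row.
#' @export
forest_data <- function(pooled) {
  stopifnot(inherits(pooled, "picnicc_pooled"))
  studies <- pooled$studies %>%
    mutate(
      row = "study",
      estimate = back_transform(.data$yi, pooled$scale),
      ci_lower = back_transform(.data$yi - 1.96 * sqrt(.data$vi),
                                pooled$scale),
      ci_upper = back_transform(.data$yi + 1.96 * sqrt(.data$vi),
                                pooled$scale)
    ) %>%
    select("row", "label", "estimate", "ci_lower", "ci_upper", "weight")
  pooled_row <- tibble(
    row = "pooled", label = paste0("RE pooled (", pooled$method, ")"),
    estimate = back_transform(pooled$estimate, pooled$scale),
    ci_lower = back_transform(pooled$ci_lower, pooled$scale),
    ci_upper = back_transform(pooled$ci_upper, pooled$scale),
    weight = 1
  )
  out <- bind_rows(studies, pooled_row)
  if (is.finite(pooled$pri_lower)) {
    out <- bind_rows(out, tibble(
      row = "prediction_interval", label = "95% PrI",
      estimate = back_transform(pooled$estimate, pooled$scale),
      ci_lower = back_transform(pooled$pri_lower, pooled$scale),
      ci_upper = back_transform(pooled$pri_upper, pooled$scale),
      weight = NA_real_
    ))
  }
  out %>% mutate(metric = pooled$metric, .before = 1)
}

#' ROC-space plot data for a bivariate pooled result
#'
#' @param biv A `picnicc_bivariate`.
#' @return Tibble with per-study points (and binomial CI crosshairs), the
#'   pooled point, and confidence/prediction ellipse coordinates, tagged
#'   by `part`.
#' @export
rocspace_data <- function(biv) {
  stopifnot(inherits(biv, "picnicc_bivariate"))
  studies <- biv$studies %>%
    mutate(
      part = "study",
      sens_lo = plogis(.data$logit_sens - 1.96 * sqrt(.data$v_sens)),
      sens_hi = plogis(.data$logit_sens + 1.96 * sqrt(.data$v_sens)),
      spec_lo = plogis(.data$logit_spec - 1.96 * sqrt(.data$v_spec)),
      spec_hi = plogis(.data$logit_spec + 1.96 * sqrt(.data$v_spec))
    ) %>%
    select("part", label = "study_id", "sens", "spec",
           "sens_lo", "sens_hi", "spec_lo", "spec_hi")
  pooled <- tibble(
    part = "pooled", label = "pooled",
    sens = biv$sens, spec = biv$spec,
    sens_lo = biv$sens_ci[1], sens_hi = biv$sens_ci[2],
    spec_lo = biv$spec_ci[1], spec_hi = biv$spec_ci[2]
  )
  ell <- bind_rows(
    suppressWarnings(roc_ellipse(biv, "confidence")),
    suppressWarnings(roc_ellipse(biv, "prediction"))
  ) %>%
    mutate(part = paste0("ellipse_", .data$type), label = .data$type) %>%
    select("part", "label", "sens", "spec")
  bind_rows(studies, pooled, ell)
}
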