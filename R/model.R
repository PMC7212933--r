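# The PICNICC model: published derivation log-odds-ratio coefficients,
# model constructor/validation, (de)serialisation, and episode scoring.

# Derivation-cohort coefficients (log ORs) and their SEs, as published.
# Extreme estimates for rare categories are preserved as published.
PICNICC_TUMOUR_COEFFS <- c(
  "Acute myeloid leukaemia"       = 0.65,
  "Ewing's sarcoma"               = -0.64,
  "Germ cell tumour"              = -0.07,
  "Hepatoblastoma"                = 0.48,
  "High-grade brain tumour"       = -0.34,
  "Hodgkin's lymphoma"            = -0.41,
  "High-risk neuroblastoma"       = 0.92,
  "Langerhans cell histiocytosis" = -14.1,
  "Low-grade brain tumour"        = -14.16,
  "Neuroblastoma"                 = 0.47,
  "Non-Hodgkin's lymphoma"        = -0.47,
  "Osteosarcoma"                  = -1.19,
  "Other tumour"                  = 0.8,
  "Retinoblastoma"                = 0.55,
  "Rhabdomyosarcoma"              = -0.24,
  "Sarcoma"                       = 0.19,
  "Wilms tumour"                  = -0.49
)

PICNICC_TUMOUR_SES <- c(
  "Acute myeloid leukaemia"       = 0.26,
  "Ewing's sarcoma"               = 0.66,
  "Germ cell tumour"              = 0.88,
  "Hepatoblastoma"                = 0.57,
  "High-grade brain tumour"       = 0.46,
  "Hodgkin's lymphoma"            = 0.7,
  "High-risk neuroblastoma"       = 0.66,
  "Langerhans cell histiocytosis" = 1025.44,
  "Low-grade brain tumour"        = 677.94,
  "Neuroblastoma"                 = 0.49,
  "Non-Hodgkin's lymphoma"        = 0.32,
  "Osteosarcoma"                  = 0.57,
  "Other tumour"                  = 0.77,
  "Retinoblastoma"                = 0.86,
  "Rhabdomyosarcoma"              = 0.32,
  "Sarcoma"                       = 0.82,
  "Wilms tumour"                  = 0.66
)

PICNICC_CONTINUOUS_COEFFS <- c(
  temp_coeff   = 0.57,
  unwell_coeff = 0.79,
  hb_coeff     = 0.18,
  ln_wcc_coeff = -0.3,
  ln_amc_coeff = -0.21
)

PICNICC_CONTINUOUS_SES <- c(
  temp_coeff   = 0.14,
  unwell_coeff = 0.19,
  hb_coeff     = 0.05,
  ln_wcc_coeff = 0.1,
  ln_amc_coeff = 0.06
)

# Human-readable labels used in serialised model specs and the coefficient
# comparison table.
PICNICC_TERM_LABELS <- c(
  temp_coeff   = "Temperature (per degC from 37)",
  unwell_coeff = "Clinical impression of 'Severely unwell'",
  hb_coeff     = "Haemoglobin (per g/dL)",
  ln_wcc_coeff = "Natural log (total white cell count)",
  ln_amc_coeff = "Natural log (absolute monocyte count)"
)

DEFAULT_REFERENCE_TUMOUR <- "Acute lymphoblastic leukaemia / other"

# The model intercept was never published. This placeholder is calibrated so
# that the default synthetic reference population has mean predicted risk of
# about 0.25 (roughly one MDI per four episodes, the prevalence scale the
# model operates on). Frozen once; see the methods vignette.
PICNICC_PLACEHOLDER_INTERCEPT <- -4.26

#' Construct a PICNICC model specification
#'
#' Builds the logistic model object used to score febrile-neutropenia
#' episodes: an intercept plus log-odds-ratio coefficients for tumour type
#' (17 named categories and one reference category fixed at 0), presentation
#' temperature (per degree Celsius above 37), the clinician impression
#' "severely unwell", haemoglobin (per g/dL), and the natural logs of the
#' total white cell count and absolute monocyte count.
#'
#' The packaged default carries the published derivation coefficients. The
#' derivation intercept was never published, so the default uses a
#' documented placeholder (chosen so the default synthetic reference
#' population has mean predicted risk of about 0.25) and says so once per
#' session; pass `intercept` explicitly to silence this, or recalibrate with
#' [recalibrate()].
#'
#' @param intercept Model intercept on the log-odds scale. `NULL` (default)
#'   uses the non-published placeholder.
#' @param tumour_coeffs Named numeric vector of tumour-type log odds ratios.
#'   Must not include the reference category; that is added with
#'   coefficient 0.
#' @param temp_coeff,unwell_coeff,hb_coeff,ln_wcc_coeff,ln_amc_coeff
#'   Scalar coefficients for the non-tumour covariates.
#' @param reference Label of the reference tumour category (coefficient 0).
#' @param name Text tag identifying the specification.
#'
#' @return An object of class `picnicc_model`.
#' @examples
#' m <- picnicc_model(intercept = -4.3)
#' m$tumour_coeffs[["Acute myeloid leukaemia"]]
#' @export
picnicc_model <- function(intercept = NULL,
                          tumour_coeffs = PICNICC_TUMOUR_COEFFS,
                          temp_coeff = 0.57,
                          unwell_coeff = 0.79,
                          hb_coeff = 0.18,
                          ln_wcc_coeff = -0.3,
                          ln_amc_coeff = -0.21,
                          reference = DEFAULT_REFERENCE_TUMOUR,
                          name = "PICNICC (derivation)") {
  intercept_published <- !is.null(intercept)
  if (is.null(intercept)) {
    intercept <- PICNICC_PLACEHOLDER_INTERCEPT
    inform(
      paste0(
        "Using placeholder intercept ", intercept,
        " (the derivation intercept was not published); ",
        "pass `intercept` or recalibrate to override."
      ),
      class = "picnicc_placeholder_intercept",
      .frequency = "once",
      .frequency_id = "picnicc_placeholder_intercept"
    )
  }
  if (is.null(names(tumour_coeffs)) || any(!nzchar(names(tumour_coeffs)))) {
    abort("`tumour_coeffs` must be a fully named numeric vector.")
  }
  if (reference %in% names(tumour_coeffs)) {
    if (tumour_coeffs[[reference]] != 0) {
      abort("The reference tumour category must have coefficient 0.")
    }
    tumour_coeffs <- tumour_coeffs[setdiff(names(tumour_coeffs), reference)]
  }
  coeffs <- c(
    tumour_coeffs,
    setNames(0, reference)
  )
  model <- structure(
    list(
      name = name,
      intercept = intercept,
      intercept_published = intercept_published,
      reference = reference,
      tumour_coeffs = coeffs,
      temp_coeff = temp_coeff,
      unwell_coeff = unwell_coeff,
      hb_coeff = hb_coeff,
      ln_wcc_coeff = ln_wcc_coeff,
      ln_amc_coeff = ln_amc_coeff
    ),
    class = "picnicc_model"
  )
  validate_model_spec(model)
}

validate_model_spec <- function(model) {
  scalar_fields <- c(
    "intercept", "temp_coeff", "unwell_coeff",
    "hb_coeff", "ln_wcc_coeff", "ln_amc_coeff"
  )
  for (f in scalar_fields) {
    v <- model[[f]]
    if (is.null(v) || length(v) != 1 || !is.numeric(v) || !is.finite(v)) {
      abort(
        paste0("Model field `", f, "` must be a single finite number."),
        class = "picnicc_model_error"
      )
    }
  }
  tc <- model$tumour_coeffs
  if (!is.numeric(tc) || any(!is.finite(tc))) {
    bad <- names(tc)[!is.finite(tc)]
    abort(
      paste0(
        "Non-finite tumour coefficient(s): ",
        paste(bad, collapse = ", ")
      ),
      class = "picnicc_model_error"
    )
  }
  n_ref <- sum(tc == 0 & names(tc) == model$reference)
  if (n_ref != 1) {
    abort(
      "Exactly one reference tumour category with coefficient 0 is required.",
      class = "picnicc_model_error"
    )
  }
  if (anyDuplicated(names(tc))) {
    abort("Duplicated tumour category labels.", class = "picnicc_model_error")
  }
  model
}

#' @export
print.picnicc_model <- function(x, ...) {
  cat("<picnicc_model> ", x$name, "\n", sep = "")
  cat(
    "  intercept: ", format(x$intercept),
    if (!x$intercept_published) " (placeholder, non-published)", "\n",
    sep = ""
  )
  cat("  reference tumour category: ", x$reference, "\n", sep = "")
  cat(
    "  ", length(x$tumour_coeffs) - 1L, " tumour coefficients + ",
    "temperature/unwell/Hb/ln(WCC)/ln(AMC)\n",
    sep = ""
  )
  invisible(x)
}

#' Tumour categories recognised by a model
#'
#' @param model A [picnicc_model()] object.
#' @return Character vector of valid `tumour_type` labels (reference
#'   category included).
#' @export
tumour_categories <- function(model = picnicc_model()) {
  names(model$tumour_coeffs)
}

#' Load a model specification from a file, list, or the packaged default
#'
#' Reads a model specification from a YAML or JSON config section whose keys
#' are the published coefficient labels (tumour category names plus
#' "Temperature (per degC from 37)", "Clinical impression of 'Severely
#' unwell'", "Haemoglobin (per g/dL)", "Natural log (total white cell
#' count)", "Natural log (absolute monocyte count)"), an `intercept`, and
#' optionally `name` and `reference`. Missing coefficients, unknown tumour
#' categories and non-finite values raise a load error naming the field.
#'
#' @param source `"default"` for the packaged derivation model, a path to a
#'   YAML/JSON file, or a named list with the same structure.
#' @return A validated [picnicc_model()].
#' @export
load_model_spec <- function(source = "default") {
  if (is.character(source) && length(source) == 1 && source == "default") {
    return(picnicc_model())
  }
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      abort(paste0("Model spec file not found: ", source))
    }
    source <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(source)
    }
  }
  if (!is.list(source)) {
    abort("`source` must be \"default\", a file path, or a named list.")
  }
  spec_from_list(source)
}

spec_from_list <- function(x) {
  get_num <- function(key, field) {
    v <- x[[key]]
    if (is.null(v)) {
      abort(
        paste0("Model spec is missing `", field, "` (key \"", key, "\")."),
        class = "picnicc_spec_error"
      )
    }
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 1 || is.na(v)) {
      abort(
        paste0("Model spec field `", field, "` is not a finite number."),
        class = "picnicc_spec_error"
      )
    }
    v
  }
  reference <- x[["reference"]] %||% DEFAULT_REFERENCE_TUMOUR
  known_keys <- c(
    names(PICNICC_TUMOUR_COEFFS), unname(PICNICC_TERM_LABELS),
    "intercept", "name", "reference", reference
  )
  extra <- setdiff(names(x), known_keys)
  if (length(extra) > 0) {
    abort(
      paste0(
        "Unknown tumour category or field in model spec: ",
        paste(extra, collapse = ", ")
      ),
      class = "picnicc_spec_error"
    )
  }
  tumour <- vapply(
    names(PICNICC_TUMOUR_COEFFS),
    function(k) get_num(k, paste0("tumour_coeffs[", k, "]")),
    numeric(1)
  )
  picnicc_model(
    intercept = get_num("intercept", "intercept"),
    tumour_coeffs = tumour,
    temp_coeff = get_num(PICNICC_TERM_LABELS[["temp_coeff"]], "temp_coeff"),
    unwell_coeff = get_num(PICNICC_TERM_LABELS[["unwell_coeff"]], "unwell_coeff"),
    hb_coeff = get_num(PICNICC_TERM_LABELS[["hb_coeff"]], "hb_coeff"),
    ln_wcc_coeff = get_num(PICNICC_TERM_LABELS[["ln_wcc_coeff"]], "ln_wcc_coeff"),
    ln_amc_coeff = get_num(PICNICC_TERM_LABELS[["ln_amc_coeff"]], "ln_amc_coeff"),
    reference = reference,
    name = x[["name"]] %||% "custom"
  )
}

#' Serialise a model specification
#'
#' Writes a model spec as YAML or JSON using the published coefficient
#' labels as keys, so that [load_model_spec()] round-trips it.
#'
#' @param model A [picnicc_model()].
#' @param path Output file; format chosen by extension (`.json` or YAML
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "picnicc_model"))
  tc <- model$tumour_coeffs
  tc <- tc[setdiff(names(tc), model$reference)]
  out <- c(
    list(
      name = model$name,
      reference = model$reference,
      intercept = model$intercept
    ),
    as.list(tc),
    setNames(
      list(
        model$temp_coeff, model$unwell_coeff, model$hb_coeff,
        model$ln_wcc_coeff, model$ln_amc_coeff
      ),
      unname(PICNICC_TERM_LABELS)
    )
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

# Vectorised linear predictor. Assumes covariates validated and complete;
# rows with any missing covariate return NA (the caller decides whether
# that is a complete-case exclusion or an error).
picnicc_lp <- function(model, tumour_type, temperature, severely_unwell,
                       haemoglobin, wcc, amc, count_floor = 0.005) {
  unknown <- setdiff(unique(tumour_type[!is.na(tumour_type)]),
                     names(model$tumour_coeffs))
  if (length(unknown) > 0) {
    abort(
      paste0(
        "Unknown tumour_type label(s): ",
        paste(unknown, collapse = ", ")
      ),
      class = "picnicc_domain_error"
    )
  }
  if (any(wcc < 0, na.rm = TRUE) || any(amc < 0, na.rm = TRUE)) {
    abort("wcc and amc must be non-negative.", class = "picnicc_domain_error")
  }
  n_floor <- sum(wcc == 0, na.rm = TRUE) + sum(amc == 0, na.rm = TRUE)
  if (n_floor > 0) {
    warn(
      paste0(
        n_floor, " zero count value(s) substituted with ", count_floor,
        " x 10^9/L before taking logs."
      ),
      class = "picnicc_zero_count"
    )
    wcc <- ifelse(!is.na(wcc) & wcc == 0, count_floor, wcc)
    amc <- ifelse(!is.na(amc) & amc == 0, count_floor, amc)
  }
  tum <- unname(model$tumour_coeffs[tumour_type])
  model$intercept +
    tum +
    model$temp_coeff * (temperature - 37) +
    model$unwell_coeff * as.numeric(severely_unwell) +
    model$hb_coeff * haemoglobin +
    model$ln_wcc_coeff * log(wcc) +
    model$ln_amc_coeff * log(amc)
}

#' Score febrile-neutropenia episodes with a PICNICC model
#'
#' Computes, for every episode row, the linear predictor (`lp`, log-odds
#' scale), the predicted probability of microbiologically documented
#' infection (`risk`), and the low-risk classification at the chosen
#' threshold (`low_risk`, inclusive: risk less than or equal to the
#' threshold is low risk). Rows with a missing model covariate get `NA`
#' scores and are reported as complete-case exclusions; they are kept in
#' the output so downstream filtering is explicit.
#'
#' Zero white-cell or monocyte counts (where the log is undefined) are
#' substituted by `count_floor`, half the smallest routinely reported assay
#' value, with a warning.
#'
#' @param data Episode data frame with columns `tumour_type`, `temperature`,
#'   `severely_unwell`, `haemoglobin`, `wcc`, `amc` (and usually `study_id`,
#'   `mdi`).
#' @param model A [picnicc_model()].
#' @param threshold Risk threshold for the low-risk call (default 0.10).
#' @param count_floor Substitute for zero `wcc`/`amc` before the log
#'   transform, in 10^9/L.
#' @return The input as a tibble with `lp`, `risk` and `low_risk` columns
#'   appended.
#' @examples
#' cohort <- generate_cohorts(synthetic_config(seed = 1))
#' scored <- score_episodes(cohort, picnicc_model(intercept = -4.3))
#' head(scored[, c("study_id", "lp", "risk", "low_risk")])
#' @export
score_episodes <- function(data, model = picnicc_model(), threshold = 0.10,
                           count_floor = 0.005) {
  data <- as_tibble(data)
  needed <- c(
    "tumour_type", "temperature", "severely_unwell",
    "haemoglobin", "wcc", "amc"
  )
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "Episode data is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      )
    )
  }
  lp <- picnicc_lp(
    model,
    tumour_type = data$tumour_type,
    temperature = data$temperature,
    severely_unwell = data$severely_unwell,
    haemoglobin = data$haemoglobin,
    wcc = data$wcc,
    amc = data$amc,
    count_floor = count_floor
  )
  n_incomplete <- sum(is.na(lp))
  if (n_incomplete > 0) {
    inform(
      paste0(
        n_incomplete, " episode(s) have a missing model covariate; ",
        "their scores are NA (complete-case exclusions)."
      ),
      class = "picnicc_incomplete_cases"
    )
  }
  data$lp <- lp
  data$risk <- plogis(lp)
  data$low_risk <- classify_low_risk(data$risk, threshold)
  data
}

#' Classify predicted risks as low risk at a threshold
#'
#' The boundary is inclusive: a predicted risk exactly at the threshold is
#' called low risk, matching a rule phrased as "at or below 10% chance".
#'
#' @param risk Numeric vector of predicted probabilities.
#' @param threshold Probability threshold in (0, 1).
#' @return Logical vector, `TRUE` where `risk <= threshold`.
#' @export
classify_low_risk <- function(risk, threshold = 0.10) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single probability strictly inside (0, 1).")
  }
  risk <= threshold
}
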