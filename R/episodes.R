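# Episode-table I/O and validation: closed tumour-category list,
# physiological temperature bounds, unit declaration for haemoglobin,
# complete-case filtering with per-field accounting.

EPISODE_COLUMNS <- c(
  "study_id", "patient_id", "tumour_type", "temperature",
  "severely_unwell", "haemoglobin", "wcc", "amc", "mdi"
)

MODEL_COVARIATES <- c(
  "tumour_type", "temperature", "severely_unwell", "haemoglobin",
  "wcc", "amc"
)

#' Validate an episode table
#'
#' Checks one-row-per-episode data against the model's domain: tumour
#' types drawn from the closed category list, temperature inside a
#' physiological range, non-negative cell counts, binary (or missing)
#' severely-unwell flag and MDI outcome, and haemoglobin declared in g/dL
#' (mmol/L input is rejected rather than converted). Missing values are
#' allowed in any field; they are handled later by [complete_cases()].
#'
#' @param data Episode data frame.
#' @param model A [picnicc_model()] supplying the tumour category list.
#' @param temperature_range Permitted temperature bounds in Celsius.
#' @param hb_units Unit declaration for the haemoglobin column; only
#'   `"g/dL"` is accepted.
#' @return The validated data as a tibble (invisibly usable in a pipe).
#' @export
validate_episodes <- function(data, model = picnicc_model(),
                              temperature_range = c(34, 43),
                              hb_units = "g/dL") {
  data <- as_tibble(data)
  if (!identical(hb_units, "g/dL")) {
    abort(
      paste0(
        "Haemoglobin must be supplied in g/dL (got \"", hb_units,
        "\"); convert before loading, no unit conversion is performed."
      ),
      class = "picnicc_load_error"
    )
  }
  required <- setdiff(EPISODE_COLUMNS, "patient_id")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "Episode table is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "picnicc_load_error"
    )
  }
  fail <- function(msg) abort(msg, class = "picnicc_load_error")

  bad_tumour <- setdiff(
    unique(data$tumour_type[!is.na(data$tumour_type)]),
    tumour_categories(model)
  )
  if (length(bad_tumour) > 0) {
    fail(paste0(
      "Unknown tumour_type label(s): ", paste(bad_tumour, collapse = ", ")
    ))
  }
  t_bad <- !is.na(data$temperature) &
    (data$temperature < temperature_range[1] |
       data$temperature > temperature_range[2])
  if (any(t_bad)) {
    fail(paste0(
      sum(t_bad), " episode(s) with temperature outside [",
      temperature_range[1], ", ", temperature_range[2], "] degC."
    ))
  }
  if (any(data$haemoglobin <= 0, na.rm = TRUE)) {
    fail("haemoglobin must be positive (g/dL).")
  }
  if (any(data$wcc < 0, na.rm = TRUE) || any(data$amc < 0, na.rm = TRUE)) {
    fail("wcc and amc must be non-negative (10^9/L).")
  }
  for (col in c("severely_unwell", "mdi")) {
    v <- data[[col]]
    if (!all(v %in% c(0, 1, NA))) {
      fail(paste0("`", col, "` must be 0, 1 or missing."))
    }
  }
  data
}

#' Read an episode CSV
#'
#' Reads a delimited episode table (one row per episode, canonical column
#' names, empty fields as missing) and validates it with
#' [validate_episodes()].
#'
#' @inheritParams validate_episodes
#' @param path CSV file path.
#' @return A validated episode tibble.
#' @export
read_episodes <- function(path, model = picnicc_model(),
                          temperature_range = c(34, 43),
                          hb_units = "g/dL") {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = readr::col_character(),
      patient_id = readr::col_character(),
      tumour_type = readr::col_character(),
      temperature = readr::col_double(),
      severely_unwell = readr::col_double(),
      haemoglobin = readr::col_double(),
      wcc = readr::col_double(),
      amc = readr::col_double(),
      mdi = readr::col_double(),
      .default = readr::col_guess()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
  validate_episodes(
    data,
    model = model,
    temperature_range = temperature_range,
    hb_units = hb_units
  )
}

#' Keep complete cases for model validation
#'
#' Retains exactly the rows with all model covariates and the MDI outcome
#' present, reporting how many rows each field removed. An empty result is
#' allowed (the caller flags the study as unusable and continues).
#'
#' @param data Episode data frame.
#' @param quiet Suppress the per-field drop message.
#' @return Filtered tibble; attribute `"dropped"` holds a tibble of
#'   per-field missing counts among the removed rows.
#' @export
complete_cases <- function(data, quiet = FALSE) {
  data <- as_tibble(data)
  fields <- intersect(c(MODEL_COVARIATES, "mdi"), names(data))
  ok <- rep(TRUE, nrow(data))
  for (f in fields) ok <- ok & !is.na(data[[f]])
  dropped <- data[!ok, , drop = FALSE]
  per_field <- tibble(
    field = fields,
    n_missing = vapply(fields, function(f) sum(is.na(dropped[[f]])), integer(1))
  )
  if (!quiet && nrow(dropped) > 0) {
    msg <- paste0(
      "Dropped ", nrow(dropped), "/", nrow(data),
      " incomplete episode(s): ",
      paste0(
        per_field$field[per_field$n_missing > 0], " (",
        per_field$n_missing[per_field$n_missing > 0], ")",
        collapse = ", "
      )
    )
    inform(msg, class = "picnicc_complete_cases")
  }
  out <- data[ok, , drop = FALSE]
  attr(out, "dropped") <- per_field
  out
}
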