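# Shared fixtures, built in code and cached per test run.

quiet_model <- function(...) suppressMessages(picnicc_model(...))

# Quarter-scale seven-study config: same structure, faster tests.
small_config <- function(seed = 11, ...) {
  synthetic_config(
    n_episodes = as.integer(ceiling(c(48, 47, 167, 121, 27, 101, 648) / 4)),
    n_patients = as.integer(ceiling(c(27, 21, 47, 63, 16, 54, 327) / 4)),
    seed = seed,
    ...
  )
}

# Single-study correct-specification config (outcomes drawn from the
# model's own risks).
correct_spec_config <- function(n = 5000L, seed = 21) {
  synthetic_config(
    study_ids = "sim", n_episodes = as.integer(n),
    n_patients = as.integer(ceiling(n / 2)), mdi_targets = 0.25,
    group_mix = c(leukaemia = 0.52, lymphoma = 0.09,
                  solid = 0.31, brain = 0.08),
    lambda = 1, delta = 0, calibrate_targets = FALSE, seed = seed
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_cohort <- function() {
  cached("default_cohort", generate_cohorts(synthetic_config(seed = 1)))
}

small_cohort <- function() {
  cached("small_cohort", generate_cohorts(small_config()))
}

small_perf <- function() {
  cached(
    "small_perf",
    suppressWarnings(suppressMessages(validate_studies(
      small_cohort(), quiet_model(), draws = 200, seed = 5
    )))
  )
}

# A hand-built episode table with known values for loader tests.
toy_episodes <- function() {
  tibble::tibble(
    study_id = rep("toy", 6),
    patient_id = paste0("P", 1:6),
    tumour_type = c(
      "Acute lymphoblastic leukaemia / other", "Acute myeloid leukaemia",
      "Wilms tumour", "Osteosarcoma", "Neuroblastoma",
      "High-grade brain tumour"
    ),
    temperature = c(38.0, 38.5, 39.2, 38.1, 40.0, 38.8),
    severely_unwell = c(0, 1, 0, 0, 1, 0),
    haemoglobin = c(9.1, 10.4, 8.0, 11.2, 7.5, 9.9),
    wcc = c(1.2, 0.4, 2.5, 0.9, 1.8, 0.6),
    amc = c(0.10, 0.02, 0.50, 0.08, 0.30, 0.05),
    mdi = c(0, 1, 0, 0, 1, 0)
  )
}
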