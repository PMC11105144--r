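#' Default synthetic feature specification
#'
#' Describes the 30 non-race features of the synthetic delivery cohort:
#' 25 binary clinical indicators grouped into mental-health history,
#' comorbidity, obstetric and medication categories, and 5 standardized
#' continuous demographic features. Each feature carries its baseline
#' level among White subjects (`baseline`: a prevalence for binary
#' features, a mean for continuous ones), its true log-odds effect on the
#' PPD outcome (`beta`), and a proxy direction (`proxy_dir`) stating how
#' the cohort profile's `proxy_strength` shifts the feature among
#' Non-White subjects (-1 lowers it, +1 raises it, 0 leaves it alone).
#'
#' Care-access-related features (documented mental-health history,
#' psychotherapy, SSRI prescriptions, prenatal visit counts) are proxy
#' features shifted downward for Non-White subjects, emulating the
#' underdocumentation patterns that keep group disparity alive after race
#' itself is removed from a model; a few comorbidity features and area
#' deprivation shift upward. Effect sizes are deliberately strong so that
#' a logistic model on these features lands in the discrimination regime
#' reported for deployed PPD risk models (AUC around 0.95).
#'
#' @return A tibble with columns `name`, `category`,
#'   `type` (`"binary"` or `"continuous"`), `baseline`, `beta`, `proxy_dir`.
#' @export
#' @examples
#' default_feature_spec()
default_feature_spec <- function() {
  tibble::tribble(
    ~name,                 ~category,       ~type,        ~baseline, ~beta, ~proxy_dir,
    "hx_depression",       "mental_health", "binary",     0.12, 5.06, -1,
    "hx_anxiety",          "mental_health", "binary",     0.15, 3.68, -1,
    "hx_mood_disorder",    "mental_health", "binary",     0.06, 4.14,  0,
    "hx_prior_ppd",        "mental_health", "binary",     0.04, 5.98,  0,
    "hx_psychotherapy",    "mental_health", "binary",     0.10, 2.76, -1,
    "hx_substance_use",    "mental_health", "binary",     0.03, 2.30,  0,
    "cm_diabetes",         "comorbidity",   "binary",     0.08, 0.92,  0,
    "cm_hypertension",     "comorbidity",   "binary",     0.10, 0.92,  1,
    "cm_thyroid_disorder", "comorbidity",   "binary",     0.07, 0.69,  0,
    "cm_obesity",          "comorbidity",   "binary",     0.20, 0.69,  1,
    "cm_anemia",           "comorbidity",   "binary",     0.18, 0.46,  1,
    "cm_migraine",         "comorbidity",   "binary",     0.09, 0.92,  0,
    "cm_autoimmune",       "comorbidity",   "binary",     0.03, 0.69,  0,
    "ob_cesarean",         "obstetric",     "binary",     0.30, 0.92,  0,
    "ob_preterm_birth",    "obstetric",     "binary",     0.09, 1.38,  0,
    "ob_preeclampsia",     "obstetric",     "binary",     0.05, 1.61,  0,
    "ob_multiple_gest",    "obstetric",     "binary",     0.03, 1.15,  0,
    "ob_nicu_admission",   "obstetric",     "binary",     0.08, 1.15,  0,
    "ob_labor_complic",    "obstetric",     "binary",     0.15, 0.92,  0,
    "rx_ssri",             "medication",    "binary",     0.08, 4.14, -1,
    "rx_benzodiazepine",   "medication",    "binary",     0.04, 2.76,  0,
    "rx_opioid",           "medication",    "binary",     0.12, 1.15,  0,
    "rx_antiemetic",       "medication",    "binary",     0.25, 0.69,  0,
    "rx_insulin",          "medication",    "binary",     0.04, 0.92,  0,
    "rx_antihypertensive", "medication",    "binary",     0.06, 0.92,  0,
    "age_std",             "demographic",   "continuous", 0.00, 0.81,  0,
    "bmi_std",             "demographic",   "continuous", 0.00, 0.58,  0,
    "parity_std",          "demographic",   "continuous", 0.00, 0.46,  0,
    "prenatal_visits_std", "demographic",   "continuous", 0.00, 0.69, -1,
    "area_deprivation_std","demographic",   "continuous", 0.00, 0.58,  1
  )
}

#' Race categories used throughout the package
#' @return Character vector of the five race categories, White first.
#' @export
race_levels <- function() c("White", "Asian", "Black", "Other", "Unknown")

#' Construct a synthetic cohort profile
#'
#' A cohort profile is the full recipe for a synthetic delivery cohort:
#' its size, race distribution, target overall PPD prevalence, target
#' Non-White/White prevalence rate ratio, the true feature effects, and
#' the strength of race-correlated proxy shifts.
#'
#' @param name Label for the profile.
#' @param n_subjects Number of deliveries to simulate.
#' @param race_probs Named numeric vector of probabilities over
#'   `race_levels()` (White, Asian, Black, Other, Unknown); must sum to 1.
#' @param target_prevalence Overall outcome prevalence in (0, 1).
#' @param target_rate_ratio Target Non-White/White outcome prevalence
#'   ratio (positive), computed on observed race with Unknown grouped as
#'   Non-White.
#' @param feature_spec Feature table as from [default_feature_spec()];
#'   its `beta` column holds the true per-feature log-odds effects.
#' @param proxy_strength Non-negative scalar; log-odds (binary) or
#'   half-unit mean (continuous) shift applied to proxy features for
#'   Non-White subjects.
#' @param seed Integer seed used by [generate_cohort()] unless overridden.
#' @return An object of class `cohort_profile`.
#' @export
#' @examples
#' dataset_profile("amc2019")
cohort_profile <- function(name,
                           n_subjects,
                           race_probs,
                           target_prevalence,
                           target_rate_ratio,
                           feature_spec = default_feature_spec(),
                           proxy_strength = 0.8,
                           seed = 1L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects <= 0) {
    abort("`n_subjects` must be a single positive count.")
  }
  race_probs <- race_probs[race_levels()]
  if (anyNA(race_probs)) {
    abort(paste0("`race_probs` must be named with exactly: ",
                 paste(race_levels(), collapse = ", ")))
  }
  if (any(race_probs < 0) || abs(sum(race_probs) - 1) > 1e-9) {
    abort("`race_probs` must be non-negative and sum to 1 (within 1e-9).")
  }
  if (!(target_prevalence > 0 && target_prevalence < 1)) {
    abort("`target_prevalence` must lie strictly in (0, 1).")
  }
  if (!(target_rate_ratio > 0)) abort("`target_rate_ratio` must be positive.")
  if (proxy_strength < 0) abort("`proxy_strength` must be non-negative.")
  req <- c("name", "category", "type", "baseline", "beta", "proxy_dir")
  if (!all(req %in% names(feature_spec))) {
    abort("`feature_spec` is missing required columns.")
  }
  structure(
    list(
      name = name,
      n_subjects = as.integer(n_subjects),
      race_probs = race_probs,
      target_prevalence = target_prevalence,
      target_rate_ratio = target_rate_ratio,
      n_features = nrow(feature_spec),
      feature_spec = as_tibble(feature_spec),
      proxy_strength = proxy_strength,
      seed = as.integer(seed)
    ),
    class = "cohort_profile"
  )
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile> ", x$name, "\n", sep = "")
  cat("  n_subjects:        ", x$n_subjects, "\n", sep = "")
  cat("  target_prevalence: ", x$target_prevalence, "\n", sep = "")
  cat("  target_rate_ratio: ", x$target_rate_ratio, " (Non-White / White)\n", sep = "")
  cat("  race_probs:        ",
      paste(sprintf("%s=%.3f", names(x$race_probs), x$race_probs), collapse = " "),
      "\n", sep = "")
  cat("  features:          ", x$n_features,
      " (proxy_strength = ", x$proxy_strength, ")\n", sep = "")
  invisible(x)
}

# Race composition of the three published dataset profiles, as counts so
# the probabilities sum to exactly 1.
.dataset_profiles <- list(
  amc2019 = list(
    n = 8007L, prevalence = 0.098, rate_ratio = 0.476,
    race_counts = c(White = 3557, Asian = 1747, Black = 555, Other = 1281, Unknown = 867)
  ),
  amc2020 = list(
    n = 9623L, prevalence = 0.146, rate_ratio = 0.637,
    race_counts = c(White = 4006, Asian = 1190, Black = 872, Other = 2140, Unknown = 1415)
  ),
  crn = list(
    n = 37673L, prevalence = 0.115, rate_ratio = 1.005,
    race_counts = c(White = 12301, Asian = 2824, Black = 5168, Other = 7784, Unknown = 9596)
  )
)

#' Cohort profiles for the three published dataset profiles
#'
#' Returns the profile of one of the three evaluation datasets of the
#' study this package re-implements: an academic medical center's 2019
#' and 2020 delivery cohorts and a multi-site clinical research network
#' cohort. Sample size, PPD prevalence, five-level race composition and
#' the observed Non-White/White prevalence rate ratio are transcribed
#' from the published cohort characteristics; the true feature effects
#' are the package defaults documented in [default_feature_spec()].
#'
#' @param dataset_name One of `"amc2019"`, `"amc2020"`, `"crn"`.
#' @param proxy_strength,seed Passed to [cohort_profile()].
#' @return A `cohort_profile`.
#' @export
#' @examples
#' dataset_profile("crn")
dataset_profile <- function(dataset_name, proxy_strength = 0.8, seed = 1L) {
  if (!is.character(dataset_name) || length(dataset_name) != 1L ||
      !dataset_name %in% names(.dataset_profiles)) {
    abort(paste0("Unknown dataset name. Supported labels: ",
                 paste(names(.dataset_profiles), collapse = ", "), "."))
  }
  p <- .dataset_profiles[[dataset_name]]
  cohort_profile(
    name = dataset_name,
    n_subjects = p$n,
    race_probs = p$race_counts / sum(p$race_counts),
    target_prevalence = p$prevalence,
    target_rate_ratio = p$rate_ratio,
    proxy_strength = proxy_strength,
    seed = seed
  )
}

#' Read and write cohort profiles as YAML or JSON
#'
#' The on-disk form holds every profile field, including the full feature
#' table, so a profile round-trips exactly. The format is chosen from the
#' file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param profile A `cohort_profile`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `cohort_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cohort_profile"))
  x <- list(
    name = profile$name,
    n_subjects = profile$n_subjects,
    race_probs = as.list(profile$race_probs),
    target_prevalence = profile$target_prevalence,
    target_rate_ratio = profile$target_rate_ratio,
    proxy_strength = profile$proxy_strength,
    seed = profile$seed,
    feature_spec = lapply(seq_len(nrow(profile$feature_spec)), function(i) {
      as.list(profile$feature_spec[i, ])
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("Profile path must end in .yaml, .yml or .json.")
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    abort("Profile path must end in .yaml, .yml or .json.")
  }
  fs <- dplyr::bind_rows(lapply(x$feature_spec, as_tibble))
  cohort_profile(
    name = x$name,
    n_subjects = x$n_subjects,
    race_probs = unlist(x$race_probs),
    target_prevalence = x$target_prevalence,
    target_rate_ratio = x$target_rate_ratio,
    feature_spec = fs,
    proxy_strength = x$proxy_strength,
    seed = x$seed
  )
}
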