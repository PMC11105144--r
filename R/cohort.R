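# Covariate and race drawing shared by calibration and generation.
# Unknown race is a label-masking event independent of everything else: a
# latent race is drawn from the four known categories (renormalized), the
# mask is applied with the profile's Unknown probability, and features and
# outcome risk depend on the latent race only.
draw_covariates <- function(n, profile) {
  fs <- profile$feature_spec
  rp <- profile$race_probs
  known <- race_levels()[1:4]
  p_known <- rp[known] / sum(rp[known])
  latent <- sample(known, n, replace = TRUE, prob = p_known)
  masked <- runif(n) < rp[["Unknown"]]
  race <- ifelse(masked, "Unknown", latent)
  nw_latent <- latent != "White"

  X <- matrix(0, n, nrow(fs), dimnames = list(NULL, fs$name))
  for (j in seq_len(nrow(fs))) {
    shift <- fs$proxy_dir[j] * profile$proxy_strength
    if (fs$type[j] == "binary") {
      p_j <- plogis(qlogis(fs$baseline[j]) + shift * nw_latent)
      X[, j] <- rbinom(n, 1L, p_j)
    } else {
      mu_j <- fs$baseline[j] + 0.5 * shift * nw_latent
      X[, j] <- rnorm(n, mu_j, 1)
    }
  }
  list(X = X, race = factor(race, levels = race_levels()), nw_latent = nw_latent)
}

.calibration_cache <- new.env(parent = emptyenv())

#' Calibrate generator intercept and Non-White offset for a profile
#'
#' Finds the logistic base intercept and the Non-White log-odds offset
#' under which the generator's expected overall outcome prevalence equals
#' the profile's `target_prevalence` and the expected Non-White/White
#' prevalence ratio (on observed race, Unknown grouped as Non-White)
#' equals `target_rate_ratio`. Expectations are taken over a covariate
#' sample of size `n_calib` drawn with a fixed internal seed, so the
#' result is deterministic given the profile; the outcome itself is never
#' drawn during calibration (risks are averaged analytically through the
#' logistic link), making the estimated prevalences smooth, monotone
#' functions of the two unknowns and the nested root-finding exact to
#' `tol`.
#'
#' @param profile A `cohort_profile`.
#' @param n_calib Size of the internal covariate sample (default 200000).
#' @param calib_seed Fixed internal seed for the covariate sample.
#' @param tol Root-finding tolerance on prevalence and rate ratio.
#' @return A list of class `cohort_offsets` with elements
#'   `base_intercept`, `nonwhite_offset`, `achieved_prevalence`,
#'   `achieved_rate_ratio` (the latter two on the calibration sample).
#' @export
#' @examples
#' \donttest{
#' calibrate_offsets(dataset_profile("amc2019"))
#' }
calibrate_offsets <- function(profile, n_calib = 200000L,
                              calib_seed = 987L, tol = 1e-6) {
  stopifnot(inherits(profile, "cohort_profile"))
  # calibration is deterministic in these inputs, so memoize it
  key <- rlang::hash(list(profile$race_probs, profile$target_prevalence,
                          profile$target_rate_ratio, profile$proxy_strength,
                          profile$feature_spec, n_calib, calib_seed, tol))
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  # Feasibility: implied group prevalences must both lie in (0, 1).
  s_w <- prevalence_share_white(profile)
  p_w <- profile$target_prevalence / (s_w + (1 - s_w) * profile$target_rate_ratio)
  p_u <- p_w * profile$target_rate_ratio
  if (p_w >= 1 || p_u >= 1) {
    abort(sprintf(paste0(
      "Targets are infeasible: prevalence %.3f with rate ratio %.3f implies ",
      "group prevalences White=%.3f, Non-White=%.3f."),
      profile$target_prevalence, profile$target_rate_ratio, p_w, p_u))
  }

  cov <- withr::with_seed(calib_seed, draw_covariates(n_calib, profile))
  eta0 <- drop(cov$X %*% profile$feature_spec$beta)
  white_obs <- cov$race == "White"

  mean_risk <- function(b0, off) plogis(b0 + eta0 + off * cov$nw_latent)
  solve_b0 <- function(off) {
    uniroot(function(b0) mean(mean_risk(b0, off)) - profile$target_prevalence,
            interval = c(-30, 15), tol = tol / 10)$root
  }
  ratio_at <- function(off) {
    p <- mean_risk(solve_b0(off), off)
    mean(p[!white_obs]) / mean(p[white_obs])
  }
  off <- tryCatch(
    uniroot(function(o) ratio_at(o) - profile$target_rate_ratio,
            interval = c(-8, 8), tol = tol)$root,
    error = function(e) abort(paste0(
      "Could not reach the target rate ratio ", profile$target_rate_ratio,
      " with any Non-White offset in [-8, 8]: ", conditionMessage(e)))
  )
  b0 <- solve_b0(off)
  p <- mean_risk(b0, off)
  out <- structure(
    list(
      base_intercept = b0,
      nonwhite_offset = off,
      achieved_prevalence = mean(p),
      achieved_rate_ratio = mean(p[!white_obs]) / mean(p[white_obs])
    ),
    class = "cohort_offsets"
  )
  .calibration_cache[[key]] <- out
  out
}

# Share of subjects observed as White (Unknown is grouped as Non-White).
# Latent race is drawn from the four known categories renormalized and then
# masked uniformly, so the observed White share equals race_probs["White"].
prevalence_share_white <- function(profile) {
  profile$race_probs[["White"]]
}

# Solve only the intercept for a different target prevalence while keeping
# a fixed Non-White offset (used for development cohorts that share the
# evaluation profile's disparity mechanism).
solve_intercept <- function(profile, nonwhite_offset, target_prevalence,
                            n_calib = 200000L, calib_seed = 987L) {
  cov <- withr::with_seed(calib_seed, draw_covariates(n_calib, profile))
  eta0 <- drop(cov$X %*% profile$feature_spec$beta)
  uniroot(function(b0) {
    mean(plogis(b0 + eta0 + nonwhite_offset * cov$nw_latent)) - target_prevalence
  }, interval = c(-30, 15), tol = 1e-7)$root
}

#' Generate a synthetic delivery cohort
#'
#' Draws race from the profile's race distribution, features from
#' race-conditional distributions (proxy features shifted for Non-White
#' subjects by the profile's `proxy_strength`), and the binary PPD
#' outcome from a logistic model with the calibrated base intercept,
#' the true feature effects, and the calibrated Non-White log-odds
#' offset. Identical profile and seed give an identical cohort.
#'
#' @param profile A `cohort_profile`.
#' @param n Optional override of the profile's `n_subjects`.
#' @param seed Optional override of the profile's seed.
#' @param offsets Optional precomputed result of [calibrate_offsets()]
#'   (calibrated on the fly when omitted); pass these when generating
#'   many cohorts from one profile.
#' @return A tibble of class `ppd_cohort`: one row per delivery with the
#'   30 feature columns, `race` (factor over five categories), `outcome`
#'   (0/1 integer) and `weight` (1). Attributes record the profile name,
#'   seed, feature names and offsets used.
#' @export
#' @examples
#' prof <- dataset_profile("amc2019")
#' cohort <- generate_cohort(prof, n = 500)
#' dplyr::count(cohort, race, outcome)
generate_cohort <- function(profile, n = NULL, seed = NULL, offsets = NULL) {
  stopifnot(inherits(profile, "cohort_profile"))
  n <- n %||% profile$n_subjects
  if (n <= 0) abort("`n` must be a positive count.")
  seed <- as.integer(seed %||% profile$seed)
  offsets <- offsets %||% calibrate_offsets(profile)

  out <- withr::with_seed(seed, {
    cov <- draw_covariates(n, profile)
    eta <- offsets$base_intercept +
      drop(cov$X %*% profile$feature_spec$beta) +
      offsets$nonwhite_offset * cov$nw_latent
    y <- rbinom(n, 1L, plogis(eta))
    dplyr::bind_cols(
      as_tibble(cov$X),
      tibble(race = cov$race, outcome = y, weight = 1)
    )
  })
  new_ppd_cohort(out,
                 feature_names = profile$feature_spec$name,
                 provenance = paste0(profile$name, ":seed=", seed),
                 offsets = offsets)
}

new_ppd_cohort <- function(data, feature_names, provenance, offsets = NULL) {
  stopifnot(all(feature_names %in% names(data)),
            all(c("race", "outcome", "weight") %in% names(data)))
  if (!all(data$outcome %in% c(0L, 1L))) abort("`outcome` must be binary 0/1.")
  if (any(data$weight <= 0)) abort("`weight` must be positive for every subject.")
  structure(
    as_tibble(data),
    feature_names = feature_names,
    provenance = provenance,
    offsets = offsets,
    class = c("ppd_cohort", class(as_tibble(data)))
  )
}

#' Feature names of a cohort
#' @param cohort A `ppd_cohort`.
#' @return Character vector of the non-race feature column names.
#' @export
cohort_features <- function(cohort) {
  attr(cohort, "feature_names") %||%
    setdiff(names(cohort), c("race", "outcome", "weight"))
}

#' Add race indicator columns to a cohort
#'
#' The risk model encodes the five-level race category as indicator
#' variables. The default two-indicator encoding (`race_nonwhite`,
#' `race_unknown`) reproduces the published variable arithmetic: 32 model
#' variables with race, 30 with race removed, 31 with a single
#' White/Non-White indicator.
#'
#' @param data A cohort tibble with a `race` column.
#' @param encoding `"two_indicator"` (adds `race_nonwhite` and
#'   `race_unknown`) or `"single_indicator"` (adds `race_nonwhite` only).
#' @return The data with indicator columns appended.
#' @export
encode_race <- function(data, encoding = c("two_indicator", "single_indicator")) {
  encoding <- match.arg(encoding)
  if (!"race" %in% names(data)) abort("`data` has no `race` column.")
  out <- dplyr::mutate(
    data,
    race_nonwhite = as.numeric(.data$race != "White")
  )
  if (encoding == "two_indicator") {
    out <- dplyr::mutate(out, race_unknown = as.numeric(.data$race == "Unknown"))
  }
  out
}

#' Race indicator variable names for an encoding
#' @inheritParams encode_race
#' @return Character vector of indicator column names.
#' @export
race_variables <- function(encoding = c("two_indicator", "single_indicator")) {
  encoding <- match.arg(encoding)
  switch(encoding,
         two_indicator = c("race_nonwhite", "race_unknown"),
         single_indicator = "race_nonwhite")
}

#' Privileged-group indicator from the race category
#'
#' White is the privileged value; all other categories are unprivileged.
#' Subjects with Unknown race are grouped as unprivileged by default;
#' with `unknown = "exclude"` they are returned as `NA` so callers can
#' drop them.
#'
#' @param race Factor or character vector over [race_levels()].
#' @param unknown `"unprivileged"` (default) or `"exclude"`.
#' @return Logical vector, `TRUE` for privileged (White) subjects.
#' @export
is_privileged <- function(race, unknown = c("unprivileged", "exclude")) {
  unknown <- match.arg(unknown)
  out <- race == "White"
  if (unknown == "exclude") out[race == "Unknown"] <- NA
  out
}

#' Read and write cohorts as CSV
#'
#' The CSV holds the feature columns followed by `race`, `outcome`,
#' `weight`. Categorical and integer columns round-trip exactly; reals
#' round-trip to full double precision.
#'
#' @param cohort A `ppd_cohort` (or plain tibble with those columns).
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `ppd_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(as_tibble(cohort), path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  feats <- NULL
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  data$race <- factor(data$race, levels = race_levels())
  data$outcome <- as.integer(data$outcome)
  feats <- setdiff(names(data), c("race", "outcome", "weight"))
  new_ppd_cohort(data, feature_names = feats, provenance = "external")
}
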