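#' Specification of a debiasing approach
#'
#' The five approaches combine fairness through blindness and
#' Kamiran-Calders reweighing:
#'
#' 1. Nullify the race inputs of the already-fitted baseline model
#'    (no refit; 32 model variables, race inputs forced to 0).
#' 2. Remove race and retrain (30 variables).
#' 3. Recode race to one White/Non-White indicator, reweigh with the
#'    observed outcome rate, retrain (31 variables).
#' 4. As 3 but reweigh with the literature outcome prevalence of 1/7
#'    (31 variables).
#' 5. Remove race entirely, reweigh with the literature prevalence,
#'    retrain (30 variables).
#'
#' @param approach_id Integer 1 to 5.
#' @param literature_prevalence Expected outcome prevalence used by the
#'   literature-rate approaches (default 1/7).
#' @return A list of class `debias_spec`: `approach_id`,
#'   `race_handling` (`"nullify"`, `"remove"`, `"binary_white_nonwhite"`),
#'   `retrain`, `weight_source` (`"none"`, `"observed"`, `"literature"`),
#'   `literature_prevalence`, `n_variables_expected`, `label`.
#' @export
#' @examples
#' debias_spec(4)
debias_spec <- function(approach_id, literature_prevalence = 1 / 7) {
  if (!is.numeric(approach_id) || length(approach_id) != 1L ||
      !approach_id %in% 1:5) {
    abort("`approach_id` must be an integer from 1 to 5.")
  }
  if (literature_prevalence <= 0 || literature_prevalence >= 1) {
    abort("`literature_prevalence` must lie strictly in (0, 1).")
  }
  approach_id <- as.integer(approach_id)
  rows <- list(
    list(race_handling = "nullify", retrain = FALSE, weight_source = "none",
         n_variables_expected = 32L,
         label = "Fairness through blindness (nullify race inputs)"),
    list(race_handling = "remove", retrain = TRUE, weight_source = "none",
         n_variables_expected = 30L,
         label = "Fairness through blindness (remove race, retrain)"),
    list(race_handling = "binary_white_nonwhite", retrain = TRUE,
         weight_source = "observed", n_variables_expected = 31L,
         label = "Reweighing (observed rate, White/Non-White indicator)"),
    list(race_handling = "binary_white_nonwhite", retrain = TRUE,
         weight_source = "literature", n_variables_expected = 31L,
         label = "Reweighing (literature rate, White/Non-White indicator)"),
    list(race_handling = "remove", retrain = TRUE,
         weight_source = "literature", n_variables_expected = 30L,
         label = "Blindness and reweighing (remove race, literature rate)")
  )
  structure(
    c(list(approach_id = approach_id,
           literature_prevalence = literature_prevalence),
      rows[[approach_id]]),
    class = "debias_spec"
  )
}

#' @export
print.debias_spec <- function(x, ...) {
  cat("<debias_spec> approach ", x$approach_id, ": ", x$label, "\n",
      "  race handling: ", x$race_handling,
      "; retrain: ", x$retrain,
      "; weights: ", x$weight_source,
      if (x$weight_source == "literature") {
        paste0(" (prevalence ", signif(x$literature_prevalence, 6), ")")
      } else "",
      "; expected variables: ", x$n_variables_expected, "\n", sep = "")
  invisible(x)
}

#' Kamiran-Calders reweighing weights
#'
#' Each subject receives the weight of its (protected group, outcome
#' class) cell,
#' \deqn{w(g, c) = \frac{P_{exp}(g, c)}{P_{obs}(g, c)}
#'              = \frac{P_{obs}(g)\,P_c(c)}{P_{obs}(g, c)},}
#' the independence-construction expected cell probability over its
#' observed probability. With `weight_source = "observed"` the class
#' marginal \eqn{P_c} is the observed outcome rate, so the weighted data
#' satisfy group-outcome independence exactly while preserving both
#' marginals and the total weight \eqn{n}. With
#' `weight_source = "literature"` the class marginal is replaced by the
#' literature prevalence (default 1/7), so the weighted outcome
#' prevalence equals that prevalence exactly and the group marginals are
#' preserved.
#'
#' @param outcomes Binary 0/1 outcomes.
#' @param privileged Logical privileged-group indicator (no `NA`).
#' @param weight_source `"observed"` or `"literature"`.
#' @param literature_prevalence Outcome prevalence used when
#'   `weight_source = "literature"`.
#' @return An object of class `reweighing`: `weights` (per subject) and
#'   `cells`, a tibble with one row per (group, class) cell holding the
#'   observed and expected probabilities and the weight.
#' @export
#' @examples
#' w <- reweighing_weights(c(1, 0, 0, 1, 0, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' tidy(w)
reweighing_weights <- function(outcomes, privileged,
                               weight_source = c("observed", "literature"),
                               literature_prevalence = 1 / 7) {
  weight_source <- match.arg(weight_source)
  if (anyNA(privileged)) abort("`privileged` must not contain NA.")
  if (!all(outcomes %in% c(0, 1))) abort("`outcomes` must be binary 0/1.")
  if (literature_prevalence <= 0 || literature_prevalence >= 1) {
    abort("`literature_prevalence` must lie strictly in (0, 1).")
  }
  n <- length(outcomes)
  p_group <- c(privileged = mean(privileged), unprivileged = mean(!privileged))
  p_class <- if (weight_source == "observed") {
    c(absent = mean(outcomes == 0), present = mean(outcomes == 1))
  } else {
    c(absent = 1 - literature_prevalence, present = literature_prevalence)
  }
  cells <- tidyr::expand_grid(
    group = c("privileged", "unprivileged"),
    class = c("absent", "present")
  )
  cells <- dplyr::mutate(
    cells,
    n_subjects = purrr::map2_int(.data$group, .data$class, function(g, cl) {
      sum((privileged == (g == "privileged")) & (outcomes == (cl == "present")))
    }),
    observed_p = .data$n_subjects / n,
    expected_p = unname(p_group[.data$group] * p_class[.data$class])
  )
  if (any(cells$n_subjects == 0L)) {
    bad <- cells[cells$n_subjects == 0L, ]
    abort(paste0("Empty (group, class) cell: ",
                 paste(bad$group, bad$class, sep = "/", collapse = ", "),
                 ". Reweighing needs all four cells populated."))
  }
  cells$weight <- cells$expected_p / cells$observed_p
  key <- paste(ifelse(privileged, "privileged", "unprivileged"),
               ifelse(outcomes == 1, "present", "absent"))
  lookup <- setNames(cells$weight, paste(cells$group, cells$class))
  structure(
    list(weights = unname(lookup[key]), cells = cells,
         weight_source = weight_source,
         literature_prevalence = literature_prevalence),
    class = "reweighing"
  )
}

#' @export
print.reweighing <- function(x, ...) {
  cat("<reweighing> source: ", x$weight_source, "\n", sep = "")
  print(x$cells)
  invisible(x)
}

#' Cell table of a reweighing object
#' @param x A `reweighing`.
#' @param ... Unused.
#' @return The cell tibble: group, class, counts, observed and expected
#'   probabilities, weight.
#' @export
tidy.reweighing <- function(x, ...) x$cells

#' Export a reweighing cell table as CSV
#' @param rw A `reweighing`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(rw, path) {
  stopifnot(inherits(rw, "reweighing"))
  readr::write_csv(rw$cells, path)
  invisible(path)
}

#' Apply a debiasing approach
#'
#' Produces the debiased model for one approach, given a training
#' cohort and (for approach 1) the fitted baseline model. Approach 1
#' returns the baseline with its race inputs nullified; the retraining
#' approaches refit on the cohort with race removed or recoded and, for
#' the reweighing approaches, with Kamiran-Calders weights computed on
#' that cohort.
#'
#' @param spec A `debias_spec` (or an approach id 1-5).
#' @param cohort Training cohort with feature columns, `race`, `outcome`.
#' @param baseline The baseline `risk_model` fitted on the full
#'   32-variable set (required for approach 1; used only there).
#' @param l2_strength Ridge penalty for retrained approaches.
#' @param unknown Unknown-race policy for the reweighing group
#'   indicator, see [is_privileged()].
#' @return A list of class `debias_result`: `spec`, `model`,
#'   `probabilities` (scores on the training cohort), and `reweighing`
#'   (`NULL` for approaches 1-2).
#' @export
#' @examples
#' prof <- dataset_profile("amc2019")
#' cohort <- generate_cohort(prof, n = 3000)
#' enc <- encode_race(cohort)
#' base <- fit_logistic_l2(enc, c(cohort_features(cohort), race_variables()))
#' res <- apply_approach(2, cohort, base)
#' glance(res$model)
apply_approach <- function(spec, cohort, baseline = NULL, l2_strength = 1,
                           unknown = "unprivileged") {
  if (!inherits(spec, "debias_spec")) spec <- debias_spec(spec)
  feats <- cohort_features(cohort)

  if (spec$approach_id == 1L) {
    if (is.null(baseline)) {
      abort("Approach 1 nullifies the baseline model; supply `baseline`.")
    }
    race_vars <- intersect(race_variables("two_indicator"),
                           names(baseline$coefficients))
    if (length(race_vars) == 0L) {
      abort("The baseline model carries no race variables to nullify.")
    }
    model <- nullify_features(baseline, race_vars)
    scored <- encode_race(cohort, "two_indicator")
    return(structure(list(spec = spec, model = model,
                          probabilities = predict_risk(model, scored),
                          reweighing = NULL),
                     class = "debias_result"))
  }

  if (spec$race_handling == "binary_white_nonwhite") {
    data <- encode_race(cohort, "single_indicator")
    feature_subset <- c(feats, race_variables("single_indicator"))
  } else {
    data <- cohort
    feature_subset <- feats
  }

  rw <- NULL
  w <- NULL
  if (spec$weight_source != "none") {
    priv <- is_privileged(cohort$race, unknown = unknown)
    keep <- !is.na(priv)
    rw <- reweighing_weights(cohort$outcome[keep], priv[keep],
                             weight_source = spec$weight_source,
                             literature_prevalence = spec$literature_prevalence)
    w <- rep(NA_real_, nrow(cohort))
    w[keep] <- rw$weights
    data <- data[keep, , drop = FALSE]
    w <- w[keep]
  }

  model <- fit_logistic_l2(data, feature_subset, l2_strength = l2_strength,
                           weights = w)
  structure(
    list(spec = spec, model = model,
         probabilities = predict_risk(model, if (spec$race_handling == "binary_white_nonwhite") {
           encode_race(cohort, "single_indicator")
         } else cohort),
         reweighing = rw),
    class = "debias_result"
  )
}
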