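#' Evaluate one model on one cohort at one threshold
#'
#' Assembles a single row of the evaluation grid: discrimination (AUC),
#' precision, sensitivity and positivity share, the five fairness
#' metrics with their range flags, and — when a baseline row is
#' supplied — an improvement flag per metric. Improvement uses strict
#' inequality on unrounded values: a fairness metric improves when its
#' absolute distance to the ideal (0 for differences, 1 for disparate
#' impact) strictly decreases, and AUC/precision/sensitivity improve
#' when they strictly increase. Undefined metrics propagate as `NA`
#' without aborting the row.
#'
#' @param probabilities Predicted risks on the evaluation cohort.
#' @param outcomes Binary 0/1 outcomes.
#' @param privileged Logical privileged-group indicator.
#' @param threshold Decision threshold in (0, 1).
#' @param baseline_row Optional baseline grid row (same threshold) for
#'   improvement flags.
#' @param ranges Fairness acceptance ranges, as [fairness_ranges()].
#' @return A one-row tibble.
#' @export
evaluate_row <- function(probabilities, outcomes, privileged, threshold,
                         baseline_row = NULL, ranges = fairness_ranges()) {
  preds <- apply_threshold(probabilities, threshold)
  perf <- precision_sensitivity(preds, outcomes)
  rep <- fairness_report(preds, outcomes, privileged, ranges = ranges)
  short <- c(statistical_parity_difference = "spd", disparate_impact = "di",
             equal_opportunity_difference = "eod", average_odds_difference = "aod",
             predictive_parity_difference = "ppd")
  vals <- setNames(rep$value, short[rep$metric])
  flags <- setNames(rep$within_range, paste0(short[rep$metric], "_in_range"))
  row <- dplyr::bind_cols(
    tibble(
      threshold = threshold,
      auc = auc(probabilities, outcomes),
      precision = perf$precision,
      sensitivity = perf$sensitivity,
      positivity = positivity_share(preds)
    ),
    as_tibble(as.list(vals)),
    as_tibble(as.list(flags))
  )
  if (!is.null(baseline_row)) {
    ideals <- c(spd = 0, di = 1, eod = 0, aod = 0, ppd = 0)
    for (m in c("auc", "precision", "sensitivity")) {
      row[[paste0(m, "_improved")]] <- row[[m]] > baseline_row[[m]]
    }
    for (m in names(ideals)) {
      row[[paste0(m, "_improved")]] <-
        abs(row[[m]] - ideals[[m]]) < abs(baseline_row[[m]] - ideals[[m]])
    }
  }
  row
}

#' Configuration of a full evaluation experiment
#'
#' @param datasets Character vector of built-in profile names
#'   (`"amc2019"`, `"amc2020"`, `"crn"`) and/or a list of
#'   `cohort_profile` objects.
#' @param thresholds Decision thresholds to evaluate (default 0.2, 0.3,
#'   0.4).
#' @param approaches Debiasing approaches to run (subset of 1:5; empty
#'   for baseline only).
#' @param l2_strength Ridge penalty for every fit.
#' @param seed Master seed; development and evaluation cohort seeds are
#'   derived from it per dataset through a fixed splitting scheme.
#' @param development_prevalence Outcome prevalence of the development
#'   cohort each model is trained on (default 0.20). The development
#'   cohort shares its profile's race mix, proxy shifts and calibrated
#'   Non-White log-odds offset; only its base rate differs, emulating
#'   temporal validation of a model developed on an earlier,
#'   higher-prevalence sample. Set to `NULL` to train on a cohort drawn
#'   at the evaluation prevalence itself.
#' @param n_override Optional cohort size overriding each profile's
#'   `n_subjects` (applied to both cohorts).
#' @param literature_prevalence Literature outcome prevalence for the
#'   reweighing approaches (default 1/7).
#' @param ranges Fairness acceptance ranges used throughout the grid,
#'   as [fairness_ranges()] (overridable).
#' @param unknown Unknown-race policy, see [is_privileged()].
#' @param dca_thresholds Decision-curve grid (default 0.01-0.50 by 0.01).
#' @param output_dir Optional directory for artifacts (grid CSV/JSON,
#'   decision-curve CSVs, weight tables, prediction-distribution
#'   summaries, config echo).
#' @return A list of class `run_config`.
#' @export
run_config <- function(datasets = c("amc2019", "amc2020", "crn"),
                       thresholds = c(0.2, 0.3, 0.4),
                       approaches = 1:5,
                       l2_strength = 1,
                       seed = 1L,
                       development_prevalence = 0.20,
                       n_override = NULL,
                       literature_prevalence = 1 / 7,
                       ranges = fairness_ranges(),
                       unknown = "unprivileged",
                       dca_thresholds = seq(0.01, 0.50, by = 0.01),
                       output_dir = NULL) {
  if (length(datasets) == 0L) abort("At least one dataset is required.")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("All thresholds must lie strictly in (0, 1).")
  }
  if (length(approaches) > 0L && !all(approaches %in% 1:5)) {
    abort("`approaches` must be a subset of 1:5.")
  }
  structure(
    list(datasets = datasets, thresholds = thresholds,
         approaches = as.integer(approaches), l2_strength = l2_strength,
         seed = as.integer(seed),
         development_prevalence = development_prevalence,
         n_override = n_override,
         literature_prevalence = literature_prevalence,
         ranges = ranges,
         unknown = unknown, dca_thresholds = dca_thresholds,
         output_dir = output_dir),
    class = "run_config"
  )
}

# Deterministic seed-splitting scheme: every cohort seed is derived from
# the master seed, the dataset index and a role code (1 development,
# 2 evaluation), kept inside the 32-bit integer range.
derive_seed <- function(seed, dataset_index, role) {
  as.integer((as.numeric(seed) * 1009 + dataset_index * 101 + role) %% 2147483629)
}

resolve_profile <- function(d) {
  if (inherits(d, "cohort_profile")) d else dataset_profile(d)
}

#' Run the full evaluation experiment
#'
#' For each dataset: calibrate the generator to the profile's prevalence
#' and rate-ratio targets, draw a development and an evaluation cohort,
#' fit the baseline 32-variable L2 logistic model on the development
#' cohort, compute the baseline decision curve on the evaluation cohort,
#' apply every configured debiasing approach, and evaluate baseline and
#' approaches at every threshold. A failure in one dataset is reported
#' and the remaining datasets still run.
#'
#' @param config A `run_config`.
#' @return A list of class `ppd_experiment`: `grid` (one row per
#'   dataset x approach x threshold), `curves` (baseline `nb_curve` per
#'   dataset), `nb_points` (net benefit at 0.3/0.4/0.5 per dataset),
#'   `weights` (reweighing cell tables per dataset and approach),
#'   `models`, `errors`, and the `config`.
#' @export
#' @examples
#' \donttest{
#' ex <- run_experiment(run_config(datasets = "amc2019", n_override = 2000))
#' ex$grid
#' }
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  grid <- list()
  curves <- list()
  nb_points <- list()
  weights <- list()
  models <- list()
  pred_dist <- list()
  errors <- list()

  for (i in seq_along(config$datasets)) {
    d <- config$datasets[[i]]
    profile <- resolve_profile(d)
    name <- profile$name
    res <- tryCatch(
      run_one_dataset(profile, i, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warn(paste0("Dataset '", name, "' failed and was skipped: ",
                  conditionMessage(res)))
      errors[[name]] <- conditionMessage(res)
      next
    }
    grid[[name]] <- res$grid
    curves[[name]] <- res$curve
    nb_points[[name]] <- res$nb_points
    weights[[name]] <- res$weights
    models[[name]] <- res$models
    pred_dist[[name]] <- res$prediction_distribution
  }

  out <- structure(
    list(grid = dplyr::bind_rows(grid), curves = curves,
         nb_points = nb_points, weights = weights, models = models,
         prediction_distribution = pred_dist,
         errors = errors, config = config),
    class = "ppd_experiment"
  )
  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

run_one_dataset <- function(profile, dataset_index, config) {
  n <- config$n_override %||% profile$n_subjects
  offsets <- calibrate_offsets(profile)
  dev_offsets <- offsets
  if (!is.null(config$development_prevalence)) {
    dev_offsets$base_intercept <- solve_intercept(
      profile, offsets$nonwhite_offset, config$development_prevalence)
    dev_offsets$achieved_prevalence <- config$development_prevalence
  }
  cohort_dev <- generate_cohort(profile, n = n,
                                seed = derive_seed(config$seed, dataset_index, 1),
                                offsets = dev_offsets)
  cohort_eval <- generate_cohort(profile, n = n,
                                 seed = derive_seed(config$seed, dataset_index, 2),
                                 offsets = offsets)

  feats <- cohort_features(cohort_dev)
  enc_dev <- encode_race(cohort_dev, "two_indicator")
  enc_eval <- encode_race(cohort_eval, "two_indicator")
  baseline <- fit_logistic_l2(enc_dev, c(feats, race_variables("two_indicator")),
                              l2_strength = config$l2_strength)
  priv <- is_privileged(cohort_eval$race, unknown = config$unknown)

  probs <- list(baseline = predict_risk(baseline, enc_eval))
  models <- list(baseline = baseline)
  weights <- list()
  for (a in config$approaches) {
    res <- apply_approach(debias_spec(a, config$literature_prevalence),
                          cohort_dev, baseline = baseline,
                          l2_strength = config$l2_strength,
                          unknown = config$unknown)
    key <- paste0("approach_", a)
    probs[[key]] <- predict_risk(res$model, enc_eval)
    models[[key]] <- res$model
    if (!is.null(res$reweighing)) weights[[key]] <- res$reweighing$cells
  }

  curve <- decision_curve(probs$baseline, cohort_eval$outcome,
                          thresholds = config$dca_thresholds)
  nbp <- tryCatch(nb_at_thresholds(curve), error = function(e) NULL)

  rows <- list()
  for (th in config$thresholds) {
    base_row <- evaluate_row(probs$baseline, cohort_eval$outcome, priv, th,
                             ranges = config$ranges)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble(dataset = profile$name, approach = "baseline"), base_row)
    for (a in config$approaches) {
      key <- paste0("approach_", a)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(dataset = profile$name, approach = key),
        evaluate_row(probs[[key]], cohort_eval$outcome, priv, th,
                     baseline_row = base_row, ranges = config$ranges))
    }
  }

  pred_dist <- purrr::imap(probs, function(p, key) {
    dplyr::count(
      tibble(approach = key,
             outcome = cohort_eval$outcome,
             bin = pmin(floor(p / 0.02) * 0.02, 0.98)),
      .data$approach, .data$outcome, .data$bin, name = "n_subjects")
  })

  list(grid = dplyr::bind_rows(rows), curve = curve, nb_points = nbp,
       weights = weights, models = models,
       probabilities = probs, outcomes = cohort_eval$outcome,
       prediction_distribution = dplyr::bind_rows(pred_dist))
}

write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(experiment$grid, file.path(dir, "evaluation_grid.csv"))
  jsonlite::write_json(experiment$grid, file.path(dir, "evaluation_grid.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (name in names(experiment$curves)) {
    write_curve_csv(experiment$curves[[name]],
                    file.path(dir, paste0("decision_curve_", name, ".csv")))
  }
  for (name in names(experiment$weights)) {
    for (key in names(experiment$weights[[name]])) {
      readr::write_csv(experiment$weights[[name]][[key]],
                       file.path(dir, paste0("weights_", name, "_", key, ".csv")))
    }
  }
  for (name in names(experiment$prediction_distribution)) {
    readr::write_csv(
      experiment$prediction_distribution[[name]],
      file.path(dir, paste0("prediction_distribution_", name, ".csv")))
  }
  cfg <- experiment$config
  cfg$datasets <- purrr::map_chr(cfg$datasets,
                                 function(d) resolve_profile(d)$name)
  cfg$output_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.ppd_experiment <- function(x, ...) {
  cat("<ppd_experiment> ", length(x$curves), " dataset(s), ",
      nrow(x$grid), " grid rows\n", sep = "")
  if (length(x$errors) > 0L) {
    cat("  failed datasets:", paste(names(x$errors), collapse = ", "), "\n")
  }
  print(dplyr::select(x$grid, "dataset", "approach", "threshold",
                      "auc", "precision", "sensitivity",
                      "spd", "di", "eod", "aod", "ppd"))
  invisible(x)
}

#' Round grid metrics for display
#'
#' Presentation rounding used in reports: AUC, precision and sensitivity
#' to 2 decimals; fairness metrics to 3. Improvement flags are computed
#' on unrounded values before this is applied.
#'
#' @param grid An evaluation grid tibble.
#' @return The grid with rounded metric columns.
#' @export
format_grid <- function(grid) {
  dplyr::mutate(
    grid,
    dplyr::across(dplyr::any_of(c("auc", "precision", "sensitivity")),
                  ~ round(.x, 2)),
    dplyr::across(dplyr::any_of(c("positivity", "spd", "di", "eod", "aod", "ppd")),
                  ~ round(.x, 3))
  )
}

#' Plot the fairness metrics of an experiment grid
#'
#' Dot plot of the five fairness metrics by approach, faceted by dataset
#' and metric, with the acceptance range shaded — the visual analogue of
#' the published evaluation table.
#'
#' @param object A `ppd_experiment`.
#' @param threshold Which evaluated threshold to display (default 0.3).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppd_experiment <- function(object, threshold = 0.3, ...) {
  short <- c(spd = "statistical_parity_difference", di = "disparate_impact",
             eod = "equal_opportunity_difference", aod = "average_odds_difference",
             ppd = "predictive_parity_difference")
  g <- dplyr::filter(object$grid, abs(.data$threshold - !!threshold) < 1e-9)
  long <- tidyr::pivot_longer(g, cols = dplyr::all_of(names(short)),
                              names_to = "metric", values_to = "value")
  ranges <- fairness_ranges()
  ranges$metric <- names(short)[match(ranges$metric, short)]
  long <- dplyr::left_join(long, ranges, by = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$approach, y = .data$value)) +
    ggplot2::geom_rect(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                       xmin = -Inf, xmax = Inf, fill = "grey85", alpha = 0.5) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$ideal),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::facet_grid(metric ~ dataset, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Fairness metrics at threshold ", threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Prediction-distribution plot
#'
#' Histogram of predicted risks by observed outcome with the decision
#' threshold marked: the display used to judge how a threshold splits
#' true and false positives.
#'
#' @param probabilities Predicted risks.
#' @param outcomes Binary 0/1 outcomes.
#' @param threshold Optional threshold to mark.
#' @return A ggplot.
#' @export
plot_prediction_distribution <- function(probabilities, outcomes,
                                         threshold = NULL) {
  df <- tibble(probability = probabilities,
               outcome = factor(outcomes, levels = c(0, 1),
                                labels = c("No PPD", "PPD")))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$probability,
                                        fill = .data$outcome)) +
    ggplot2::geom_histogram(binwidth = 0.02, boundary = 0,
                            position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "Predicted risk", y = "Deliveries", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}
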