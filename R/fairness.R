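#' Grouped confusion statistics
#'
#' Exact confusion counts by protected group, with the derived rates the
#' fairness metrics are built from: positive prediction rate
#' (TP+FP)/n, true positive rate TP/(TP+FN), false positive rate
#' FP/(FP+TN), and positive predictive value TP/(TP+FP). Rates with a
#' zero denominator are `NA`.
#'
#' @param predictions A `ppd_predictions` tibble or 0/1 label vector.
#' @param outcomes Binary 0/1 outcomes.
#' @param privileged Logical vector, `TRUE` for privileged (White)
#'   subjects, as from [is_privileged()]. `NA` entries (excluded
#'   subjects) are dropped with their predictions and outcomes.
#' @return A tibble of class `group_confusion` with one row per group
#'   (`"privileged"`, `"unprivileged"`).
#' @export
#' @examples
#' group_confusion(c(1, 0, 1, 0), c(1, 0, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
group_confusion <- function(predictions, outcomes, privileged) {
  labels <- prediction_labels(predictions)
  if (length(labels) != length(outcomes) || length(outcomes) != length(privileged)) {
    abort("`predictions`, `outcomes` and `privileged` differ in length.")
  }
  keep <- !is.na(privileged)
  labels <- labels[keep]; outcomes <- outcomes[keep]; privileged <- privileged[keep]
  for (g in c(TRUE, FALSE)) {
    if (!any(privileged == g)) {
      abort(paste0("The ", if (g) "privileged" else "unprivileged",
                   " group has zero subjects."))
    }
  }
  one <- function(g, label) {
    l <- labels[privileged == g]; y <- outcomes[privileged == g]
    tp <- sum(l == 1 & y == 1); fp <- sum(l == 1 & y == 0)
    tn <- sum(l == 0 & y == 0); fn <- sum(l == 0 & y == 1)
    tibble(
      group = label, n = length(l), tp = tp, fp = fp, tn = tn, fn = fn,
      positive_prediction_rate = (tp + fp) / length(l),
      tpr = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
      fpr = if (fp + tn == 0L) NA_real_ else fp / (fp + tn),
      ppv = if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
    )
  }
  structure(
    dplyr::bind_rows(one(TRUE, "privileged"), one(FALSE, "unprivileged")),
    class = c("group_confusion", class(tibble()))
  )
}

gc_get <- function(gc, group, col) {
  gc[[col]][gc$group == group]
}

#' Statistical parity difference
#'
#' Difference of positive-prediction rates, unprivileged minus
#' privileged (Non-White minus White). 0 is the fairness ideal.
#'
#' @param gc A `group_confusion`.
#' @return A real in `[-1, 1]`.
#' @export
statistical_parity_difference <- function(gc) {
  stopifnot(inherits(gc, "group_confusion"))
  gc_get(gc, "unprivileged", "positive_prediction_rate") -
    gc_get(gc, "privileged", "positive_prediction_rate")
}

#' Disparate impact
#'
#' Ratio of positive-prediction rates, unprivileged over privileged
#' (Non-White over White). 1 is the fairness ideal; the conventional
#' acceptance range is `[0.8, 1.25]`. When the privileged rate is 0 the
#' ratio is undefined and reported as `NA` (never infinity).
#'
#' @param gc A `group_confusion`.
#' @return A positive real, or `NA` when undefined.
#' @export
disparate_impact <- function(gc) {
  stopifnot(inherits(gc, "group_confusion"))
  pr <- gc_get(gc, "privileged", "positive_prediction_rate")
  if (pr == 0) return(NA_real_)
  gc_get(gc, "unprivileged", "positive_prediction_rate") / pr
}

#' Equal opportunity difference
#'
#' Difference of true positive rates, unprivileged minus privileged.
#' `NA` when a group has no positive-class subjects.
#'
#' @param gc A `group_confusion`.
#' @return A real, or `NA` when undefined.
#' @export
equal_opportunity_difference <- function(gc) {
  stopifnot(inherits(gc, "group_confusion"))
  gc_get(gc, "unprivileged", "tpr") - gc_get(gc, "privileged", "tpr")
}

#' Average odds difference
#'
#' Mean of the group differences in false positive rate and true
#' positive rate (unprivileged minus privileged): the equalized-odds
#' summary. `NA` when either component is undefined.
#'
#' @param gc A `group_confusion`.
#' @return A real, or `NA` when undefined.
#' @export
average_odds_difference <- function(gc) {
  stopifnot(inherits(gc, "group_confusion"))
  0.5 * ((gc_get(gc, "unprivileged", "fpr") - gc_get(gc, "privileged", "fpr")) +
           (gc_get(gc, "unprivileged", "tpr") - gc_get(gc, "privileged", "tpr")))
}

#' Predictive parity difference
#'
#' Difference of positive predictive values, unprivileged minus
#' privileged. `NA` when a group has zero predicted positives.
#'
#' @param gc A `group_confusion`.
#' @return A real, or `NA` when undefined.
#' @export
predictive_parity_difference <- function(gc) {
  stopifnot(inherits(gc, "group_confusion"))
  gc_get(gc, "unprivileged", "ppv") - gc_get(gc, "privileged", "ppv")
}

#' Observed-outcome prevalence benchmark
#'
#' Rate difference and rate ratio of the observed outcome between the
#' unprivileged and privileged groups, independent of any model. These
#' benchmark the statistical parity difference and disparate impact: a
#' cohort whose disease rates already differ between groups cannot have
#' both calibrated predictions and statistical parity.
#'
#' @param outcomes Binary 0/1 outcomes.
#' @param privileged Logical privileged-group indicator (`NA` dropped).
#' @return A one-row tibble: `rate_difference`, `rate_ratio` (`NA` when
#'   the privileged prevalence is 0).
#' @export
#' @examples
#' prevalence_benchmark(c(1, 0, 0, 1, 0, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
prevalence_benchmark <- function(outcomes, privileged) {
  keep <- !is.na(privileged)
  outcomes <- outcomes[keep]; privileged <- privileged[keep]
  if (!any(privileged) || !any(!privileged)) {
    abort("Both groups must be non-empty.")
  }
  prev_p <- mean(outcomes[privileged])
  prev_u <- mean(outcomes[!privileged])
  tibble(
    rate_difference = prev_u - prev_p,
    rate_ratio = if (prev_p == 0) NA_real_ else prev_u / prev_p
  )
}

#' Default fairness acceptance ranges
#'
#' The conventional closed acceptance intervals: `[-0.1, 0.1]` for the
#' four difference metrics and `[0.8, 1.25]` for disparate impact.
#' Endpoints are inclusive.
#'
#' @return A tibble with `metric`, `ideal`, `lower`, `upper`.
#' @export
fairness_ranges <- function() {
  tibble(
    metric = c("statistical_parity_difference", "disparate_impact",
               "equal_opportunity_difference", "average_odds_difference",
               "predictive_parity_difference"),
    ideal = c(0, 1, 0, 0, 0),
    lower = c(-0.1, 0.8, -0.1, -0.1, -0.1),
    upper = c(0.1, 1.25, 0.1, 0.1, 0.1)
  )
}

#' Five-metric fairness report
#'
#' Computes the five group-fairness metrics from thresholded
#' predictions, flags each against its acceptance range (endpoints
#' inclusive), and attaches the observed-prevalence benchmark.
#' Undefined metrics (zero denominators) propagate as `NA` values with
#' `NA` flags; the report never aborts on them and never coerces them
#' to 0 or infinity.
#'
#' @param predictions A `ppd_predictions` tibble or 0/1 label vector.
#' @param outcomes Binary 0/1 outcomes.
#' @param privileged Logical privileged-group indicator, as from
#'   [is_privileged()]; `NA` entries are excluded.
#' @param ranges Acceptance ranges, as [fairness_ranges()].
#' @return A tibble of class `fairness_report` with columns `metric`,
#'   `value`, `ideal`, `lower`, `upper`, `within_range`; attributes
#'   `benchmark` (tibble), `group_confusion`, and `unknown_policy`.
#' @export
#' @examples
#' rep <- fairness_report(c(1, 0, 1, 0), c(1, 0, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
#' rep
fairness_report <- function(predictions, outcomes, privileged,
                            ranges = fairness_ranges()) {
  gc <- group_confusion(predictions, outcomes, privileged)
  values <- c(
    statistical_parity_difference = statistical_parity_difference(gc),
    disparate_impact = disparate_impact(gc),
    equal_opportunity_difference = equal_opportunity_difference(gc),
    average_odds_difference = average_odds_difference(gc),
    predictive_parity_difference = predictive_parity_difference(gc)
  )
  out <- dplyr::mutate(
    dplyr::left_join(tibble(metric = names(values), value = unname(values)),
                     ranges, by = "metric"),
    # endpoints are inclusive; the 1e-9 guard absorbs floating-point
    # noise from count-ratio arithmetic at an exact endpoint
    within_range = .data$value >= .data$lower - 1e-9 &
      .data$value <= .data$upper + 1e-9
  )
  keep <- !is.na(privileged)
  structure(
    out,
    benchmark = prevalence_benchmark(outcomes[keep], privileged[keep]),
    group_confusion = gc,
    unknown_policy = if (anyNA(privileged)) "excluded" else "unprivileged",
    class = c("fairness_report", class(tibble()))
  )
}

#' @export
print.fairness_report <- function(x, ...) {
  cat("<fairness_report>  (privileged group: White; Unknown race ",
      attr(x, "unknown_policy"), ")\n", sep = "")
  NextMethod()
  bm <- attr(x, "benchmark")
  cat(sprintf("observed-outcome benchmark: rate difference %.3f, rate ratio %s\n",
              bm$rate_difference,
              ifelse(is.na(bm$rate_ratio), "NA", sprintf("%.3f", bm$rate_ratio))))
  invisible(x)
}

#' Export a fairness report as JSON
#'
#' Writes metric values, range flags, acceptance intervals, group
#' confusion counts and the prevalence benchmark.
#'
#' @param report A `fairness_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_fairness_json <- function(report, path) {
  stopifnot(inherits(report, "fairness_report"))
  jsonlite::write_json(
    list(
      metrics = as_tibble(report),
      benchmark = attr(report, "benchmark"),
      group_confusion = as_tibble(attr(report, "group_confusion")),
      unknown_policy = attr(report, "unknown_policy")
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
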