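#' Net benefit of a prediction rule at a threshold
#'
#' Net benefit is expected benefit minus expected harm per subject:
#' \deqn{NB = \frac{TP}{n} - \frac{FP}{n}\,\frac{P}{1-P}}
#' where \eqn{P} is the probability threshold at which a clinician would
#' treat. True positives count fully; false positives are discounted by
#' the odds of the threshold, the harm weight implied by being willing
#' to treat at risk \eqn{P}.
#'
#' @param tp,fp True and false positive counts (vectorized).
#' @param n Population size (positive).
#' @param threshold Probability threshold strictly below 1.
#' @return Net benefit (same length as the longest argument).
#' @export
#' @examples
#' net_benefit(tp = 10, fp = 20, n = 100, threshold = 0.3)  # 0.0142857...
net_benefit <- function(tp, fp, n, threshold) {
  if (any(n <= 0)) abort("`n` must be positive.")
  if (any(threshold <= 0 | threshold >= 1)) {
    abort("`threshold` must lie strictly in (0, 1): the harm weight P/(1-P) diverges at 1.")
  }
  if (any(tp < 0) || any(fp < 0) || any(tp + fp > n)) {
    abort("Counts must satisfy 0 <= tp, 0 <= fp, tp + fp <= n.")
  }
  tp / n - (fp / n) * threshold / (1 - threshold)
}

#' Decision curve over a threshold grid
#'
#' At each grid threshold \eqn{P}, subjects with probability at or above
#' \eqn{P} are labelled positive and the model net benefit is computed
#' from the resulting confusion counts. Two reference strategies are
#' included: treat-all, with net benefit
#' \eqn{\pi - (1-\pi) P/(1-P)} for prevalence \eqn{\pi}, and treat-none,
#' identically 0. The default grid covers 0.01 to 0.50 in steps of 0.01
#' (thresholds below 0.5 being the policy region of interest for a
#' minimal-harm preventive intervention); any grid inside (0, 1) can be
#' supplied.
#'
#' @param probabilities Predicted risks.
#' @param outcomes Binary 0/1 outcomes.
#' @param thresholds Increasing grid of thresholds in (0, 1).
#' @return A tibble of class `nb_curve` with columns `threshold`,
#'   `model_nb`, `treat_all_nb`, `treat_none_nb`; attributes `n` and
#'   `prevalence`.
#' @export
#' @examples
#' dc <- decision_curve(c(0.1, 0.4, 0.8, 0.9), c(0, 0, 1, 1))
#' nb_at_thresholds(dc, c(0.3, 0.4, 0.5))
decision_curve <- function(probabilities, outcomes,
                           thresholds = seq(0.01, 0.50, by = 0.01)) {
  if (length(thresholds) == 0L) abort("`thresholds` grid is empty.")
  if (length(probabilities) != length(outcomes)) {
    abort("`probabilities` and `outcomes` differ in length.")
  }
  if (!all(outcomes %in% c(0, 1))) abort("`outcomes` must be binary 0/1.")
  n <- length(outcomes)
  prevalence <- mean(outcomes)
  rows <- purrr::map(thresholds, function(p) {
    lab <- probabilities >= p
    tp <- sum(lab & outcomes == 1)
    fp <- sum(lab & outcomes == 0)
    tibble(
      threshold = p,
      model_nb = net_benefit(tp, fp, n, p),
      treat_all_nb = prevalence - (1 - prevalence) * p / (1 - p),
      treat_none_nb = 0
    )
  })
  structure(
    dplyr::bind_rows(rows),
    n = n, prevalence = prevalence,
    class = c("nb_curve", class(tibble()))
  )
}

#' Net benefit at reporting thresholds
#'
#' Looks up exact grid values (no interpolation): asking for a point not
#' on the computed grid is an error, never a silent interpolation.
#'
#' @param curve An `nb_curve`.
#' @param points Thresholds to report (default the common reporting
#'   triple 0.3, 0.4, 0.5).
#' @return A tibble with `threshold`, `model_nb`, `treat_all_nb`.
#' @export
nb_at_thresholds <- function(curve, points = c(0.3, 0.4, 0.5)) {
  stopifnot(inherits(curve, "nb_curve"))
  idx <- purrr::map_int(points, function(p) {
    i <- which(abs(curve$threshold - p) < 1e-9)
    if (length(i) != 1L) {
      abort(sprintf("Threshold %g is not on the computed grid.", p))
    }
    i
  })
  as_tibble(curve)[idx, c("threshold", "model_nb", "treat_all_nb")]
}

#' Plot a decision curve
#'
#' Standard decision-curve display: model net benefit against threshold
#' with the treat-all and treat-none references.
#'
#' @param object An `nb_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nb_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("model_nb", "treat_all_nb", "treat_none_nb"),
    names_to = "strategy", values_to = "net_benefit"
  )
  long$strategy <- factor(long$strategy,
                          levels = c("model_nb", "treat_all_nb", "treat_none_nb"),
                          labels = c("Model", "Treat all", "Treat none"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                                     colour = .data$strategy,
                                     linetype = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(min(-0.01, min(long$net_benefit)),
                                      attr(object, "prevalence") * 1.1)) +
    ggplot2::labs(x = "Probability threshold", y = "Net benefit",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Export a decision curve as CSV
#' @param curve An `nb_curve`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(as_tibble(curve), path)
  invisible(path)
}
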