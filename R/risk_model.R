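#' Fit an L2-regularized logistic risk model
#'
#' Maximizes the weighted penalized log-likelihood
#' \deqn{\sum_i w_i [y_i \log p_i + (1-y_i)\log(1-p_i)] - \lambda \|\beta\|^2}
#' by Newton-Raphson (iteratively reweighted least squares), with the
#' intercept unpenalized. Weights follow the weight-as-multiplicity
#' convention: they multiply per-subject log-likelihood terms and the
#' penalty is not weight-scaled, so giving every subject weight 2 is
#' identical to duplicating every subject, and scaling all weights by
#' `c` is equivalent to an unweighted fit with `l2_strength / c`. This
#' is the convention under which Kamiran-Calders reweighing weights act
#' as pseudo-counts.
#'
#' Continuous features (columns with values outside \{0, 1\}) are
#' standardized by their training mean and standard deviation; binary
#' features enter raw. The standardization constants are stored in the
#' model and reused at prediction time.
#'
#' @param data A data frame with the feature columns, an outcome column,
#'   and optionally a weight column.
#' @param features Character vector of feature column names to use.
#' @param outcome Name of the binary outcome column (default `"outcome"`).
#' @param l2_strength Non-negative ridge penalty \eqn{\lambda} on the
#'   standardized scale (default 1).
#' @param weights `NULL` for an unweighted fit, the name of a column in
#'   `data`, or a positive numeric vector of length `nrow(data)`.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `risk_model`: intercept, named
#'   coefficients (standardized scale), `l2_strength`,
#'   `nullified_features`, standardization table, and training metadata.
#' @export
#' @examples
#' prof <- dataset_profile("amc2019")
#' cohort <- generate_cohort(prof, n = 2000)
#' m <- fit_logistic_l2(cohort, features = cohort_features(cohort))
#' glance(m)
fit_logistic_l2 <- function(data, features, outcome = "outcome",
                            l2_strength = 1, weights = NULL,
                            max_iter = 100L, tol = 1e-10) {
  if (length(features) == 0L) abort("`features` must be non-empty.")
  missing_cols <- setdiff(c(features, outcome), names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."))
  }
  if (l2_strength < 0) abort("`l2_strength` must be non-negative.")
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) abort("Outcome must be binary 0/1.")
  if (length(unique(y)) < 2L) {
    abort("Outcome has a single class; cannot fit a logistic model.")
  }
  X <- as.matrix(data[features])
  if (!all(is.finite(X))) abort("Non-finite feature values in the training data.")

  w <- NULL
  weighted <- !is.null(weights)
  if (is.character(weights)) {
    w <- data[[weights]]
  } else if (is.numeric(weights)) {
    if (length(weights) != nrow(data)) abort("`weights` has the wrong length.")
    w <- weights
  } else {
    w <- rep(1, nrow(data))
  }
  if (any(w <= 0) || !all(is.finite(w))) abort("Weights must be positive and finite.")

  is_binary <- apply(X, 2L, function(v) all(v %in% c(0, 1)))
  center <- ifelse(is_binary, 0, colMeans(X))
  # population (1/n) standard deviation: keeps the fit exactly invariant
  # under subject duplication, matching the weight-as-multiplicity contract
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  scale_ <- ifelse(is_binary, 1, apply(X, 2L, pop_sd))
  if (any(scale_ == 0)) {
    # constant continuous column: leave it unscaled rather than divide by 0
    center[scale_ == 0] <- 0
    scale_[scale_ == 0] <- 1
  }
  Z <- cbind(`(Intercept)` = 1, sweep(sweep(X, 2L, center), 2L, scale_, "/"))
  p1 <- ncol(Z)
  penalty <- c(0, rep(l2_strength, p1 - 1L))

  beta <- numeric(p1)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(Z, w * (y - mu))) - 2 * penalty * beta
    H <- crossprod(Z * (w * mu * (1 - mu)), Z)
    diag(H) <- diag(H) + 2 * penalty
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      intercept = beta[1L],
      coefficients = setNames(beta[-1L], features),
      l2_strength = l2_strength,
      nullified_features = character(0),
      standardization = tibble(feature = features, center = unname(center),
                               scale = unname(scale_)),
      training_meta = list(weighted = weighted, n_obs = nrow(data),
                           converged = converged, iterations = iter,
                           feature_subset = features)
    ),
    class = "risk_model"
  )
}

#' Nullify model inputs
#'
#' Marks features whose raw input is forced to 0 at scoring time (the
#' stored standardization constants are still applied afterwards). This
#' is "fairness through blindness" without refitting: the model keeps
#' its coefficients but can no longer see the nullified inputs.
#'
#' @param model A `risk_model`.
#' @param features Character vector, a subset of the model's features.
#' @return The model with `nullified_features` set.
#' @export
nullify_features <- function(model, features) {
  stopifnot(inherits(model, "risk_model"))
  unknown <- setdiff(features, names(model$coefficients))
  if (length(unknown) > 0L) {
    abort(paste0("Cannot nullify features absent from the model: ",
                 paste(unknown, collapse = ", "), "."))
  }
  model$nullified_features <- union(model$nullified_features, features)
  model
}

#' Predict outcome risk
#'
#' Computes `plogis(intercept + sum_j beta_j z_j)` where `z_j` is the
#' stored standardization applied to the raw input, and the raw input of
#' every nullified feature is replaced by 0 before standardization.
#'
#' @param model A `risk_model`.
#' @param data A data frame providing every non-nullified model feature.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, data) {
  stopifnot(inherits(model, "risk_model"))
  feats <- names(model$coefficients)
  needed <- setdiff(feats, model$nullified_features)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Missing feature columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  X <- matrix(0, nrow(data), length(feats), dimnames = list(NULL, feats))
  for (f in needed) X[, f] <- data[[f]]
  X[, model$nullified_features] <- 0
  Z <- sweep(sweep(X, 2L, model$standardization$center), 2L,
             model$standardization$scale, "/")
  plogis(model$intercept + drop(Z %*% model$coefficients))
}

#' Coefficients on the raw input scale
#'
#' Back-transforms the standardized-scale coefficients so that
#' `plogis(intercept + X %*% beta)` on raw inputs reproduces the model.
#'
#' @param model A `risk_model`.
#' @return List with `intercept` and named `coefficients`.
#' @export
raw_coefficients <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  sc <- model$standardization
  b_raw <- model$coefficients / sc$scale
  list(intercept = model$intercept - sum(b_raw * sc$center),
       coefficients = setNames(b_raw, sc$feature))
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> L2-regularized logistic regression\n")
  cat("  features:   ", length(x$coefficients),
      if (length(x$nullified_features) > 0L) {
        paste0(" (", length(x$nullified_features), " nullified)")
      } else "", "\n", sep = "")
  cat("  l2_strength:", x$l2_strength, "\n")
  cat("  weighted:   ", x$training_meta$weighted,
      "  n_obs: ", x$training_meta$n_obs, "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted risk model
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `nullified`), the intercept first.
#' @export
tidy.risk_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    nullified = c(FALSE, names(x$coefficients) %in% x$nullified_features)
  )
}

#' One-row model summary
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A one-row tibble: feature count, nullified count, penalty,
#'   weighting flag, training size, convergence.
#' @export
glance.risk_model <- function(x, ...) {
  tibble(
    n_features = length(x$coefficients),
    n_nullified = length(x$nullified_features),
    l2_strength = x$l2_strength,
    weighted = x$training_meta$weighted,
    n_obs = x$training_meta$n_obs,
    converged = x$training_meta$converged
  )
}

#' Threshold probabilities into a prediction set
#'
#' The comparison is inclusive: a subject is labelled positive exactly
#' when its probability is greater than or equal to the threshold, so a
#' risk at the cutoff flags the patient.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Scalar strictly inside (0, 1).
#' @return A tibble of class `ppd_predictions` with columns
#'   `probability` and `label`, and the threshold as an attribute.
#' @export
#' @examples
#' apply_threshold(c(0.1, 0.3, 0.9), 0.3)
apply_threshold <- function(probabilities, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single value strictly inside (0, 1).")
  }
  structure(
    tibble(probability = probabilities,
           label = as.integer(probabilities >= threshold)),
    threshold = threshold,
    class = c("ppd_predictions", class(tibble()))
  )
}

prediction_labels <- function(predictions) {
  if (inherits(predictions, "ppd_predictions") || is.data.frame(predictions)) {
    predictions$label
  } else {
    as.integer(predictions)
  }
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a random positive
#' outranks a random negative, ties counted one half. Threshold-free by
#' construction and invariant to strictly increasing transforms of the
#' scores.
#'
#' @param probabilities Numeric scores.
#' @param outcomes Binary 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.6, 0.6, 0.2), c(1, 0, 1, 0))  # 0.875
auc <- function(probabilities, outcomes) {
  if (length(probabilities) != length(outcomes)) {
    abort("`probabilities` and `outcomes` differ in length.")
  }
  if (!all(outcomes %in% c(0, 1))) abort("`outcomes` must be binary 0/1.")
  n_pos <- sum(outcomes == 1)
  n_neg <- sum(outcomes == 0)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC needs both outcome classes present.")
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[outcomes == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision and sensitivity of thresholded predictions
#'
#' Precision is TP/(TP+FP) and sensitivity TP/(TP+FN). With zero
#' predicted positives the precision is undefined and reported as `NA`
#' (never coerced to 0).
#'
#' @param predictions A `ppd_predictions` tibble or a 0/1 label vector.
#' @param outcomes Binary 0/1 outcomes.
#' @return A one-row tibble: `precision`, `sensitivity`, and the
#'   underlying `tp`, `fp`, `fn` counts.
#' @export
#' @examples
#' precision_sensitivity(c(1, 1, 1, 0), c(1, 1, 0, 1))
precision_sensitivity <- function(predictions, outcomes) {
  labels <- prediction_labels(predictions)
  if (length(labels) != length(outcomes)) {
    abort("`predictions` and `outcomes` differ in length.")
  }
  tp <- sum(labels == 1 & outcomes == 1)
  fp <- sum(labels == 1 & outcomes == 0)
  fn <- sum(labels == 0 & outcomes == 1)
  tibble(
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    sensitivity = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn
  )
}

#' Share of subjects predicted positive
#' @param predictions A `ppd_predictions` tibble or 0/1 label vector.
#' @return Proportion of positive labels.
#' @export
positivity_share <- function(predictions) {
  labels <- prediction_labels(predictions)
  if (length(labels) == 0L) abort("`predictions` is empty.")
  mean(labels == 1)
}

#' Serialize a risk model to JSON
#'
#' Stores the intercept, named coefficients, penalty, nullified features
#' and standardization constants at full precision; [read_model_json()]
#' restores a scoring-equivalent model.
#'
#' @param model A `risk_model`.
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `risk_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(
    list(
      intercept = model$intercept,
      coefficients = as.list(model$coefficients),
      l2_strength = model$l2_strength,
      nullified_features = model$nullified_features,
      standardization = model$standardization,
      training_meta = model$training_meta
    ),
    # 17 significant digits: doubles round-trip to the exact same value
    path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      intercept = x$intercept,
      coefficients = unlist(x$coefficients),
      l2_strength = x$l2_strength,
      nullified_features = as.character(x$nullified_features %||% character(0)),
      standardization = as_tibble(x$standardization),
      training_meta = x$training_meta
    ),
    class = "risk_model"
  )
}
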