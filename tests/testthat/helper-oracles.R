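# Naive per-subject enumeration oracle for the five fairness metrics.
# Deliberately loop-based and independent of the package's grouped
# confusion-count path.
naive_fairness_oracle <- function(labels, outcomes, privileged) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  count <- function(cond) {
    k <- 0L
    for (i in seq_along(labels)) if (cond(i)) k <- k + 1L
    k
  }
  for_group <- function(g) {
    n <- count(function(i) privileged[i] == g)
    pos_pred <- count(function(i) privileged[i] == g && labels[i] == 1)
    tp <- count(function(i) privileged[i] == g && labels[i] == 1 && outcomes[i] == 1)
    fp <- count(function(i) privileged[i] == g && labels[i] == 1 && outcomes[i] == 0)
    fn <- count(function(i) privileged[i] == g && labels[i] == 0 && outcomes[i] == 1)
    tn <- count(function(i) privileged[i] == g && labels[i] == 0 && outcomes[i] == 0)
    list(ppr = rate(pos_pred, n), tpr = rate(tp, tp + fn),
         fpr = rate(fp, fp + tn), ppv = rate(tp, tp + fp))
  }
  p <- for_group(TRUE)
  u <- for_group(FALSE)
  list(
    spd = u$ppr - p$ppr,
    di = if (is.na(p$ppr) || p$ppr == 0) NA_real_ else u$ppr / p$ppr,
    eod = u$tpr - p$tpr,
    aod = 0.5 * ((u$fpr - p$fpr) + (u$tpr - p$tpr)),
    ppd = u$ppv - p$ppv
  )
}

# Random small labelled cohort with both protected groups guaranteed.
random_eval_case <- function(n = NULL) {
  n <- n %||% sample(8:200, 1L)
  privileged <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
  list(
    labels = sample(0:1, n, replace = TRUE),
    outcomes = sample(0:1, n, replace = TRUE),
    privileged = privileged
  )
}

# Small profile used across tests: no Unknown race so group membership is
# latent-free, quick to calibrate at reduced n_calib.
test_profile <- function(n = 2000, prevalence = 0.15, rate_ratio = 0.6,
                         proxy_strength = 0.8, seed = 1L) {
  cohort_profile(
    name = "test",
    n_subjects = n,
    race_probs = c(White = 0.5, Asian = 0.2, Black = 0.15, Other = 0.1,
                   Unknown = 0.05),
    target_prevalence = prevalence,
    target_rate_ratio = rate_ratio,
    proxy_strength = proxy_strength,
    seed = seed
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
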