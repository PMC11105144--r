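---
title: "Auditing and debiasing a postpartum depression risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and debiasing a postpartum depression risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ppdfair packages the quantitative part of a pre-implementation review
of a clinical risk model: is a postpartum-depression (PPD) predictor
worth acting on at a given risk threshold, does it treat racial groups
equitably, and which of the standard debiasing moves helps without
destroying clinical usefulness? This vignette explains the models and
procedures behind each function, the parameters that matter, what the
synthetic cohorts do and do not emulate, and the design decisions that
were genuinely open.

## The risk model

The predictor under audit is a logistic regression with an L2 penalty.
`fit_logistic_l2()` maximizes

$$\sum_i w_i \left[ y_i \log p_i + (1-y_i)\log(1-p_i)\right]
  \;-\; \lambda \lVert \beta \rVert^2,$$

with the intercept unpenalized, by Newton–Raphson (penalized IRLS,
convergence when no coefficient moves by more than 1e-10; the
closed-form Newton step makes the optimum reproducible to machine
precision, which the tests exploit by comparing against a general-purpose
quasi-Newton optimizer on the same objective).

Three conventions are fixed and tested rather than left implicit:

* **Weights are multiplicities.** Weights multiply per-subject
  log-likelihood terms and the penalty is *not* weight-scaled, so
  giving every subject weight 2 is exactly equivalent to duplicating
  the data, and scaling all weights by $c$ equals an unweighted fit
  with $\lambda/c$. This is the convention under which reweighing
  weights behave as pseudo-counts.
* **Standardization.** Continuous features are centered and scaled by
  their training mean and *population* (1/n) standard deviation;
  binary features enter raw. The population variant keeps the fit
  exactly invariant under duplication; the constants are stored in the
  model and reused at scoring time. The penalty $\lambda$ (default 1)
  therefore acts on the standardized scale. The original deployed
  model's exact penalty and preprocessing live in its development
  publication, so the default here is an explicit, configurable
  stand-in.
* **Thresholding is inclusive** (`probability >= threshold` flags the
  subject): a risk at the cutoff triggers the intervention.

Input nullification (`nullify_features()`) implements fairness through
blindness without refitting: the *raw* input of a nullified feature is
replaced by 0 before the stored standardization is applied, which for
the binary race indicators is identical to scoring a cohort whose race
columns are zeroed.

Performance metrics are the threshold-free AUC (Mann–Whitney form,
ties counted one half), precision and sensitivity. Precision with zero
predicted positives is reported as `NA`, never as 0 — coercing it
would fabricate a number where the quantity is undefined.

## Decision curves

`decision_curve()` evaluates net benefit
$NB(P) = TP/n - (FP/n)\,P/(1-P)$ over a grid of thresholds, default
0.01 to 0.50 in steps of 0.01. The sub-0.5 region is the policy region
for a minimal-harm preventive intervention (education, social-work
referral, lifestyle counseling), where missing an at-risk patient
costs more than a false referral. Treat-all and treat-none reference
curves are included — the paper-style model-only formula is not
interpretable without them — and `nb_at_thresholds()` reports exact
grid values only, refusing to interpolate silently. Reports round net
benefit to 3 decimals; full precision is kept internally.

## The fairness audit

Race is the protected attribute, dichotomized with White as the
privileged value. The five metrics (statistical parity difference,
disparate impact, equal opportunity difference, average odds
difference, predictive parity difference) are computed from exact
grouped confusion counts, flagged against the conventional closed
ranges $[-0.1, 0.1]$ and $[0.8, 1.25]$ with **inclusive endpoints**
(a 1e-9 guard absorbs floating-point noise from count ratios that land
exactly on an endpoint). Undefined metrics — a group with no positive
predictions or no positive-class subjects — propagate as `NA` with
`NA` flags; the report never aborts and never substitutes 0 or
infinity.

Subjects with **Unknown race** are grouped as unprivileged by default:
the audit dichotomizes White vs everyone else, and a subject whose
record does not document White race is not in the privileged group.
The alternative — excluding them — is supported
(`is_privileged(race, unknown = "exclude")`) and every report records
which policy produced it, since the two can differ materially when the
Unknown share is large (a quarter of the clinical research network
profile).

`prevalence_benchmark()` reports the observed-outcome rate difference
and rate ratio between the groups. These are the context for the
parity metrics: a cohort whose disease rates differ by a factor of two
cannot have both calibrated predictions and statistical parity, so a
parity violation is expected wherever the benchmark ratio is far
from 1.

## Debiasing approaches

The five approaches and their variable counts (32/30/31/31/30 against
the baseline's 32) are fixed by `debias_spec()`. Two design points
were genuinely open:

* **Race encoding.** The five-level race category enters the baseline
  model as exactly two indicators, `race_nonwhite` and `race_unknown`
  — the only encoding consistent with the published variable
  arithmetic (32 with race, 30 without, 31 with a single
  White/Non-White indicator). Which two dummies is configurable in
  `encode_race()`.
* **Approaches 3–4 keep a single White/Non-White indicator** rather
  than removing race entirely: the source material's table (31
  variables) and its prose ("removed race") conflict, and the variable
  count is only consistent with retention, so the table is treated as
  authoritative. Approach 5 is the fully-removed variant, so both
  readings are present in the comparison anyway.

Reweighing uses the Kamiran–Calders independence construction: the
expected probability of a (group, class) cell is the product of the
observed group marginal and a class marginal — the observed outcome
rate (approach 3) or the literature prevalence 1/7 (approaches 4–5) —
and each subject's weight is expected over observed cell probability.
Two exact algebraic consequences are tested: observed-source weights
sum to $n$ and make the weighted group–outcome joint factorize
exactly; literature-source weights pin the weighted prevalence at
exactly 1/7 while preserving the group marginals.

## The synthetic cohort generator

The published evaluation ran on private EHR data, so the package
generates cohorts that reproduce the three dataset profiles'
*published margins*: size, PPD prevalence, five-level race
composition, and Non-White/White prevalence rate ratio (0.476, 0.637,
1.005). Within a cohort:

* 25 binary clinical indicators (mental-health history, comorbidity,
  obstetric, medication) and 5 standardized continuous demographic
  features are drawn race-conditionally;
* the outcome is Bernoulli of a logistic model with fixed true
  coefficients, a calibrated base intercept, and a calibrated
  Non-White log-odds offset;
* **Unknown race is a label-masking event**: a latent race drawn from
  the four known categories is masked with the profile's Unknown
  probability, independently of features and outcome — the
  least-assumption mechanism, since no masking mechanism is documented.

**Calibration** (`calibrate_offsets()`) solves for the base intercept
and Non-White offset by nested Brent root-finding on expected
prevalences over a fixed covariate sample (n = 200,000, internal seed
987). Because the outcome is averaged analytically through the
logistic link rather than drawn, the objective is smooth and monotone
in both unknowns and the solution is deterministic given the profile;
infeasible targets (a rate ratio forcing a group prevalence past 1)
are rejected with the implied group prevalences named. Generated
cohorts land within Monte-Carlo error of the targets: across the three
profiles at n = 100,000 the rate ratios come out within 0.02 of
0.476/0.637/1.005.

Two generator parameters carry the scientific content:

* **True coefficient magnitudes** are set so that a logistic model on
  these features discriminates with AUC ≈ 0.96 — the regime reported
  for the deployed PPD model (0.94–0.97). This makes some per-feature
  odds ratios larger than typical epidemiological estimates; the
  alternative (realistic per-feature effects, AUC ≈ 0.85) would audit
  a much weaker model than the one under review.
* **`proxy_strength` (default 0.8** on the log-odds scale) shifts
  care-access features (documented depression/anxiety history,
  psychotherapy, SSRI prescriptions, prenatal visits) down and a few
  comorbidity features up for Non-White subjects. At 0.8, roughly half
  of the White/Non-White outcome gap flows through features the model
  can see, so removing race roughly halves — but does not eliminate —
  the statistical parity violation, the residual-disparity pattern the
  debiasing comparison is about. Setting it to 0 produces
  group-identical feature distributions (verified by two-sample tests
  in the suite).

**What the generator does not emulate:** feature–feature correlation
beyond what race induces, temporal drift within a cohort, informative
missingness, the original feature semantics (names are realistic but
effects are synthetic), and outcome misclassification. Passing tests
therefore show that the *methods* behave as specified under known
ground truth — not that the specific published coefficients or table
cells are recovered, which is impossible without the private data.

## The evaluation experiment

`run_experiment()` mirrors a temporal-validation design: for each
dataset, every model (baseline and approaches) is trained on a
**development cohort** and evaluated on the profile-calibrated evaluation cohort. The
development cohort shares the profile's race mix, proxy shifts and
calibrated Non-White offset; only its base rate differs —
`development_prevalence`, default **0.20**, the upper end of the
population prevalence estimates (14%–20%) cited for PPD. Two reasons:

1. The deployed model was developed on an earlier sample and validated
   on later years; at validation it over-predicted (sensitivity 0.95
   at threshold 0.3 with positivity near twice the prevalence), which
   is only possible when the training base rate exceeds the
   evaluation base rate.
2. A model fit and evaluated on the same cohort is calibrated: at
   threshold 0.3 its sensitivity sits near 0.6 and its group TPR gaps
   dominate the audit — a qualitatively different (and less
   interesting) regime than the one under review.

Set `development_prevalence = NULL` to get the same-cohort regime.

Holding the disparity *mechanism* (offset and proxies) fixed rather
than the rate *ratio* is deliberate: re-targeting the ratio at a
higher prevalence would inflate the offset the model learns and
overstate group error gaps at evaluation.

All randomness flows from one master seed through a documented
splitting scheme (`seed`, dataset index, role ∈ {development,
evaluation} → 32-bit cohort seed), so two runs of the same
configuration are byte-identical, including the exported CSVs. A
failing dataset (e.g. infeasible calibration targets) is logged and
skipped; the remaining datasets still run.

Improvement flags in the grid use strict inequality on unrounded
values — display rounding (2 decimals for AUC/precision/sensitivity,
3 for fairness metrics) is presentation-only via `format_grid()`.

## Numerical choices and problem sizes

* Root-finding tolerances: 1e-6 on the rate ratio, 1e-7 on prevalence.
* IRLS: at most 100 Newton iterations, step tolerance 1e-10; a
  constant continuous column is left unscaled rather than divided by
  zero.
* Model JSON serialization writes 17 significant digits so scores
  round-trip exactly; cohort CSVs round-trip categorical and integer
  columns exactly and reals to better than 1e-12.
* The test suite validates metrics against naive per-subject
  enumeration oracles on 200 random small cohorts (n ≤ 200),
  generator calibration at n = 100,000 over 10 seeds, and the
  qualitative evaluation pattern over 10 replicates at the published
  cohort sizes. Parameter recovery of the fit runs at n = 50,000 with
  penalty 1e-4 on a design where the information matrix is well
  conditioned — balanced outcome, binary prevalences ≥ 0.2, moderate
  effects — because recovery of a 6-log-odds effect carried by 4% of
  subjects is information-limited at any realistic cohort size and
  would test the data, not the optimizer.

## Known limitations

* The audit is binary-group; intersectional and multi-attribute
  fairness are out of scope, as are significance tests on metric
  differences and calibration-curve fairness.
* Net benefit is reported without confidence intervals.
* The five-level race category is synthetic at the margins the
  profiles publish; subgroup structure within "Non-White" is
  unconstrained because the source tables do not report per-category
  outcome rates.
* Fairness metrics presume the recorded outcome is the ground truth;
  if the group disparity partly reflects underdiagnosis, a model
  matching the recorded rates perpetuates it — the benchmark ratio is
  reported precisely so this can be seen, not solved.

```{r example}
library(ppdfair)
ex <- run_experiment(run_config(seed = 1))
format_grid(ex$grid)
autoplot(ex, threshold = 0.3)
```
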