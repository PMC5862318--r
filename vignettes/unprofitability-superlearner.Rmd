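---
title: "Predicting enrollee unprofitability with a super learner: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enrollee unprofitability with a super learner: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unprofitr)
```

## The problem

In individual health-insurance markets with community rating and risk
adjustment, an insurer cannot price or refuse enrollees by health status, but
it can still *shape its benefits* — most visibly the prescription-drug
formulary — to attract enrollees it expects to profit from and deter those it
expects to lose money on. Whether that incentive has any teeth is an
empirical question: after risk-adjustment transfers, is anything about an
enrollee's drug utilization still predictive of how unprofitable they are?

`unprofitr` implements that analysis as a reusable, fully testable pipeline:

1. derive an individual-level **unprofitability** outcome from plan-payment
   formulas (`add_plan_payments()`);
2. predict it from binary drug-utilization indicators with a **super
   learner** ensemble over 15 candidate learners (`fit_super_learner()`);
3. evaluate honestly with **nested cross-validation**, relative-efficiency
   comparisons, a falsification test and residual diagnostics
   (`nested_cv_evaluate()`, `falsification_test()`, `residual_report()`).

Because real enrollee-level claims data are proprietary, the package ships a
synthetic cohort generator (`generate_cohort()`) that reproduces the
*statistical structure* the analysis relies on, so every stage can be
exercised and verified end to end.

## The unprofitability outcome

Let $C_i$ be enrollee $i$'s annual cost and $S_i$ a positive, diagnosis-based
risk score. With community rating, every plan charges the market-average
premium $M_i = \bar C$. The (simplified) risk-adjustment transfer is

$$A_i = \left(\frac{S_i}{\bar S} - 1\right)\bar C,$$

so revenue is $R_i = \bar C \, S_i/\bar S$, profit $F_i = R_i - C_i$, and

$$U_i \;=\; -F_i \;=\; C_i - \bar C\,\frac{S_i}{\bar S}.$$

Two exact identities follow and are enforced in the tests: transfers sum to
zero (budget neutrality) and the cohort mean of $U_i$ is zero — risk
adjustment redistributes, it does not create or destroy, revenue. $U$ is also
scale-equivariant in costs and invariant to rescaling all risk scores.
Premium variation by age, geography or smoking status is deliberately
excluded (no configuration option is offered): allowing it would break the
mean-zero identity that anchors both interpretation and testing. A cohort of
one enrollee is permitted with a warning ($U_1 = 0$ trivially).

```{r payments}
vocab <- generate_vocabulary()
cohort <- generate_cohort(vocab, cohort_config(vocab, n = 2000, seed = 1))
cohort <- add_plan_payments(cohort)
c(mean = mean(cohort$unprofit), median = median(cohort$unprofit),
  sd = sd(cohort$unprofit))
```

The mean is zero by construction; the negative median with a large standard
deviation is the signature of heavy-tailed health spending — most enrollees
are mildly profitable, a few are catastrophically unprofitable.

## What the synthetic cohort emulates

The generator reproduces the features of large commercial claims data that
the method's behaviour depends on; its defaults are the package's fixed
study conditions:

* **Indicator hierarchy.** 239 therapeutic-class indicators aggregating into
  31 therapeutic groups, plus 8 generic-status and 5 maintenance-category
  indicators. Group, generic and maintenance indicators are exact ORs of
  their member classes. Two classes stand in for HIV antivirals and MS
  biological response modifiers: low prevalence (0.4% / 0.2%), very high
  cost effects ($25,000 / $30,000), always forced through the screener.
* **Zero inflation.** 30% of enrollees have no drug spending at all (all
  indicators zero); drug spending is roughly 15% of total spending.
* **Heavy tails.** Non-drug annual cost is a two-part model — a Bernoulli
  indicator of any spending (85%) times a lognormal severity
  (sdlog 1.4, mean $3,000 overall) — plus, with probability
  2×10⁻⁴, an additive Pareto(5×10⁵, 1.5) catastrophic outlier that is
  independent of every indicator. Class effects enter additively in
  expectation with mean-one lognormal noise, so
  $E[C\mid X]$ is exactly the configured linear index; that is what makes
  the generator's selection properties provable rather than approximate.
* **Within-group correlation.** Classes in the same therapeutic group share
  a latent per-enrollee uniform with probability `group_assoc` (default
  0.3), a copula construction that leaves marginal prevalences exact.
* **Partial risk capture — the phenomenon of interest.** The risk score is
  a noisy, mean-normalized copy of expected cost in which class $c$'s
  effect is attenuated by `risk_capture[c]` (default Beta(8, 2), mean 0.8).
  With capture 1 and no noise, risk adjustment neutralizes a class's
  selection signal *exactly in expectation*; any capture below 1 leaves a
  residual association between that class and $U$ for the learners to find.
  The generator therefore makes the target of the whole analysis a known,
  tunable quantity: give one class a $5,000 effect with capture 0 and the
  user-vs-non-user gap in mean unprofitability recovers $5,000 up to
  simulation error (an acceptance test does exactly this at n = 200,000).
* **Demographics** (age ≈ 42, 49% female) are generated for summary output
  only and are never predictors — they are already handled by risk
  adjustment in the market being modelled.

What it does **not** emulate: the joint distribution of real therapeutic
classes, diagnosis-driven risk-score error structure, multi-year cost
dependence, or any propensity-matched market population. A green test suite
therefore certifies the *method and its implementation*, not any claim about
a particular insurance market.

All randomness flows from one integer seed through named substreams
(indicators, costs, risk noise, folds, falsification outcome), so every
stage is independently reproducible and the whole pipeline is bit-for-bit
repeatable.

## The learner library

Five algorithms are crossed with three variable sets, giving the default
$K = 15$ library (`learner_library()`), with ids suffixed `.f`, `.g`, `.l`:

| algorithm | implementation | settings |
|---|---|---|
| `nnet` | `nnet::nnet` | one hidden layer of 2 units, `decay = 0.1`, `maxit = 40` |
| `lasso` | `glmnet::cv.glmnet(alpha = 1)` | λ at 10-fold internal-CV minimum, 50-knot grid |
| `ridge` | `glmnet::cv.glmnet(alpha = 0)` | as above |
| `tree` | `rpart::rpart(method = "anova")` | `cp = 0.01`, `minsplit = 20`, unpruned |
| `glm` | `lm.fit` | main terms, rank-pivoted least squares |

Variable sets: **full** (`.f`) — all class indicators plus generic and
maintenance flags (group aggregates are excluded as exact ORs of their
members); **groups** (`.g`) — group, generic and maintenance indicators
only; **screened** (`.l`) — the capped-lasso selection described below.

Settings the method description leaves open are fixed here as package
defaults: the penalized fits select λ at the internal-CV *minimum* (not the
1-SE rule) over a 50-knot grid; the tree is used unpruned at `cp = 0.01`
with rpart's internal cross-validation and surrogate machinery disabled
(nothing consumes them); the neural net does not standardize its binary
inputs but centers/scales the dollar outcome internally for optimizer
stability, with `decay = 0.1` and 40 BFGS iterations — ample for a two-unit
linear-output net and sized so that full nested-CV runs at the
n = 20,000 study scale complete in minutes on one core. All are adjustable
via `sl_control()`.

Degenerate inputs never crash a fit: a constant outcome (or any fitting
failure) degrades to a mean-predicting fit with a warning, mirroring how a
production pipeline must behave inside hundreds of automated fold fits.
Collinear columns in the linear learner are resolved by rank-pivoted least
squares (aliased coefficients set to zero), which leaves predictions
identical to any other least-squares solution on the training span.
Predictions of the convex learners are invariant to predictor-column
permutation up to solver tolerance; the neural net is invariant only up to
optimization error, since its random initialization assigns starting
weights by column position and its objective is non-convex.

## The capped lasso screener

`screen_variables()` defines the `.l` set: fit one lasso path (100
logarithmic knots from the smallest empty-set λ downward, no
standardization, intercept never counted), walk λ downward, and keep the
largest active set of size ≤ 10. When the active set jumps from ≤ 10
straight past the cap between adjacent knots — simultaneous entrants — the
set at the larger λ is kept and the tied entrants are excluded. The chosen
set always comes from a *single* λ; there is no mixing across the path. The
result is augmented with the forced HIV and MS class ids if absent. The
screener involves no randomness at all: selection is driven purely by the
cap rule, not by cross-validation, which is the only reading under which "a
larger penalty excluding the ties" is well defined. Inside cross-validation
the screener runs once per fold on training rows only
(`screen_within_fold()`); the three `.l` learners of a fold share that one
selection, because the screener defines a variable set, not a per-learner
step.

## The super learner

`fit_super_learner()` implements the three steps:

1. **Out-of-fold predictions.** Balanced random `v`-fold assignment
   (sizes differ by at most one); every learner fits on each fold's
   training rows and predicts its validation rows, filling the $n \times K$
   matrix $Z$. Row $i$ is only ever predicted by fits that never saw
   $U_i$ — the property the leakage tests assert directly.
2. **Convex weights.** $\hat\alpha$ minimizes
   $\sum_i (U_i - \sum_k \alpha_k Z_{ik})^2$ over the probability simplex.
   This is solved as the simplex-constrained quadratic program itself:
   Lawson–Hanson non-negative least squares (normalized) provides a warm
   start, and accelerated projected gradient descent (step $1/L$ from the
   largest eigenvalue of the $K \times K$ Gram matrix, convergence
   tolerance $10^{-14}$ on the iterate) takes it to the global optimum of
   the convex problem. Normalized NNLS alone is the common shortcut and is
   usually indistinguishable, but only the exact simplex solution
   *guarantees* the invariant that the ensemble's CV objective is no worse
   than any single learner's — an invariant the tests assert, so the
   package solves the problem it states. If all $K$ columns of $Z$ are
   identical the problem is degenerate and uniform weights are returned
   with a warning; $K = 1$ forces $\alpha = 1$.
3. **Refit.** Every learner refits on the full data (screened learners
   re-screen on the full data) and the ensemble predicts
   $\hat\Psi_{SL}(x) = \sum_k \hat\alpha_k \hat\Psi_k(x)$, so ensemble
   predictions always lie inside the per-row envelope of learner
   predictions. A learner that fails outright on the full data is dropped
   with its weight renormalized and a prominent warning.

Fold assignment is simple random, not stratified by outcome; learner-level
seeds are derived from `(run seed, fold, learner id)` only — never from the
data — which is what makes the leakage tests exact.

## Evaluation

Performance metrics are pooled single-sum formulas over out-of-fold
predictions: $\mathrm{CV\,MSE} = n^{-1}\sum_i (U_i - z_i)^2$ and
$\mathrm{CV}\,R^2 = 1 - \sum_i (U_i - z_i)^2 / \sum_i (U_i - \bar U)^2$
(negative values are reported as-is), with relative efficiency
$\mathrm{CV}\,R^2_k / \mathrm{CV}\,R^2_{SL}$. Because the ensemble's own
weights are tuned on $Z$, an honest estimate for the super learner requires
**nested** cross-validation: `nested_cv_evaluate()` wraps the entire
procedure — inner folds, per-fold screening, weight estimation, refit — in
an outer 10-fold loop (both fold counts default to 10) and pools the outer
out-of-fold predictions. The report carries one metric row per learner plus
the ensemble, per-outer-fold weight vectors, and a robust residual summary
flagging residuals more than 6 MADs from the median (with the generator's
Pareto component these flags are dominated by a handful of
catastrophic-cost enrollees, exactly as in real spending data).

`falsification_test()` is the negative control: the outcome is replaced by
a Gaussian draw with the empirical mean and SD of $U$ — the marginal family
is a documented package choice — independent of every predictor, and the
nested CV is rerun. Any R² meaningfully different from zero indicates
leakage; correct implementations round to 0.0%.

```{r nested, eval = FALSE}
ev <- nested_cv_evaluate(cohort, seed = 1)
tidy(ev)
autoplot(ev)
```

## Problem sizes and numerical tolerances

Sizes used by the shipped tests and acceptance script are the package's
own choices: payment identities are checked to $10^{-8}$ relative
tolerance; weight-estimation oracles to $10^{-3}$ against dense grid
search; the falsification headline runs at n = 20,000 with the full
15-learner library and nested 10 × 10 CV, the repeated-seed falsification
check at n = 3,000 across five seeds; the selection-signal recovery check
at n = 200,000. Structural and oracle tests use cohorts of a few hundred
rows with reduced fold counts.

## Known limitations

* The generator's class effects are additive in expectation; real claims
  exhibit interactions and dose/duration structure the full variable set
  cannot represent here, so the relative ranking of learners on synthetic
  cohorts should not be read as a forecast of their real-data ranking.
* The risk score is a direct transform of expected cost rather than the
  output of a regulatory diagnosis-to-score formula; `risk_capture` is a
  stylized, per-class knob for risk-adjustment imperfection.
* CV R² values carry no confidence intervals, and with weak residual
  signal the nested-CV estimate is noticeably conservative at small n.
* The neural net, with two hidden units and binary inputs, is close to
  linear in practice; it contributes diversity, not expressive depth.
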