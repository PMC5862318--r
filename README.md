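# unprofitr

Super learner prediction of health-plan enrollee unprofitability from
prescription-drug utilization.

## The problem

In community-rated insurance markets with risk adjustment (such as the ACA
Marketplaces), insurers cannot price or deny coverage by health status —
but they can tune the drug formulary to deter enrollees they expect to lose
money on. That incentive only exists if, *after* risk-adjustment transfers,
drug utilization still predicts enrollee unprofitability. `unprofitr` is a
tested, reusable pipeline for that question, aimed at health economists and
biostatisticians studying service-level selection.

The outcome is derived from plan-payment accounting. With premium
$M_i = \bar C$ (the market mean cost) and transfer
$A_i = (S_i/\bar S - 1)\,\bar C$ for diagnosis-based risk score $S_i$,
individual unprofitability is

$$U_i = C_i - \bar C \, \frac{S_i}{\bar S},$$

which has cohort mean exactly zero. $U_i$ is predicted from binary
drug-utilization indicators (therapeutic classes nested in therapeutic
groups, plus generic-status and maintenance-category flags) by a **super
learner**: five algorithms (two-unit neural network, internally
cross-validated lasso and ridge, ANOVA regression tree, main-terms linear
regression) crossed with three variable sets (full, therapeutic groups, and
a capped-lasso screened set of at most ten variables always augmented with
the HIV and MS drug classes), $K = 15$ learners combined by the convex
weights $\hat\alpha$ minimizing 10-fold cross-validated squared error.
Honest performance — CV MSE, CV R², relative efficiency — comes from
nesting the entire procedure in an outer 10-fold cross-validation, plus a
falsification test on an outcome simulated independently of all predictors.

Because enrollee-level claims data are proprietary, the package includes a
synthetic cohort generator reproducing the structure the analysis relies
on: 239 classes in 31 groups, ~30% of enrollees with zero drug spending,
heavy-tailed costs with rare catastrophic outliers, and a risk score that
captures a configurable fraction of each class's cost signal — so the
residual selection signal the method hunts for is a known, plantable
quantity. See the methods vignette
(`vignettes/unprofitability-superlearner.Rmd`) for the model, defaults and
design decisions.

## Worked example

```r
library(unprofitr)

vocab <- generate_vocabulary()
#> <drug_vocabulary> 239 classes in 31 groups; 8 generic + 5 maintenance indicators
#> forced classes: cls_119, cls_191

cohort <- generate_cohort(vocab, cohort_config(vocab, n = 2000, seed = 1)) |>
  add_plan_payments()
round(c(mean_cost = mean(cohort$cost), zero_drug = mean(cohort$drug_cost == 0),
        mean_U = mean(cohort$unprofit), median_U = median(cohort$unprofit),
        sd_U = sd(cohort$unprofit)), 2)
#> mean_cost zero_drug    mean_U  median_U      sd_U
#>   4688.67      0.31      0.00  -1945.81  18394.41
```

Mean unprofitability is $0 by construction (risk adjustment redistributes
revenue, it does not create it); the negative median with a large SD is the
heavy right tail of health spending — most enrollees are mildly profitable,
a few are catastrophically unprofitable.

```r
sl <- fit_super_learner(cohort, seed = 1)
sl
#> <super_learner> 15 learners, 10-fold CV, n = 2000
#> weights:  ridge.l = 0.35, lasso.f = 0.31, lasso.l = 0.31, glm.f = 0.02, nnet.g = 0.01
head(tidy(sl)[order(-tidy(sl)$weight), ], 3)
#> # A tibble: 3 × 5
#>   id      algorithm variable_set weight    cv_risk
#>   <chr>   <chr>     <chr>         <dbl>      <dbl>
#> 1 ridge.l ridge     screened      0.347 338503493.
#> 2 lasso.f lasso     full          0.312 338512331.
#> 3 lasso.l lasso     screened      0.312 338512331.
```

The weights are the convex combination over the 15 candidate learners; here
the penalized regressions on the screened and full sets carry nearly all of
it, and `cv_risk` is each learner's own cross-validated squared error
($^2$). Honest evaluation of the whole ensemble then uses nested CV:

```r
ev <- nested_cv_evaluate(cohort, seed = 1)   # outer 10-fold, heavier
tidy(ev)        # CV MSE, CV R^2, relative efficiency per learner + ensemble
autoplot(ev)    # three-panel comparison figure
falsification_test(cohort, seed = 1)  # ~0: no signal in an independent outcome
```

`run_pipeline(pipeline_config(...))` chains
generate → derive → fit → evaluate and writes the cohort CSVs, the fitted
ensemble JSON, the metrics JSON, a screened-variable audit JSON and a
timing log; `inst/cli/unprofitr` is a thin command-line wrapper over the
same functions.

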