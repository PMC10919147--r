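# survite

Counterfactual treatment recommendation for right-censored survival data,
built around the question a neuro-oncology registry cannot answer directly:
*which glioblastoma (GBM) patients actually benefit from adding chemotherapy
to adjuvant radiotherapy?* In observational registries ~90% of patients
receive chemoradiotherapy (CRT) and only ~10% radiotherapy alone (RT), with
strong selection (older patients get RT), so naive arm comparisons are
confounded. `survite` estimates each patient's **individual treatment
effect (ITE)** — the difference in predicted median survival between the two
arms — recommends an arm, and evaluates the recommendation with the standard
causal-survival toolbox.

## What is in the box

* **Synthetic registry generator** (`generator_params()`, `generate_cohort()`):
  a SEER-like GBM cohort with configurable covariate marginals, a logistic
  treatment-propensity model (age-dependent, ~90/10 CRT/RT), arm-specific
  Weibull proportional-hazards survival with treatment-effect heterogeneity
  (the CRT benefit attenuates with age and male sex and reverses for tumors
  extending into the ventricular system), independent exponential censoring
  plus an administrative horizon — and closed-form ground truth: the true
  propensity, the true median survival under both arms
  `median = scale * (log 2 / exp(lp))^(1/shape)`, and the true optimal arm.
* **T-learner counterfactual models** (`fit_tlearner()`): one survival model
  per arm — Cox proportional hazards, log-rank-splitting survival tree,
  random survival forest, or a Cox-loss neural network (`deepsurv`) trained
  with decoupled weight decay (AdamW).
* **Balanced twin-head survival network** (`fit_bites()`): a shared
  representation trunk, an integral-probability-metric penalty (RBF-kernel
  MMD by default, entropic Wasserstein optional) aligning the two arms'
  latent distributions, and two Cox-loss risk heads, trained end-to-end:

  `L = NPLL_RT(head0(phi(X_RT))) + NPLL_CRT(head1(phi(X_CRT))) + alpha * IPM(phi(X_RT), phi(X_CRT))`

* **Recommendation and evaluation** (`compute_ite_and_recommend()`,
  `recommendation_effect()`, `performance_by_arm()`): per-patient predicted
  medians and ITE; consistent-vs-inconsistent hazard ratio (HR) and
  IPTW-adjusted HR (propensity on all encoded covariates, robust variance);
  5-year restricted-mean-survival-time difference (dRMST); number needed to
  treat NNT = RMST(consistent)/dRMST; per-arm Harrell C-index and IPCW
  integrated Brier score with bootstrap CIs; within-recommendation-group
  Kaplan–Meier comparisons.
* **Interpretation** (`survshap_t()`, `aggregate_rankings()`,
  `behavior_odds_ratios()`): time-dependent Shapley attributions of the
  predicted survival function (exact coalition enumeration or permutation
  sampling; local accuracy `baseline(t) + sum_j phi_j(t) = S(t|x)` holds by
  construction), importance-rank aggregation across patients, and logistic
  odds ratios describing who gets recommended RT.
* **Pipeline** (`run_config()`, `run_pipeline()`, `exec/survite` CLI):
  generate → split (stratified 80/20) → fit → recommend → evaluate →
  interpret, with one master seed, JSON-lines logging and byte-reproducible
  CSV outputs.

## Worked example

```r
library(survite)

p  <- generator_params(n = 4000, seed = 11)   # SEER-like GBM world
co <- generate_cohort(p)
sp <- split_cohort(co, 0.8, seed = 5)
tr <- cohort_subset(co, sp$train); te <- cohort_subset(co, sp$test)

m   <- fit_bites(tr, seed = 7)                # balanced twin-head network
ite <- compute_ite_and_recommend(m, te$covariates, actual = te$treatment)
mean(ite$recommended == te$ground_truth$optimal_arm)
#> [1] 0.8975

recommendation_effect(te, ite, n_boot = 1000, seed = 1)
#> <recommendation_report> tau = 60 months
#>   HR  0.486 (0.399-0.593) | HRa 0.795 (0.570-1.110)
#>   dRMST 9.04 (6.75-11.46) months | NNT 2.19 (1.80-2.83)
#>   counts: n_consis=654 n_inconsis=146 n_rrt=108 n_rcrt=692
```

Reading: the network recommends RT for 108/800 held-out patients (the true
RT-optimal share in this world is ~9%) and identifies the truly optimal arm
for 90% of them. Patients whose actual treatment matched the
recommendation die at roughly half the rate of those treated inconsistently
(HR 0.49); after inverse-probability weighting on all covariates the
protective association attenuates toward (and here overlaps) the null, as
expected when the consistency groups differ systematically in age. Following
the recommendation is worth ~9 months of restricted mean survival over
5 years; about 2.2 patients must follow it to save one expected event.
Within the CRT-recommended group, actually receiving CRT is significantly
better (log-rank p = 0.003); within the RT-recommended group it is not
(p = 0.52) — the signature of a recommender that has found the subgroup for
whom chemotherapy adds nothing.

The same run end-to-end, from the shell:

```sh
Rscript exec/survite run-all --config my_config.json --out-dir runs/demo
```

## Layout

```
R/                 implementation (generator, survival stats, metrics,
                   learners, balanced network, recommendation, evaluation,
                   Shapley interpretation, pipeline, serialization)
exec/survite       CLI: generate | fit | recommend | evaluate | interpret | run-all
scripts/acceptance.R   acceptance report
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette (model, assumptions, design choices)
```
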