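# permfitr

Permutation feature importance **testing** for black-box risk models, built
around postoperative-infection prediction in ICU surgical cohorts.

Flexible classifiers predict postoperative infection well from baseline
demographic, preoperative and operative features, but they do not say *which*
features matter, with what confidence. `permfitr` implements PermFIT — a
permutation-based importance test with formal inference — for four learners
(RBF SVM, random forest, XGBoost, and a bootstrap-filtered "stable" deep
neural network ensemble), plus the evaluation protocol around it: stratified
10-fold cross-validation with per-fold select-then-refit, imbalance-aware
metrics (PR-AUC), and a feature-significance frequency matrix. A seeded
synthetic ICU-cohort generator with a known outcome model makes every stage
testable without any external data.

## The test

For feature $X_j$, let $\hat\pi(\mathbf{X})$ be the fitted conditional risk
and $\mathbf{X}^{(j)}$ the design with $X_j$'s values randomly permuted
(one-hot blocks move as units). Each sample contributes the log-likelihood
contrast

$$
\Lambda_{ij} = Z_i \log\frac{\hat\pi(\mathbf{X}_{i\cdot})}{\hat\pi(\mathbf{X}^{(j)}_{i\cdot})}
 + (1-Z_i) \log\frac{1-\hat\pi(\mathbf{X}_{i\cdot})}{1-\hat\pi(\mathbf{X}^{(j)}_{i\cdot})} .
$$

With $\hat\Lambda_j$ the mean contrast and
$\widehat{\mathrm{Var}}[\hat\Lambda_j]$ its estimated variance (sample
variance over samples divided by $n$), the statistic
$\lambda_j = \hat\Lambda_j / \sqrt{\widehat{\mathrm{Var}}[\hat\Lambda_j]}$
is referred to the upper normal tail. Predictions are always obtained by
cross-fitting — the model scoring a row never saw that row — which is what
keeps the test calibrated for null features.

## Worked example

```r
library(permfitr)

cohort <- generate_cohort(n = 1500, seed = 42)   # 25 features, 2 true signals
cohort
#> permfit_cohort: n = 1500, p = 25, prevalence = 0.247
#>   signal set: preoperative_infection, age

imp <- permfit(learner_config("xgb", seed = 42), cohort,
               S = 5, R = 5, alpha = 0.05, seed = 42)
head(imp[order(imp$p_value), ], 5)
#>                      feature lambda_hat   var_hat  z_stat   p_value significant
#>                          age  0.1006243 7.198e-05 11.8607 9.470e-33        TRUE
#>       preoperative_infection  0.0227239 2.354e-05  4.6836 1.410e-06        TRUE
#>                liver_disease  0.0020234 8.629e-07  2.1782 1.470e-02        TRUE
#>  peripheral_vascular_disease  0.0008657 1.985e-07  1.9430 2.601e-02        TRUE
#>                      obesity  0.0004043 3.023e-07  0.7353 2.311e-01       FALSE
```

The two generated signals (age, coefficient 1.0 per SD; preoperative
infection, coefficient 1.2, odds ratio ≈ 3.3) dominate with p-values many
orders below 0.05, while the 23 null features hover around the nominal
level — two are (marginally) false-positive here, as expected at a raw 5%
per-feature test without multiplicity correction. `lambda_hat` is the mean
log-likelihood contrast (larger = more predictive information destroyed by
permuting the feature), `var_hat` its estimated variance, and `z_stat` the
normal test statistic.

The full protocol — shared stratified folds, per-fold selection, refit,
held-out metrics, frequency matrix — is one call:

```r
res <- run_pipeline(cohort, c("rf", "xgb", "dnn"), k = 10, seed = 7,
                    fast = TRUE)
res$aggregated$xgb        # mean (95% CI) per metric over the 10 folds
res$frequency             # features x learners: folds significant (0-10)
export_report(res$aggregated, res$frequency, "report/")
```

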