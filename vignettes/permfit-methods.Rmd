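---
title: "Permutation feature importance testing for ICU infection risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation feature importance testing for ICU infection risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permfitr)
```

## The problem

A sizeable fraction of ICU patients undergo surgery, and roughly a quarter of
them develop a postoperative infection. Flexible classifiers (support vector
machines, random forests, gradient boosting, deep networks) predict this risk
well from baseline demographic, preoperative and operative features, but they
are black boxes: they rank features at best, and a ranking carries no error
control. `permfitr` implements a permutation-based feature importance *test*
(PermFIT) that attaches a p-value to each feature's conditional contribution
to any of these models, together with the evaluation protocol that goes with
it: stratified 10-fold cross-validation in which each training fold selects
its significant features and refits before scoring the untouched test fold.

Because the real cohort behind this design (a credentialed ICU EHR database)
cannot ship with a package, `permfitr` includes a first-class synthetic
cohort generator with the same feature schema and a fully known
outcome-generating model. Everything downstream — learners, test, pipeline,
metrics — is exercised against that known truth.

## The importance score and its test

Let $\pi(\mathbf{X}) = \Pr(Z = 1 \mid \mathbf{X})$ be the conditional risk
given features $\mathbf{X} = (X_1, \dots, X_p)$, and let
$\mathbf{X}^{(j)}$ denote $\mathbf{X}$ with its $j$-th feature replaced by an
independent permutation $X_j'$ of its values. The population importance of
$X_j$ is the expected squared difference
$\Lambda_j = E\,[\pi(\mathbf{X}) - \pi(\mathbf{X}^{(j)})]^2$, which is zero
exactly when $X_j$ contributes nothing beyond the other features. The
empirical quantity the package works with is the per-sample log-likelihood
contrast

$$
\Lambda_{ij} = Z_i \log\frac{\hat\pi(\mathbf{X}_{i\cdot})}{\hat\pi(\mathbf{X}^{(j)}_{i\cdot})}
 + (1 - Z_i)\log\frac{1 - \hat\pi(\mathbf{X}_{i\cdot})}{1 - \hat\pi(\mathbf{X}^{(j)}_{i\cdot})},
$$

whose mean $\hat\Lambda_j = \frac1n \sum_i \Lambda_{ij}$ estimates the
importance. With $\widehat{\mathrm{Var}}[\hat\Lambda_j]$ the sample variance
of the $\Lambda_{ij}$ divided by $n$, the test statistic is

$$
\lambda_j = \frac{\hat\Lambda_j}{\sqrt{\widehat{\mathrm{Var}}[\hat\Lambda_j]}},
$$

compared with the upper tail of the standard normal. The test is one-sided
because the population importance is nonnegative: only a large positive mean
is evidence of contribution. The squared-difference form is the population
target; the log-likelihood contrast is what the inference runs on.

Two implementation points matter for validity:

* **Cross-fitting.** `permfit()` splits the data into `S` folds (default 5),
  fits the learner on each complement and scores only held-out rows. A model
  scoring its own training rows produces spurious positive contrasts for
  null features; cross-fitting is what makes the null distribution of
  $\lambda_j$ approximately standard normal.
* **Block permutation.** One-hot indicator columns of a categorical feature
  move as a unit under a single row permutation; permuting indicator columns
  independently would fabricate impossible rows.

`R` independent permutations per feature (default 10) are averaged per
sample before pooling, which reduces permutation noise without biasing the
score; `R = 1` reproduces the literal single-permutation formulation. The
variance estimate is taken on the averaged per-sample scores, so the test
remains valid for any `R`. When a learner never uses a feature, every
contrast is exactly zero and the variance estimate degenerates; the record
is then reported non-significant with a warning, which is common and
harmless for boosted trees with few rounds.

No multiple-testing correction is applied by default: selection operates at
a raw per-feature level of 0.05, matching the protocol this package
implements. The `alpha` argument is the only knob.

## Learners

All four learners sit behind one contract: `fit_learner()` /
`predict_proba()`, with predictions clipped to $[10^{-6}, 1 - 10^{-6}]$
because the score takes logarithms. Defaults are the study settings:

* **Random forest** (`ranger`): 1000 probability trees, minimum node size 3.
* **XGBoost**: learning rate 0.3, maximum depth 5, up to 5 boosting rounds
  chosen by internal 5-fold cross-validation on training data.
* **SVM** (`e1071`): RBF kernel; gamma and cost tuned over
  $\{10^{-3}, \dots, 10^{3}\}$ in decade steps by internal cross-validation;
  probabilities via Platt scaling. The Platt link is strictly monotone in
  the decision value, so ranking metrics are unaffected by it.
* **DNN**: four hidden layers (50, 40, 30, 20), ReLU activations, sigmoid
  output, cross-entropy loss, minibatch Adam (initial rate $10^{-3}$,
  reduce-on-plateau decay), 1000 epochs at batch size 30. The optimizer
  family and architecture follow the protocol; ReLU, Adam, dropout 0.3 on
  hidden layers and decoupled weight decay $10^{-4}$ are this package's
  documented defaults where the protocol names only the behavior
  ("adaptive learning rate") and not the algorithm. The network is
  implemented in compiled code (RcppArmadillo) and is bit-reproducible
  under a fixed seed.

### The stable DNN ensemble

A single network of this size is unstable at a few thousand samples:
training runs memorize, and random initialization moves held-out accuracy
noticeably. `fit_stable_dnn()` implements the bootstrap-and-filter remedy:
fit `B` networks on bootstrap resamples (default `B = 100`; the protocol
does not fix `B`), score each member by cross-entropy on its out-of-bag
rows, rank members best-first, and keep the prefix of size $k^\*$ that
minimizes the cross-entropy of the averaged prediction on the full training
sample — the training-loss-minimizing kept count. Out-of-bag scoring is this
package's choice of "scoring algorithm"; the kept-count rule follows the
stated training-loss minimization. Prediction is the arithmetic mean of the
kept members, clipped.

## The evaluation pipeline

`run_pipeline()` reproduces the protocol end to end:

1. One stratified fold plan (default $k = 10$) is built once and shared
   bit-identically by every learner, so models are compared on identical
   splits. Stratification by outcome is on by default: at 25% prevalence,
   unstratified 10% folds have unstable class counts. Fold sizes differ by
   at most one.
2. Per fold, PermFIT runs **only on the training rows**; features
   significant at $\alpha = 0.05$ are selected. If the selected set is empty
   the fold refits on all features and is flagged (`fallback_all`); the
   default conditions never hit this case.
3. The learner is refitted on the training rows restricted to the selected
   features' columns and scored on the test fold, whose rows were never
   seen by any fitting, tuning or selection step (asserted structurally in
   the tests).
4. Fold metrics — accuracy, ROC-AUC, PR-AUC, sensitivity, specificity, F1 at
   the fixed threshold 0.5 — are aggregated as mean $\pm 1.96\,
   \mathrm{sd}/\sqrt{k}$, truncated to $[0,1]$. The normal fold-level CI is
   a documented choice; the protocol does not state its CI construction, and
   a per-patient bootstrap is a reasonable alternative the package does not
   default to.
5. The feature × learner frequency matrix counts the folds (0–10) in which
   each feature was significant — the basis of the significance heatmap.
   `export_report()` writes the formatted metric table
   (`0.817 (0.811, 0.822)`-style cells), the frequency matrix and a
   full-precision JSON.

ROC-AUC uses the rank (Mann–Whitney) form with ties counted 1/2; PR-AUC
uses the average-precision step rule, never linear interpolation, so a
constant scorer scores exactly the prevalence — the right baseline for a
25%-prevalence outcome. The classification threshold stays at 0.5 with no
Youden-style search, which is consistent with the low-sensitivity /
high-specificity pattern such cohorts show at 25% prevalence.

## The synthetic cohort generator

`default_schema()` declares 25 features: age (normal, mean 64.2; SD 15 as a
documented assumption), gender, ethnicity, marital status, insurance,
admission type and location, surgery type (7 categories led by cardiac at
40.45%), and binary comorbidity/history indicators (hypertension 58.28%,
diabetes 26.54%, congestive heart failure 19.9%, ...). Marginals printed in
the cohort description are used as-is; the rest are typical ICU-surgical
values documented in the schema. Five Elixhauser-style indicators fill the
set to 25, since only about 20 features are named explicitly; they are
assumptions, not reported facts.

`generate_cohort()` draws features mutually independently (only marginals
are reported; an optional correlation knob was considered and rejected as
untestable against any published quantity) and generates the outcome from a
logistic model whose linear predictor may include linear, pairwise
interaction, squared and threshold terms — enough structure for nonlinear
learners to dominate linear ones by construction when desired. The
intercept is calibrated by root finding so the mean true risk matches the
25% prevalence target within 0.005. The default truth
(`default_effects()`) has two signals — preoperative infection with
logistic coefficient 1.2 (odds ratio ≈ 3.3) and age with 1.0 per marginal
SD — and 23 nulls.

What the generator does **not** emulate: feature correlation (real
comorbidities co-occur), missingness (the complete-case contract rejects
missing cells outright), temporal structure, and coding noise in
ICD-derived outcomes. Passing tests therefore demonstrate the statistical
properties of the method — calibrated type-I error, power, leakage-free
evaluation — not the clinical numbers of any real cohort; the published
headline metrics require the credentialed source data and are out of reach
by design.

## Numerical choices and problem sizes

* Probability clipping at $10^{-6}$ bounds every log in the score.
* Intercept calibration solves to $10^{-8}$ and errors if the 0.005
  prevalence tolerance cannot be met in a $\pm 35$ bracket.
* Continuous features are standardized with training-fold constants for the
  DNN and SVM; trees receive raw values (they are invariant to monotone
  rescaling, and raw values keep split points interpretable).
* Degenerate variance (all scores equal) yields p = 1 for a non-positive
  mean and p = 0 otherwise, with a warning.
* Per-fold, per-feature and per-member seeds are derived deterministically
  from one master seed, so every result in the package is exactly
  reproducible; tree learners reproduce bit-identically, the DNN exactly as
  well since its RNG lives in the compiled trainer.
* The `fast = TRUE` profile (100 epochs, `B = 20`, 200 trees, narrower SVM
  grid) is the package's continuous-integration profile. The statistical
  test suite runs at desk scale: 100 all-null cohorts of n = 500 for type-I
  error, 50 replicates of n = 2000 for power, 5 seeds of the full 10-fold
  pipeline at n = 2000 for end-to-end recovery. These sizes are the
  package's own choices for a laptop-class machine; the method itself has
  no size-dependent logic.

## Known limitations

* Permutation importance is marginal-permutation based; with strongly
  correlated features it can split importance across a correlated group or
  leak some signal into permuted copies. Conditional (knockoff-style)
  schemes are out of scope.
* The importance analysis is exploratory variable identification within a
  predictive framework, not confirmatory hypothesis testing; no
  multiplicity control is applied by default.
* The DNN is a from-scratch trainer adequate for tabular cohorts of this
  shape; it does not aim to be a general deep-learning framework (no GPU,
  no alternative architectures).
* Empty-selection folds refit on all features; at very small n or very weak
  signal this fallback can blur the selected-vs-all comparison.
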