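---
title: "Methods: quantifying validation bias in small-sample machine learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying validation bias in small-sample machine learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(valbias)
```

## The problem

Studies that apply supervised classification to expensive human data (brain
imaging, motion and eye tracking, clinical panels) typically work with tens
of participants and tens to hundreds of features. In that regime the choice
of validation protocol dominates the reported accuracy: if feature selection
or hyperparameter tuning ever sees the rows that are later used for
evaluation, the estimate is optimistically biased, and the bias grows as the
sample shrinks. `valbias` provides a fully seeded Monte-Carlo laboratory for
measuring that bias: dataset generators with a known ground truth, the two
model-development pipelines most common in this literature, five validation
protocols that differ only in *where* development happens, and sweep drivers
that turn accuracy distributions into means, confidence intervals and tests
against the 50% two-class chance level.

## The stated world of the generators

All simulations draw from two dataset families with balanced binary labels
(`1` is the class carrying any shift):

* **Pure noise** — every entry i.i.d. standard normal; features are
  unrelated to labels, so every leakage-free protocol has expectation 50%.
* **Discriminable** — 50 features of which 10 carry a class-conditional mean
  shift of 0.5 (unit SD). The Mahalanobis separation is
  $\sqrt{10 \cdot 0.25} \approx 1.58$, putting the Bayes accuracy near
  $\Phi(1.58/2) \approx 79\%$, consistent with the observed plateau of about
  77% for leakage-free protocols at large N.

Defaults that the generators fix, and why:

* sample sizes are even, with exactly N/2 per class — 50% is then the exact
  null for any balanced evaluation;
* rows are generated class-blocked and then shuffled by the seed, so no
  downstream stage can silently benefit from input order;
* `meta` stores generator, parameters and seed; `regenerate_dataset()`
  reproduces the matrix bit-for-bit.

Features that the generators deliberately do *not* emulate: correlated
features, heavy tails, outliers, missing values, class imbalance. A green
test here establishes protocol properties (bias, chance-level recovery,
leakage), not robustness to messy data.

**Seed discipline.** Every stochastic operation derives a child seed from a
single master seed and a fixed path of integers (`derive_seed()`, a
multiplicative-congruential mix kept below $2^{31}$). Results are therefore
reproducible independent of execution order, and sweeps share each generated
dataset across all schemes compared at a design point, making between-scheme
comparisons paired by construction.

## Pipelines

Two canonical recipes (presets of `pipeline_spec()`):

* **`svm`** — SVM-RFE feature selection followed by a grid-tuned RBF-kernel
  SVM ($C = 2^j$, $j = 1..7$; $\gamma = 2^i$, $i = -1..-7$; 10-fold inner
  CV).
* **`logreg`** — two-sample t-test ranking (top 10 by $|t|$) followed by a
  grid-tuned penalized logistic regression (L1/L2 crossed with $C = e^i$,
  $i = 0..9$). The grid-size sweep instead uses `make_grid("logistic", m)`
  with exponents evenly spaced on $[-4, 4]$, as both parameter ranges are
  part of the stated designs; the even spacing on the exponent scale is this
  package's recorded choice where the design leaves it open.

The SVM (linear and RBF) is solved by the package's own SMO solver
(`src/smo.cpp`), a LIBSVM-style dual solver with second-order working-set
selection, stopping tolerance $10^{-3}$ and an iteration cap of $10^5$
(cap hits are flagged in results, never fatal). It is verified in the test
suite against analytic two-point solutions and the KKT optimality
conditions. Two performance choices matter at N = 1000: kernels are
precomputed once per grid search, and solves are warm-started from the
previous RFE step or the previous `C` on the same kernel (the dual optimum
moves little, and any warm-started solution still satisfies the same
stopping tolerance).

The logistic classifier is glmnet's penalized binomial model with
`lambda = 1/(n C)` — the standard bridge between the sum-of-losses `C`
parametrization and glmnet's mean-loss `lambda` — without standardization
(the generators are already unit-scale). Nearly unpenalized fits on
separable small folds have no finite optimum (perfect separation); the
coordinate-descent cap then triggers and the fit falls back to the largest
converged penalty on its path. Such events are counted
(`logistic_cap_hits()`), not raised.

### Feature selection details

* **t-test selection**: classic pooled-variance two-sample t per feature;
  top `k = 10` by $|t|$, ties to the lower feature index. Zero pooled
  variance with a nonzero gap yields an infinite sentinel that outranks all
  finite statistics; a constant feature scores 0. Pooled variance (not
  Welch) matches the balanced equal-variance generators and is the classic
  default where the method is named only "two-sample t-test".
* **SVM-RFE**: starting from all features, each iteration fits a linear SVM
  with `C = 1` on the available rows, records the accuracy of the current
  subset, and removes the feature with the smallest squared weight (ties to
  the lower index). The returned set is the visited subset with the highest
  step accuracy; accuracy ties prefer the smallest subset (parsimony). How
  the per-step "classification accuracy" is measured is not pinned down by
  the source description; this package's default is stratified 10-fold CV of
  the same linear SVM on the training rows (reseeded per call), with
  `eval_method = "resubstitution"` available for sensitivity analysis.

## The five protocols

With development = feature selection + hyperparameter tuning + final fit:

| scheme | selection | tuning | fit | evaluation |
|---|---|---|---|---|
| `split` | train portion | train portion | train portion | held-out 20% once |
| `kfold` | **all rows** | **all rows** | per-fold training rows | each fold |
| `nested` | per-fold training rows | per-fold training rows | per-fold training rows | each fold |
| `fs_out` | **all rows** | per-fold training rows | per-fold training rows | each fold |
| `tune_out` | per-fold training rows | **all rows** | per-fold training rows | each fold |

Bold marks the deliberate leak. Every result carries a **ledger** recording
the exact row indices each stage saw; `audit_ledger()` computes per-fold
overlaps between development and evaluation, and the test suite asserts the
zero/nonzero pattern above — the suite proves each scheme is what it claims
rather than assuming it.

Recorded design choices:

* Overall ACC is the unweighted mean of the per-fold accuracies (the stated
  formula), not the pooled-prediction accuracy.
* The non-nested `kfold` refits the classifier in each fold with frozen
  features and hyperparameters (a per-fold "train a model" step is part of
  the protocol description).
* `tune_out`'s single global tuning needs a feature space even though the
  leak under study is tuning; by default it sees the features selected on
  all rows, with `tune_feature_space = "all"` as the alternative wiring —
  the exact wiring is not pinned down by the protocol description.
* The train/test split fraction defaults to 0.2 ("a portion" is otherwise
  unspecified) and is configurable.

**Folds.** Assignments use a seeded shuffle within class blocks followed by
one global round-robin pass: fold sizes always differ by at most one, and
stratification is exact whenever `K` does not exceed the per-class counts.
For larger `K` — which the stated designs require: the fold-count sweep runs
to leave-one-out, the ratio sweep reaches N = 14 under 10-fold CV, and the
toy experiment tunes 10-fold on 10 rows — the same rule degrades gracefully
to the most class-balanced assignment possible. We deliberately accept this
instead of a hard per-class-count error, which would make those stated
designs unrepresentable; only `K < 2` or `K > n` is an error. All folds and
splits are stratified because unstratified folds at N = 20 frequently
produce single-class evaluation folds.

**Tie-breaks in tuning.** Grids are stored smallest `C` first, then smallest
$\gamma$ (RBF) or L2 before L1 (logistic); score ties resolve to the
earliest combo, i.e. the most regularized model.

## Sweeps and summaries

`run_sweep()` iterates design points × runs × pipelines × schemes with
50 runs per point at publication scale (`*-quick` presets downscale runs and
points, never the protocol logic). `summarize_accuracy()` reports the mean,
the 95% t-interval $\bar x \pm t_{0.975, R-1}\, s/\sqrt{R}$, and the
two-sided one-sample t-test against 50%; zero-variance samples yield a
zero-width interval and a degenerate flag. Between-scheme comparisons are
reported as unpaired two-sample t-tests (as in the source analyses) with the
paired variant alongside, since the shared-dataset design actually pairs
them. No multiple-testing correction is applied, matching the per-point 95%
reporting; at 50 sample-size points roughly 2–3 false positives per curve
are expected by chance. `fit_trend()` provides the 5th-order least-squares
polynomial used as a plotting aid.

Preset ranges follow the stated designs: sample sizes 20–1000 in steps of
20; feature counts 20–200 at N = 100; RBF grid sizes 2×2 to 20×20 and
logistic 2×2 to 200×2; fold counts from 2 to leave-one-out (values chosen so
every point is either stratifiable or exactly leave-one-out); ratio sweep
ratios {1/3, 1/2, 1, 2, 3, 10, 20}. For the ratio sweep the two stated
sample-size ranges disagree (14–446 in the figure caption, 42–446 in the
text); the preset follows the caption, with even N values
{14, 22, 42, 66, 100, 148, 222, 334, 446} so classes stay balanced. Whether
one generated dataset was shared across validation methods within a run is
also not stated; this package regenerates per (run, point) and shares the
dataset across the methods compared at that point, which pairs the
comparisons without coupling design points.

## The two illustrative experiments

* **`toy_boundary()`** — 10 standard-normal samples (5 per class, two
  features); one row per class is the designated validation pair (a balanced
  pair makes 50% the exact null). A pooled model is grid-tuned and fitted on
  all 10 rows, a held-out model on the 8 training rows; both are scored on
  the pair, and on their own training rows. Tuning on 10 (or 8) rows
  degrades to leave-one-out inner folds. Whether the original demonstration
  re-tuned per repeat or fixed the hyperparameters is ambiguous ("the same
  settings as in the main analyses"); per-repeat grid tuning is the default,
  and `tune = FALSE` provides the fixed-parameter mode.
* **`toy_selection()`** — 50 noise samples, pools of 20–100 features,
  top-10 by $|t|$ selected either on all rows or on the 80% training rows;
  the mean $|t|$ of the selected features is then recomputed on the training
  and on the 20% validation rows. Pooled selection makes held-out noise look
  discriminative, increasingly so with pool size; split selection stays at
  the independent-noise null.

## Survey statistics

`survey_statistics()` relates reported accuracy to sample size across
surveyed studies: KS normality tests of N raw and log10-transformed, Pearson
r (with df and $R^2$) on (log10 N, accuracy), Spearman's rho on the raw
scale, the median N, and per-modality correlations (skipped below 3
studies). The normality test is Lilliefors-style — mean and SD estimated
from the data, with the Dallal–Wilkinson p-value approximation — because
the published D statistics with p-values imply composite normality testing;
the known-parameter variant is available (`estimated = FALSE`). The
repository ships a synthetic fixture generator
(`make_survey_fixture()`: log-uniform sample sizes on [20, 2000], linear
accuracy trend in log10 N with Gaussian noise, clipped to (50, 100]) and a
small synthetic example CSV — not the real supplementary table, which is a
PDF that users must transcribe themselves (header
`study,n,accuracy,year,modality,classifier`).

## Numerical choices and degenerate inputs

* SMO: tolerance $10^{-3}$, iteration cap $10^5$, curvature floor
  $10^{-12}$; decision ties (`f = 0`) predict class 1.
* glmnet: `thresh = 1e-8`, `maxit = 1e5`, short decreasing lambda path
  ending at the target for pathwise stability; single-feature designs are
  padded with a zero column (glmnet requires two).
* Zero-variance accuracy samples: degenerate CI/test flags instead of NaN.
* Constant features: t = 0; label-copy features: infinite-t sentinel.
* Non-convergent SVM fits: flagged (`n_unconverged`, `converged`), results
  still recorded.

## Known limitations

* Only balanced two-class problems; no probability calibration, class
  weights, or kernels beyond linear/RBF — outside the study's scope.
* The SMO solver is exact but single-threaded; publication-scale sweeps
  (50 runs × 50 points with SVM-RFE at N up to 1000) are CPU-days, which is
  why presets exist at two scales.
* Survey statistics reproduce the published values only given a user
  transcription of the supplementary study table; the shipped fixtures are
  synthetic stand-ins and are labelled as such.
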