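---
title: "Identifying CABG surgical site infections from claims data: methods"
author: "ssiclaims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying CABG surgical site infections from claims data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssiclaims)
```

## The problem

Surveillance of surgical site infection (SSI) after coronary artery bypass
graft (CABG) surgery is done by infection-control personnel who review charts
against CDC criteria. That is accurate but labor-intensive, so researchers
routinely fall back on administrative claims data, usually by searching for
SSI-related ICD-9-CM diagnosis codes. Code lists are known to both miss true
cases and flag false ones, which distorts patient-level outcome research.
This package implements a family of *alternative identification models* that
replace or supplement the code lists with medical-use surrogates — antibiotic
exposure, length of stay, and operative extent — and evaluates every model
against the surveillance label as the reference standard.

A practical constraint shapes everything: in the Taiwan National Health
Insurance claims that motivated this design, treatment items are aggregated
per hospitalization *without time stamps*. A dose of cefazolin given before,
during and after surgery appears only as a total. None of the models may
therefore use sequence or timing information, and prophylactic antibiotic use
cannot be separated from therapeutic use.

## The six surrogate criteria

`compute_criteria()` derives six binary indicators per episode, each cut at a
threshold chosen for Taiwanese CABG practice (3–7 days of prophylaxis is
common, so dose thresholds sit above the prophylactic range):

| criterion | definition | default threshold |
|---|---|---|
| c1 | distinct antibiotic substances | > 3 |
| c2 | total antibiotic dose (DDD) | > 7 |
| c3 | cefazolin dose (DDD) | > 7 |
| c4 | any second-line antibiotic | — |
| c5 | length of stay (days) | > 21 |
| c6 | vessels obstructed (operation-duration proxy) | > 2 |

Doses are expressed in WHO defined daily doses (DDD); the conversion from raw
dose happens upstream in the claims system and is out of scope here. The
second-line catalog (`second_line_catalog()`) holds 18 broad-spectrum/reserve
agents by ATC code; cefazolin, the standard first-line prophylactic agent, is
deliberately excluded and identified by its own ATC code J01DB04 (the source
tables never print the cefazolin code, so the WHO code is adopted and kept
configurable). All comparisons are strict "greater than": the wording behind
each criterion is "more than", so boundary equality fails.

## The models

* **ICD-9-CM model** (`classify_icd9()`): positive when a listed code appears
  among the *secondary* diagnoses of the index admission (996.03, 996.61,
  996.72, 998.5) or among the primary/secondary diagnoses of readmissions or
  ambulatory visits within a year of discharge (the septicemia range
  038.0–038.4 plus 038.8, 038.9, 682.6, 682.9, 780.6, 790.7, 875.0, 875.1,
  891.0, 891.1, 996.03, 996.61, 996.72, 998.3, 998.5). Restricting the index
  admission to secondary positions avoids infections present on admission.
* **Models 1–3, criteria counting** (`classify_strict()`,
  `classify_moderate()`, `classify_loose()`): positive when all six, at least
  `k` (default 3), or at least one criterion holds. The moderate rule's
  source wording, "more than three criteria", is read as *at least three*: the
  literal reading (four or more) would sit next to the all-six strict rule
  instead of between the extremes, defeating its "moderate" label. `k` is an
  argument, so the literal reading is one keystroke away.
* **Model 4, stepwise logistic regression** (`train_logistic_model()`): the
  six surrogate variables enter in continuous form (the second-line indicator
  has no underlying continuum and stays 0/1). Selection is classical
  stepwise on likelihood-ratio p-values at 0.05 entry / 0.05 removal;
  the fit is IRLS to a 1e-8 coefficient tolerance. The fitted probability is
  always oriented to P(SSI): published risk models of this kind sometimes
  model the complementary outcome (recognizable by an intercept around +10
  and negative slopes with a cutoff like 0.03); that is the mirror image
  (negate the coefficients, map cutoff c to 1 − c) and is not reproduced.
  The probability cutoff maximizes the Youden index J = sensitivity +
  specificity − 1 on the training ROC curve (`roc_and_youden()`).
* **Model 5, classification tree** (`train_cart_model()`): CART grown by Gini
  improvement and pruned by minimal cost-complexity pruning with V-fold
  cross-validation. Implemented from scratch in the package (see below);
  `rpart` is used in the test suite only as an independent cross-check.

`confusion()` and `compute_metrics()` evaluate any of these against the
surveillance label, reporting sensitivity, specificity, PPV, NPV and accuracy
in the "percent (numerator/denominator)" style of the source study's tables;
`run_experiment()` fits everything on a training cohort ("center A"), scores
a verification cohort ("center B") that contributes nothing to fitting, and
formats both tables.

## Numerical and algorithmic conventions

Where analyses of this kind usually delegate details to commercial
statistics software, this package fixes them explicitly so results are
reproducible:

* **ROC sweep**: cutoffs are the distinct score values, the decision rule is
  "positive when score ≥ cutoff", AUC is the trapezoidal area which equals
  the Mann–Whitney statistic with ties counted one half. Youden ties break
  toward the smallest cutoff (keeps sensitivity maximal at equal J), taken as
  the first exact maximum of the sweep.
* **CART**: candidate thresholds are midpoints between consecutive distinct
  values; "value ≤ threshold" goes left, equality included; split ties break
  by variable input order, then by the smaller threshold; leaf class ties
  predict non-SSI (the prevalent class). Growth defaults are
  `minsplit = 20`, `minbucket = 7`, `maxdepth = 5` — a scale appropriate for
  cohorts of roughly a thousand episodes — with equal misclassification costs
  and training-data priors. Weakest-link pruning records one entry per
  collapse event; cross-validated selection evaluates geometric-mean
  penalties on class-stratified folds and picks the minimum-cost penalty,
  breaking ties toward the simpler tree ("1-SE" is available as an option,
  since the source says only "most appropriate tree"). With fewer minority
  cases than folds, the fold count is reduced with a warning rather than
  silently proceeding.
* **Logistic regression**: separation (diverging coefficients or fully
  saturated fitted probabilities) is flagged on the returned fit with a
  warning, never hidden; singular designs are an error naming the collinear
  columns.
* **ICD-9 codes**: canonical form is dotted; undotted 5-digit codes get the
  dot inserted after the third digit; undotted 4-digit codes are ambiguous
  and rejected.
* **Rounding**: printed percents are half-up to two decimals, matching the
  published tables (base `round()` is round-half-even and would print
  e.g. 99.11 where the tables print 99.12).

## The synthetic cohort generator

The claims and surveillance data of the motivating study are confidential, so
`simulate_cohort()` generates cohorts whose class-conditional (SSI vs
non-SSI) distributions match the published cohort-characteristics table of
the 1,017-surgery training center (24 SSIs): sex, cefazolin use, second-line
use and the ICD flag are Bernoulli per class; age is normal truncated to
[20, 100] (under-20 patients are excluded upstream); vessels obstructed take
values {1, 2, 3} with probabilities solved from the class mean and SD;
length of stay is lognormal with scale from the class median and shape from
the class mean; antibiotic-type counts are 1 + negative binomial; doses are
gamma. Only first and second moments (and the LOS median) are published, so
the family choices are the package's own; they are swappable per block via
`cohort_spec(families = ...)`.

Three design points deserve explanation:

* **Total dose decomposition.** The episode invariant cefazolin ≤ total dose
  must hold. Flooring an independently drawn total at the cefazolin dose
  would inflate the non-SSI total-dose mean by roughly 14% (measured by
  simulation), so the generator instead draws total = cefazolin + an
  independent gamma non-cefazolin component whose mean and variance are
  solved so the class-level total matches the published moments exactly in
  expectation.
* **Second-line margins.** The published table's second-line row is
  internally inconsistent (the "all" and "non-SSI" columns both read 115
  while the SSI column reads 20); the generator resolves it as non-SSI
  95/993 and SSI 20/24 so the margins reconcile (95 + 20 = 115).
* **Independence within class.** No covariance information is published, so
  variables are sampled independently within class, and the ICD flag is a
  marginal per-class Bernoulli rather than a mechanistic consequence of
  infection events. This is the generator's most consequential limitation:
  see below.

The verification center is simulated with the same class-conditional blocks
at n = 845 and prevalence 17/845, because only its size and SSI count are
published. The SSI-class LOS standard deviation (58.72, larger than its
mean) cannot be matched by a lognormal anchored at the published median; the
heavy-tailed lognormal is an assumption, not known intent.

## What the tests show — and what they cannot

The test suite checks the arithmetic and the algorithms against independent
oracles: closed-form 2×2 logits and `glm()` for the IRLS fitter; brute-force
pair counting and `pROC` for the AUC; brute-force cutoff search for the
Youden index; a slow exhaustive Gini search for `best_split()`; exhaustive
depth-2 tree search as a lower-bound comparison and `rpart` for the grower;
and the published performance tables, whose every cell is reproduced exactly
from its confusion counts. Generator calibration is verified on 50,000
episodes per class (class-conditional distributions do not depend on
prevalence, and at the realistic 2.4% prevalence the SSI class of a 100,000
cohort would be so small that sampling noise alone approaches the 2%
tolerance). The stepwise acceptance check uses one signal and one noise
candidate so that the per-replicate false-selection probability equals the
nominal 5% entry level, making 18-of-20 the matching binomial bound; with
several noise candidates the familywise entry rate (1 − 0.95^k) would make
that bound unattainable for any classical stepwise at its stated thresholds.

Passing tests on synthetic cohorts demonstrate that the pipeline is
implemented correctly under the published marginal moments — not that the
models would attain the published performance on real claims. Two gaps
matter. First, within-class independence makes the classes *more* linearly
separable than real data: with ~24 SSI events and several strongly shifted
covariates, the stepwise logistic model quasi-completely separates the
training cohort in a substantial fraction of simulated cohorts (the fit is
flagged, training AUC reaches 1.0), which makes its in-sample PPV optimistic
and means the tree model's PPV advantage over the regression model — the
central finding on the real data — does not reliably re-emerge in-sample
under simulation. The qualitative extremes do reproduce: the loose rule
attains 100% sensitivity with single-digit PPV, the strict rule the reverse.
Second, the exact split points and node populations of the published tree
depend on the unavailable training data and are out of reach by
construction; the tree module reproduces the *method*, not the figure.

## Problem sizes

The shipped tests run the oracle comparisons on 200 random ROC datasets
(n ≤ 50) and 100 random tree datasets (n ≤ 30); parameter recovery on
100,000 simulated episodes; generator fidelity on 100,000 balanced episodes;
and the qualitative-ordering experiment on ten seeded 1,017-episode cohorts
— the training-center size of the motivating study.
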