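---
title: "Modelling post-therapy T-cell clonal expansion from pre-treatment features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-therapy T-cell clonal expansion from pre-treatment features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expandnet)
```

## The problem

Checkpoint-inhibitor immunotherapy helps only a minority of patients, and
the leading single biomarkers — tumor mutation load and PD-L1
immunohistochemistry — are imperfect predictors of who. One finer-grained,
earlier readout of response is the expansion of tumor-infiltrating
lymphocyte (TIL) clones in peripheral blood shortly after treatment:
T-cell clones seen in the tumor before therapy whose abundance in blood
rises afterwards. `expandnet` models the **log number of expanded TIL
clones** as a function of attributes measured *before* treatment, so a
fitted model can be applied to a new, untreated patient.

The package targets the cohort regime this problem actually lives in:
about twenty patients, 19 pre-treatment attributes in three categories
(7 clinical, 7 tumor, 5 circulating), occasional missing values, and more
model features than patients.

## The model

Each binary attribute (prior intravesical BCG, albumin < 4) enters as a
single 0/1 column. Each continuous attribute $x$ enters twice, as $x$ and
$\log(1+x)$, to give a linear model a cheap handle on saturating
dose-response shapes; the standard schema yields $2 + 17 \times 2 = 36$
columns. The response is $y = \log(1 + \text{count})$; the pseudocount
(default 1) keeps patients with zero expanded clones in the model, and
both pseudocount and base are configurable and recorded.

The regression is the elastic net: minimize over $(\beta_0, \beta)$

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2
  + \lambda\left(\rho\|\beta\|_1 + \tfrac{1-\rho}{2}\|\beta\|_2^2\right).$$

Sparsity ($\ell_1$) gives automatic feature selection; the ridge term
stabilizes correlated columns — which matters here, since every
continuous attribute contributes a strongly correlated $(x, \log(1+x))$
pair. $\rho$ is selected from $\{0.1, 0.5, 0.7, 0.9, 0.95, 0.99\}$ and
$\lambda$ from a 100-point geometric path between $\lambda_{\max}(\rho)$
(the smallest penalty that zeroes every coefficient) and
$10^{-3}\lambda_{\max}$, both by leave-one-out cross-validation on the
training set. Ties in cross-validated error resolve to the largest
$\lambda$, then the smallest $\rho$ — the sparser, more regularized
model. A 1000-tree random forest with library defaults is included
purely as a comparator; on cohorts this small it overfits badly and is
excluded from every headline analysis.

### Leakage-safe evaluation

Training-set error is meaningless at $p > n$ (it can be driven to zero),
so the package reports only *held-out* performance, from an outer
leave-one-out loop: for each patient, the full pipeline — median
imputation of missing cells, centering and scaling, hyperparameter
selection by *inner* leave-one-out, and the final fit — is rebuilt from
scratch on the remaining patients, and the held-out patient is predicted.
Imputation and standardization statistics are fitted on training rows
only; the test suite asserts that perturbing a held-out patient's
attributes leaves that fold's fitted model bit-identical.

Accuracy is summarized as held-out variance explained,

$$\mathrm{VE} = 1 - \frac{\mathrm{MSE}_{\mathrm{LOOCV}}}{\tfrac1n\sum_i (y_i - \bar y)^2},$$

whose denominator is the in-sample MSE of the constant-mean predictor
(empirical variance, denominator $n$; whether $n$ or $n-1$ was intended
by convention cannot be settled from the description we follow, so $n$
is the default and the choice is configurable). VE can be negative when
a model generalizes worse than the mean; reported "nominal" values clamp
at zero, and raw values are always retained.

### Permutation inference

Two nonparametric tests are built on the LOOCV error, both one-sided
(small error = evidence of association), both with the add-one
convention $p = (\#\{b: \mathrm{MSE}_b \le \mathrm{MSE}_{\mathrm{obs}}\} + 1)/(B+1)$,
which makes the p-value exactly valid for any fixed pipeline:

* **Response permutation** — the global null of no feature–response
  association: responses are shuffled across patients uniformly at
  random and the *entire* nested pipeline is rerun per replicate.
* **Category permutation** — the conditional null that one category
  (clinical, tumor or circulating) carries no information *given that
  the other features remain available*: one random patient permutation
  is applied jointly to every raw attribute of the category, before
  encoding, so each $(x, \log(1+x))$ pair and the within-category
  correlation structure move between patients intact. Whether the
  original analysis permuted raw attributes or encoded columns is not
  documented; raw-attribute permutation is the coherent choice and is
  what we implement.

Replicates use RNG substreams keyed on `(seed, replicate)`, so results
are independent of execution order. A mode that freezes hyperparameters
across replicates would be much faster but tests a different null; it is
not what the package reports.

### Triage of durable clinical benefit

For patients labelled with durable clinical benefit (DCB: progression
free at six months), the package compares biomarkers by a deliberately
simple rule: treat everyone whose score reaches a threshold, set the
threshold as high as possible subject to *all* DCB patients being
treated, and report the fraction of non-DCB patients treated. Non-DCB
patients tied with the threshold count as treated — the conservative
convention that guarantees 100% DCB capture under any tie structure.
The statistic depends only on ranks, so it is invariant to monotone
transformations, and the test suite checks it against a brute-force
minimum over all thresholds. Held-out predicted expansion is compared
against missense SNV count, expressed neoantigen count and PD-L1
staining. PD-L1 is carried as a comparator column only — it is not among
the 19 model attributes.

## The synthetic cohort generator

Real patient data cannot ship with the package, so every stage is
exercised on synthetic cohorts with known ground truth. The generator
emulates the *statistical shape* of the study cohort:

* 21 patients; the 19-attribute schema;
* marginals by attribute type — Bernoulli for the two binary attributes,
  rounded log-normals spanning one to two orders of magnitude for counts
  (mutation loads, neoantigen counts, TCR counts, chemotherapy history),
  scaled Betas for bounded fractions (clonality, T-cell fraction,
  top-clone frequency);
* a sparse linear signal: `support_size` (default 4) coefficients of
  equal magnitude and random sign placed on standardized encoded
  columns, preferentially the $\log(1+x)$ transforms, matching the
  model family; placement can be restricted to one category
  (`signal_categories`) for localization experiments;
* noise sized via the oracle variance explained
  $\mathrm{VE}^* = \mathrm{Var}(X\beta)/(\mathrm{Var}(X\beta)+\sigma^2)$
  (default target 0.8 — a high but imperfect signal, the regime the
  method is designed for), or directly via `noise_sd`;
* counts quantized back through the response transform
  (`count = max(0, round(e^y - 1))`), a baseline log-expansion level of
  2.5 (a typical patient has about a dozen expanded clones);
* 5% missingness on continuous attributes; a Bajorin-score fallback
  column; DCB drawn from a logistic link on the standardized noiseless
  linear predictor (intercept $-0.3$, slope $1.5$: roughly 40% DCB,
  positively tied to expansion); PD-L1 staining weakly linked to the
  same signal.

What the generator does **not** emulate: the joint covariance of real
attributes. Real cohorts carry strongly correlated informative blocks
(missense SNV count, expressed SNV count, neoantigen counts rise and
fall together); here attributes are drawn independently, so a planted
signal of total strength $\mathrm{VE}^* = 0.8$ split over four
independent columns gives each column a marginal correlation near the
largest *spurious* correlation among the ~32 noise columns at $n = 21$.
Passing tests therefore demonstrate correctness of the machinery and
calibration of the tests, but held-out VE on these synthetic cohorts is
highly seed-dependent and its typical values sit well below what a real
cohort with correlated informative features can support. This is a
property of the simulation scope, not of the estimator: an independent
glmnet-based implementation of the same nested pipeline shows the same
behaviour on the same cohorts.

## Numerical choices

* **Solver.** Coordinate descent on centered data via Gram-matrix
  (covariance) updates, warm-started along the $\lambda$ path, written
  in C++ — the nested design (21 outer folds × 6 ratios × 100 penalties
  × 20 inner folds, re-run hundreds of times inside permutation tests)
  makes the solver the package's hot spot. Stopping follows standard
  coordinate-descent practice: the largest variance-weighted squared
  coefficient change in a sweep, relative to the response variance, must
  fall below the tolerance (default $10^{-7}$). Unit tests pin the
  solver to closed forms: least squares at $\lambda \to 0$,
  soft-thresholding on orthonormal designs at $\rho = 1$, the ridge
  normal equations at $\rho = 0$ (a test-only mode), the exact zero
  model at $\lambda \ge \lambda_{\max}$, and objective values never
  worse than glmnet's on random problems.
* **Preprocessing order.** Encode, then impute, then standardize, so
  medians are taken per encoded feature on its own scale. Median of an
  even count is the midpoint of the two central order statistics.
  Standardization is center/scale to population standard deviation
  (denominator $n$, configurable), applied to all columns including
  binary ones; a column constant in training gets scale 1 and becomes
  all-zero after centering — uninformative rather than undefined.
* **Degenerate inputs.** A column with no observed training values is an
  error naming the column (and the fold, in cross-validation). A
  constant response makes every penalty equivalent; the tie rule then
  returns the null model with intercept $\bar y$.
* **Problem sizes in the test suite.** Experiments that re-run the full
  nested pipeline inside permutation loops are expensive (one canonical
  nested LOOCV is a few seconds of coordinate descent), so the suite
  runs them at sizes chosen to keep the whole run in minutes: test
  calibration uses 30 null cohorts at $B = 99$ with an exact binomial
  acceptance band, signal-localization uses 10 cohorts at $B = 99$, and
  both use a reduced hyperparameter grid (single $\rho = 0.95$, 15-point
  path) — the properties under test (exact validity, localization) do
  not depend on grid breadth. Recovery experiments run at the canonical
  configuration across 20 seeds. The acceptance script mirrors these
  choices and uses $B = 999$ for its single significance test.

## Known limitations

* Held-out VE at $n = 21$ has enormous sampling variability; single
  cohorts can land anywhere from strongly negative to near the oracle.
  Any application to a real cohort of this size should report the
  permutation p-value alongside VE, never VE alone.
* The category permutation test conditions on the remaining features
  but is reported unadjusted across the three categories, mirroring the
  original analysis; apply your own multiplicity control if categories
  are compared.
* The generator's marginal-only scope (above) makes synthetic recovery
  rates conservative relative to cohorts with correlated informative
  features.
* The random-forest comparator is deliberately untuned; conclusions
  about forests in general should not be drawn from it.
* The optional adapter for the publicly hosted processed cohort data is
  limited to `load_cohort()` over the canonical column layout documented
  in `default_schema()`; mapping the external repository's own file
  layout requires a download and is out of scope offline.
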