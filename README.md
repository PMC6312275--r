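# expandnet

Multifactorial prediction of post-therapy T-cell clonal expansion from
pre-treatment clinical, tumor and circulating features, on small
immunotherapy cohorts.

## What problem this solves

Anti-PD-L1 therapy benefits a minority of patients, and single
biomarkers (tumor mutation load, PD-L1 staining) rank patients
imperfectly. A finer-grained, earlier readout of response is the number
of tumor-infiltrating lymphocyte (TIL) clones that expand in peripheral
blood shortly after treatment. `expandnet` models the log of that count,
`y = log(1 + expanded clones)`, from 19 attributes measured *before*
treatment (7 clinical, 7 tumor, 5 circulating), so the model applies to
new, untreated patients — and then asks whether ranking patients by
predicted expansion triages durable clinical benefit (DCB,
progression-free at 6 months) better than any single biomarker.

The statistical core, for cohorts with `p = 36 > n ≈ 21`:

* **Encoding** — binary attributes as 0/1; each continuous attribute `x`
  as the pair `(x, log(1+x))`: 36 design columns from 19 attributes.
* **Elastic net** — minimize
  `(1/2n) Σᵢ (yᵢ − β₀ − xᵢᵀβ)² + λ(ρ‖β‖₁ + (1−ρ)/2 ‖β‖₂²)`,
  with `ρ` chosen from {.1, .5, .7, .9, .95, .99} and `λ` from a
  100-point geometric path by leave-one-out cross-validation.
* **Nested leave-one-out evaluation** — per held-out patient, the whole
  pipeline (median imputation, standardization, hyperparameter
  selection, fit) is rebuilt on the other patients; accuracy is reported
  as held-out variance explained,
  `VE = 1 − LOOCV-MSE / empirical variance of y`.
* **Permutation tests on LOOCV error** — a global test (responses
  permuted) and a per-category conditional test (a category's raw
  attribute block permuted jointly across patients, with the other
  features still available), both with the exact-valid p-value
  `(k+1)/(B+1)`.
* **Triage statistic** — the minimum fraction of non-DCB patients that
  must be treated, under a single score threshold, so that every DCB
  patient is treated.
* **Synthetic cohort generator** — cohorts with the study's statistical
  shape plus ground truth (true support, oracle VE), so calibration and
  recovery are testable without any patient data.

## Worked example

```r
library(expandnet)

sim <- simulate_cohort(simulation_config(seed = 1))
sim$cohort
#> <cohort: 21 patients, 19 attributes>
#>   responses recorded: 21; DCB labels: 21

loocv <- run_loocv(sim$cohort)
loocv
#> <LOOCV (elastic_net, 21 patients): MSE 2.007, baseline 5.239, VE 61.7% (nominal 61.7%)>

biomarker_comparison(sim$cohort, loocv$predictions)[,
  c("biomarker", "treated_non_dcb", "n_non_dcb", "pct_non_dcb_treated")]
#>                    biomarker treated_non_dcb n_non_dcb pct_non_dcb_treated
#> 1        predicted_expansion               4         8                50.0
#> 2         missense_snv_count               5         6                83.3
#> 3 expressed_neoantigen_count               8         8               100.0
#> 4         pd_l1_staining_pct               8         8               100.0
```

Reading this: the constant-mean predictor has MSE 5.24 on this synthetic
cohort (the empirical variance of log expansion); the nested elastic net
reduces held-out MSE to 2.01, explaining 61.7% of the variance in
patients it never saw. Triaging by held-out predicted expansion treats
all DCB patients while treating only 4/8 (50%) of non-DCB patients;
single biomarkers need 83–100% on this cohort.

The full fit on all 21 patients, for the coefficient report:

```r
feats <- encode_features(sim$cohort)
pp <- fit_preprocessor(feats)
fit <- fit_elastic_net(apply_preprocessor(pp, feats),
                       derive_response(sim$cohort), preprocessor = pp)
fit
#> <elastic-net fit: rho = 0.99, lambda = 0.1832, 10/36 features retained>
plot_coefficients(fit)
```

Significance and ablations:

```r
permute_response_test(sim$cohort, B = 999)   # global association test
ablate_categories(sim$cohort)                # drop each category in turn
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "expandnet", package = "expandnet")`, with
subcommands `simulate`, `featurize`, `loocv`, `ablate`, `permtest`,
`triage`, `report`.

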