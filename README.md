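# cucurve

Clinical utility (CU) curves for risk prediction models, with the
model-evaluation workflow that surrounds them.

## The problem

A prediction model gives each patient an absolute risk of disease; turning
it into a prediction *rule* means choosing a risk threshold above which you
act — biopsy, catheterise, treat. ROC curves, C statistics, NRI and IDI all
measure model performance, but none of them tells a clinician what a
threshold *costs* in the unit they act in: patients flagged per true case
found.

The CU curve re-expresses the model's operating points on exactly that
axis. At each threshold *t* (rule: risk ≥ *t* is positive) it plots

- **y**: sensitivity = TP / (TP + FN), the fraction of cases captured;
- **x**: NNCOC = (TP + FP) / TP = 1 / PPV, the **n**umber **n**eeded to
  **c**apture **o**ne **c**ase.

The point where the curve first reaches 100 % sensitivity is clinically
special: every patient below that threshold is a non-case, so the length of
the horizontal segment at 100 % is the fraction of the cohort the model can
rule out entirely. Because NNCOC changes by discrete case/non-case counts it
is not monotone in the threshold — CU curves zigzag, and this package
deliberately preserves that rather than smoothing it away.

Around the curve, the package implements the standard evaluation toolkit:
maximum-likelihood logistic risk scoring, C statistics with DeLong
variance and confidence intervals, paired/unpaired DeLong and
patient-resampling bootstrap AUC comparisons, continuous (category-free)
NRI, IDI, and the Hosmer–Lemeshow calibration test — plus seeded synthetic
cohort generators so everything is testable without external data.

## Worked example

Generate a 303-patient cohort with a known logistic model (mixed
continuous/binary covariates, ~46 % outcome prevalence), fit the risk
model, and build the CU curve:

```r
library(cucurve)
coh    <- generate_logistic_cohort(n_patients = 303, seed = 42)
fit    <- fit_logistic(coh$design, coh$outcomes)
scored <- scored_cohort(fit$fitted_risks, coh$outcomes)
curve  <- build_cu_curve(scored)

curve
#> CU curve: 303 patients, 143 cases, 302 threshold points
#> 100% sensitivity first reached at threshold 0.04254: 285 flagged, NNCOC 2.0, 18 ruled out

c_statistic(scored)
#> C statistic 0.825 (95% CI 0.778-0.871), delong method; 143 cases / 160 non-cases

hosmer_lemeshow(scored)
#> Hosmer-Lemeshow: chi-square 9.569 on 8 df, P = 0.297 (10 groups)

threshold_for_sensitivity(curve, 0.90)
#>     threshold n_flagged true_positives sensitivity specificity       ppv    nncoc
#> 189 0.3887682       190            129   0.9020979     0.61875 0.6789474 1.472868
```

Reading the output: flagging everyone with risk ≥ 4.25 % captures all 143
cases while letting 18 of 303 patients (6 %) be ruled out without
intervention, at a cost of 2.0 patients flagged per case found. If 90 %
sensitivity suffices, a threshold of 39 % risk flags only 190 patients and
the NNCOC drops to 1.5. `write_curve_table()` serialises the full
threshold-by-threshold table; `render_curves()` draws the two-panel
ROC + CU figure; `continuous_nri()`, `idi()`, `compare_auc_delong()` and
`compare_auc_bootstrap()` compare two models on the same patients.

A command-line driver covers the three standard workflows (single model,
two nested models, subgroup comparison):

```sh
Rscript inst/cli/cucurve.R --input cohort.csv --outcome y \
  --covariates age,sex --covariates-b age,sex,marker \
  --seed 7 --out-dir results/
```

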