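# abxdelegate

Counterfactual antibiotic-prescribing policies that combine a machine-learned
infection risk with observed physician decisions.

## The problem

At an initial consultation for suspected urinary tract infection (UTI), the
definitive laboratory culture result arrives only days later, so the
physician must prescribe — or delay — under uncertainty.  Prescribing to a
patient without a bacterial infection ("overprescribing") fuels antibiotic
resistance; delaying treatment for a true infection has a sickness cost.
Given, for each consultation *i*, a machine-learned bacterial risk
*m<sub>i</sub>* ∈ [0, 1], the physician's decision *d<sub>i</sub>* ∈ {0, 1}
and the laboratory outcome *y<sub>i</sub>* ∈ {0, 1}, the package fits and
evaluates two counterfactual prescription rules δ:

* **full automation** — prescribe iff *m<sub>i</sub>* > *k*;
* **delegation** — delay if *m<sub>i</sub>* ≤ *k<sub>L</sub>*, prescribe if
  *m<sub>i</sub>* ≥ *k<sub>H</sub>*, and defer to the physician's observed
  decision in between.

Thresholds are chosen by constrained minimisation of antibiotic use,

&nbsp;&nbsp;min Σ (δ<sub>i</sub> − d<sub>i</sub>)&nbsp;&nbsp; s.t. &nbsp;
Σ y<sub>i</sub>(δ<sub>i</sub> − d<sub>i</sub>) ≥ 0,

i.e. cut prescriptions without reducing the number of treated infections —
which raises the aggregate payoff
Π = α Σ y<sub>i</sub>(δ<sub>i</sub> − d<sub>i</sub>) − β Σ (δ<sub>i</sub> −
d<sub>i</sub>) for *any* positive cost weights (α, β).  Because physicians
hold private diagnostic information (point-of-care dipstick and microscopy
tests, symptom assessment) that the risk score lacks — quantified per
consultation by ι<sub>i</sub> = |y<sub>i</sub> − m<sub>i</sub>| −
|y<sub>i</sub> − d<sub>i</sub>| — delegation can cut antibiotic use where
full automation, facing the same constraint, must *increase* it.

The confidential registry data this design was developed on are not
obtainable, so the package includes a calibrated synthetic cohort generator
(`generator_config()`, `calibrate_generator()`, `generate_cohort()`) whose
cohorts reproduce the documented structure: bacterial rate 0.38, risk-score
AUC 0.721, prescribing rates 0.61 / 0.26 conditional on positive / negative
tests, dipstick / microscopy use 72% / 13%, calibration on the 45-degree
line, and an inverted-U private-information profile.

## Worked example

```r
library(abxdelegate)

cohort <- generate_cohort(generator_config(seed = 5))
print(cohort)
#> <abx_cohort> 48406 consultations (seed 5)
#>   bacterial rate 0.374, prescribing rate 0.391

optimize_automation(cohort)
#> <automation policy> k = 0.407897  [objective 1183, constraint 0]

pol <- optimize_delegation(cohort)
print(pol)
#> <delegation policy> k_L = 0.317908, k_H = 0.592022  [objective -2579, constraint 0]

report <- bootstrap_policy_ci(cohort, pol, bootstrap_spec(n_samples = 100, seed = 3))
print(report)
#> Counterfactual policy outcomes
#>   k_L  0.318
#>   k_H  0.592
#>   Change in treated UTI, in %                 0.0  [-0.9, 1.0]
#>   Change in antibiotic use, in %            -13.6  [-14.4, -12.8]
#>   Change in overprescribing, in %           -32.7  [-33.8, -31.3]
#>   Physician decisions overruled, in %        14.9  [14.6, 15.3]
#>   Patients delegated to physicians, in %     45.2  [44.8, 45.7]
#>   consultations               48406 ->    48406
#>   uti                         18111 ->    18111
#>   treated_uti                 11018 ->    11018
#>   prescriptions               18911 ->    16332
#>   overprescribing              7893 ->     5314
```

Reading the output: the fitted delegation rule delays prescribing below risk
0.318, auto-prescribes above 0.592, and leaves the 45% of consultations in
between with the physician.  It cuts antibiotic use by 13.6% and
overprescribing by 32.7% while the number of treated infections is unchanged
(the constraint binds at 0), overruling 14.9% of observed decisions.  The
automation objective is *positive* (+1183 prescriptions): a single threshold
that must not reduce treated infections can only add prescriptions — the
complementarity between the risk score and physician information is what
delivers the reduction.  Bracketed intervals are 95% percentile bootstrap
CIs with predictions and thresholds held fixed.

Further entry points: `risk_bins()` (calibration and conditional-outcome
curves), `private_info()` and `diagnostic_rate_by_risk()` (where physicians
beat the score and why), `roc_curve()` / `auc_mann_whitney()`,
`sequential_reoptimize()` (deployment-style rolling refits),
`test_intensity_strata()` (sample-selection robustness), `run_pipeline()`
(end-to-end with all artefacts written to a directory; a thin CLI wrapper is
in `inst/scripts/run-pipeline.R`).

See `vignettes/delegation-policies.Rmd` for the model, calibration method,
numerical conventions and limitations.

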