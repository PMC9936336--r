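# catrisk

Competing-risks validation of cancer-associated thrombosis risk scores.

Ambulatory patients with active cancer face a high risk of venous
thromboembolism (VTE), and clinical risk assessment models are used to
target primary thromboprophylaxis. `catrisk` computes the two most relevant
scores from tabular patient records and provides the complete statistical
stack needed to validate them in a cohort where death before VTE is a
competing first event:

- **Khorana score** (0–6): 2 points for a very-high-risk tumor site
  (stomach/gastroesophageal, pancreas), 1 for a high-risk site, 1 each for
  hemoglobin < 10 g/dL or ESA use, leukocytes > 11 000/µL, platelets
  ≥ 350 × 10³/µL, BMI ≥ 35.
- **ONKOTEV score** (0–4): one point each for Khorana > 2, metastatic
  disease, macroscopic vascular/lymphatic compression, previous VTE;
  validated in the four levels 0 / 1 / 2 / >2.
- **Estimators**, all implemented in the package: product-limit cumulative
  incidence `F̂_k(t) = Σ_{t_i ≤ t} Ŝ(t_i−) d_k(t_i)/n(t_i)` with
  delta-method variance and log(−log) intervals; Gray's K-sample test on
  weighted subdistribution risk sets; Fine–Gray regression
  (IPCW-weighted partial likelihood, Newton–Raphson, robust sandwich
  variance); IPCW cumulative/dynamic time-dependent AUC; incidence-rate and
  events-per-variable arithmetic.
- **Synthetic cohorts**: a calibrated generator (`simulate_cohort()`)
  emulating a ~425-patient prospective cohort, so every pipeline stage is
  testable without patient-level data.

## Worked example

```r
library(catrisk)
coh <- simulate_cohort(sim_config(n = 425, seed = 7))
run_validation(coh)
```

```
=== score validation report (n = 425 ) ===
first events: VTE 74 | death 60 | censored 291
VTE incidence rate: 1.3 per 100 person-months

ONKOTEV strata:
 stratum   n vte cif_landmark
       0 101   7        0.069
       1 264  45        0.110
       2  51  16        0.216
      >2   9   6        0.444

Gray's test (rho = 0): chi-square = 35.46, df = 3, p = 9.733e-08
events per group: 0=7, 1=45, 2=16, >2=6

Fine-Gray subdistribution-hazard fit (n = 425; 74 events, 60 competing)
              coef   HR ci_low ci_high        p
khorana_gt2 0.5336 1.71   0.92    3.14 8.75e-02
metastatic  0.6006 1.82   1.06    3.13 2.93e-02
compression 1.2139 3.37   1.92    5.92 2.44e-05
prior_vte   1.0083 2.74   1.45    5.17 1.83e-03

time-dependent AUC (marker = ONKOTEV score):
 horizon_months  auc ci_low ci_high n_cases n_controls
              3 0.57   0.48    0.67      32        393
              6 0.62   0.54    0.69      51        374
             12 0.63   0.56    0.69      68        281

EPV check: 4 predictors x 10 events => n >= 400 (adequate)
```

Reading the output: the four score strata separate the 6-month cumulative
incidence of VTE monotonically (6.9% → 44.4% here), Gray's test rejects
equality of the four incidence curves, the Fine–Gray model quantifies each
component's subdistribution hazard ratio with death as a competing event,
and the time-dependent AUC summarizes discrimination of the integer score
at the 3/6/12-month landmarks. `write_validation_report(report, dir)` emits
the same content as CSV tables (including full CIF step curves) plus a
`summary.json` with every setting echoed for provenance.

Real cohorts enter through `read_cohort("cohort.csv")` (fixed schema,
documented in `?read_cohort`), followed by `eligibility_filter()` (removes
anticoagulated and under-18 records) and `complete_case_filter()` (removes
records where a score component or the outcome is missing); every filter
logs its removal count. A thin command line lives at
`inst/cli/catrisk.R` (`summarize`, `score`, `simulate`, `validate`).

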