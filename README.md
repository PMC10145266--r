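# tacropk

Analysis toolkit for intensively sampled tacrolimus dosing-interval
pharmacokinetics in transplant cohorts, with CYP3A pharmacogenetics and
limited-sampling-strategy development.

Tacrolimus exposure varies more than ten-fold between patients in the first
days after lung transplantation, and trough-based monitoring tracks the
true exposure (AUC over the 12-h dosing interval) poorly. The workflow this
package implements is the standard one for a cohort with full 9-point
profiles (0, 0.5, 1, 2, 4, 6, 8, 10, 12 h post-dose), twice-daily dosing
and CYP3A5\*3 / CYP3A4\*1G genotypes:

* **Non-compartmental analysis** — dosing-interval AUC by the linear-up
  log-down trapezoidal rule; CL/F = 1000·dose/AUC (L/h); observed
  C<sub>max</sub>, C<sub>min</sub>, T<sub>max</sub>; dose-normalised
  variants; geometric mean ± geometric SD (CV%) summaries.
* **Limited sampling** — per-timepoint OLS of AUC on a single
  concentration, judged by the Sheiner–Beal metrics (MPE, MAE, per-subject
  percent errors, F<sub>15</sub>/F<sub>20</sub>/F<sub>25</sub>) and a
  clinical acceptability rule (|MPE| ≤ 15, MAE ≤ 30, F15 > 40, F20 > 45,
  F25 > 50).
* **Pharmacogenetics** — carrier classification (CYP3A5 \*3/\*3 vs the
  rest; CYP3A4 \*1/\*1 vs \*1G carriers), Hardy–Weinberg testing
  (chi-squared plus the exact Levene–Haldane enumeration, chosen
  automatically when expected counts fall below 5), EM haplotype
  frequencies with D′ and r² for the two-locus system, one-way ANOVA on
  log-scale parameters and Spearman covariate scans.
* **Published covariate models** — three literature formulas for tacrolimus
  CL/F (haematocrit-only; weight/voriconazole/dose/haematocrit;
  weight/haematocrit/dose/postoperative-time with genotype and
  voriconazole factors), evaluated as printed for cross-study comparison.
* **Cohort simulator** — steady-state one-compartment profiles with
  genotype-dependent log-normal clearance and controllable two-locus LD,
  so the entire pipeline is testable without patient data.

## Worked example

```r
library(tacropk)
report <- run_pipeline(list(sim = sim_config(seed = 14)))
print(report)
```

```
Tacrolimus PK analysis report: 14 subjects

Genotype-stratified summary (CYP3A5):
            parameter                   all           CYP3A5*3/*3          non-CYP3A5*3/*3
           CL/F (L/h) 12.94 ± 2.63 (124.28)   3.26 ± 1.37 (31.89)  22.45 ± 1.45 (38.15) ***
 AUC0-12h/D (ng.h/mL) 77.28 ± 2.63 (124.28) 306.43 ± 1.37 (31.89)  44.54 ± 1.45 (38.15) ***
             Tmax (h)      2.00 (1.00–4.00)      2.00 (1.00–2.00)         1.50 (1.00–4.00)
 ...

Limited-sampling scan:
 time_h  n    r2  MPE  MAE F15 F20 F25 acceptable
    0.0 13 0.973  8.4 20.6  46  54  77       TRUE
    4.0 14 0.996  5.5  9.7  79  93  93       TRUE
 ...

Published-model comparison (adjusted CL/F, L/h):
  model adjusted_clf ratio_to_cohort
 darley        21.60            1.67
   chen         6.54            0.51
    cai         5.15            0.40
 cohort        12.94            1.00
```

Reading this: each summary cell is the geometric mean ± geometric SD with
the geometric CV% in parentheses; stars mark the ANOVA comparison of the
log-transformed parameter between CYP3A5 classes (\*\*\* is p ≤ 0.001 — in
this simulated cohort the non-expressers clear the drug about 7 times
faster, so their dose-normalised exposure is correspondingly lower). The
scan table shows, per sampling time, the regression R² against observed
AUC, the mean signed and absolute percent prediction errors, the percent of
subjects within ±15/20/25%, and the acceptability verdict; mid-interval
concentrations (around 4 h) predict AUC best. The last table evaluates the
published covariate models at a typical patient (64.5 kg, haematocrit 30%,
2 mg/day, postoperative day 3.5, on voriconazole) next to the cohort's own
geometric-mean CL/F.

The same pipeline runs from files
(`run_pipeline(list(conc_file = ..., dose_file = ..., genotype_file = ...))`)
with CSV schemas `subject_id,time_h,conc_ng_ml[,blq]`,
`subject_id,dose_mg` and `subject_id,cyp3a5,cyp3a4`. See the methods
vignette (`vignettes/tacrolimus-pk-methods.Rmd`) for the model, the
estimators, the simulator's assumptions and the design choices.

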