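# cmgap

Claims-based measurement of medication adherence with the **continuous
medication gap (CMG)**, and evaluation of the convergent validity of
7-day-recall self-reports (automated telephone queries and structured
interviews) against it.

## The problem

Clinicians and health plans need to know whether patients with chronic
cardiometabolic conditions actually take their oral diabetes, blood
pressure, and cholesterol medications. Self-report is cheap but subject
to under-disclosure; pharmacy dispensing claims offer an objective
criterion. `cmgap` implements the claims side, the self-report side, and
the statistics that connect them, for epidemiologists and health-services
researchers working with dispensing extracts.

## The measure

For one patient and one therapeutic indication, order the fills within a
12-month lookback anchored at the adherence-assessment date. Each pair of
consecutive fills of a drug defines a *refill interval*. With interval
length `L_k` days and usable supply `S_k` (the supply dispensed at the
opening fill plus surplus carried over from earlier intervals),

```
gap_k       = max(0, L_k - S_k)
carryover_k = max(0, S_k - L_k)          # flows into interval k+1
CMG         = sum(gap_k) / sum(L_k)      # over first fill .. last fill
```

The supply accounting is **time-forward**: surplus carries only into the
future, so a later stockpile never erases a gap already incurred. CMG
requires at least two fills (one completed refill interval), continuous
prescription benefits over the lookback, and single-system pharmacy
coverage; insulin is excluded because claims carry no fixed days supply
for it. Adherence is *optimal* when CMG ≤ 20% (medication on hand at
least 80% of observed days), *suboptimal* otherwise.

Self-reported missed-pill days over the last 7 days (integer 0–7, from
automated telephone queries or interviews) are categorized as 0, 1, or
2–7 missed days. Convergent validity is tested per indication and source
with an exact Fisher–Freeman–Halton test on the 3×2 table of category ×
(optimal, suboptimal); respondents without a calculable CMG are reported
alongside, not tested. Cross-mode agreement is summarized over
query/interview response pairs made within 30 days of each other:
concordant, higher disclosure on interview, or higher disclosure on the
automated query.

## Worked example

The package ships a synthetic cohort generator with known ground truth:
each patient–indication has a latent taking propensity `p ~ Beta(8, 2)`,
refills arrive `days_supply + delay` days apart with geometric delays of
mean `days_supply * (1 - p) / p` (so the expected uncovered fraction is
`1 - p`), and 7-day recalls are `Binomial(7, 1 - p)`.

```r
library(cmgap)
params <- cohort_params(n_patients = 120, seed = 42)
report <- run_pipeline(pipeline_config(synthetic = params))
print(report)
```

```
== Mean CMG and optimal adherence by source x indication ==
  atsm      blood_pressure n=108  mean CMG 0.204 (SD 0.138)  optimal 55.6%
  atsm      cholesterol    n=108  mean CMG 0.204 (SD 0.150)  optimal 51.9%
  atsm      diabetes_oral  n=108  mean CMG 0.186 (SD 0.142)  optimal 61.1%
  ...
== Missed-day category vs CMG adherence (exact test) ==
  atsm diabetes_oral  (p = 3.83e-10)
    zero         optimal  34  suboptimal   4  non-calculable   2
    one          optimal  21  suboptimal   5  non-calculable   4
    two_to_seven optimal  11  suboptimal  33  non-calculable   6
  ...
== Cross-mode concordance of missed-day reports ==
  diabetes_oral  n=120  concordant 34.2%  higher interview 37.5%  higher ATSM 28.3%
```

Mean CMG ≈ 0.19–0.20 recovers the generator's mean non-adherence level
`E[1 - p] = 0.2`; the tiny exact-test p-values reflect that in this
honest-reporting cohort, respondents reporting more missed days really do
have more supply gaps (12 of 120 patients are deliberately
non-calculable: single fill or dual coverage). Ground-truth recovery is
exact by construction:

```r
report$recovery
#>   indication      n bias_vs_truth rmse_vs_truth bias_vs_propensity rmse_vs_propensity
#> 1 blood_pressure 108            0             0           -0.00948             0.0629
#> 2 cholesterol    108            0             0           -0.00895             0.0652
#> 3 diabetes_oral  108            0             0           -0.00586             0.0565
```

`rmse_vs_truth = 0` certifies the whole path — generation, CSV
round-trip, cohort filtering, windowing, time-forward gap accounting —
because the pipeline's CMG and the generator's realized uncovered-day
fraction are the same quantity measured two ways.

Real extracts enter through the same door:

```r
report <- run_pipeline(pipeline_config(
  claims = "claims.csv", eligibility = "eligibility.csv",
  selfreports = "selfreports.csv", output_dir = "out"))
```

writing per-stage CSVs, a run manifest with exhaustive patient
accounting, and a plain-text report.

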