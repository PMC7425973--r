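# phasecost

Phase-of-care attribution of disease-associated healthcare expenditures
from monthly claims panels, with two estimation methods that can be run on
the same cases and compared head to head.

## The problem

How much does a disease — here, primary hepatocellular carcinoma (HCC) —
add to a patient's healthcare expenditure per patient per month (PPPM)?
Claims databases record *total* spending, so the disease-associated share
has to be isolated statistically. Two standard designs answer this:

* **Matched comparison.** Each case is matched, exactly and without
  replacement, to one never-HCC control on sex, 5-year age band, 15
  Charlson comorbidity conditions and an anchor month (the index month of
  diagnosis, expanding up to 12 months if needed; the death month, with no
  expansion, for the decedent cohort). The estimate for a phase is the mean
  paired difference

  $$\hat\Delta_{\text{matched}} = \tfrac1n \sum_j \left(\bar y^{\text{case}}_j - \bar y^{\text{control}}_j\right),$$

  with a paired-*t* 95% interval, where the bars are PPPM means over the
  case's phase months (controls aligned by the pair's anchor offset).

* **Within-patient fixed effects.** Each case acts as their own control:
  price-adjusted expenditure on patient-month rows (a pre-disease
  reference window plus the phase months) is regressed on phase
  indicators, time-dependent age and weighted Charlson score, absorbing
  patient fixed effects by within-patient demeaning. The phase
  coefficients are the net estimates.

Months are classified into **phases of care** around the index month:
*initial* (the 3-month window centred on the index month), *terminal* (the
6-month window ending at death) and *continuing* (everything between),
with special rules when death occurs within 7 months of the index month.
Expenditures are deflated to a 2018 price base with biennial fee-schedule
revision rates and converted at the purchasing-power parity of $1.00 =
102.5 yen. The two methods are compared by

* proportional difference: `1 - matched / fixed_effects`, and
* absolute difference: `fixed_effects - matched` (USD PPPM).

Because the national claims source this design was developed for is
access-restricted, the package ships a seeded synthetic claims generator
(`simulation_config()`, `generate_population()`) that emulates its
structure — gamma baseline expenditures scaled by age and comorbidity,
comonotone condition flags, competing mortality, phase-specific injected
increments with a ground-truth table, and an end-of-life expenditure surge
common to all decedents — so every stage is verifiable at desk scale.

## Worked example

```r
library(phasecost)
cfg <- simulation_config(n_patients = 5000, study_start = "2011-04",
                         study_end = "2015-03", seed = 1,
                         hcc_monthly_hazard = 1.2e-3,
                         post_hcc_death_hazard = 0.04,
                         background_death_hazard = 0.004)
run <- run_pipeline(run_config(simulation = cfg, out_dir = "example_run",
                               match_seed = 2), quiet = TRUE)
run$manifest$counts[c("eligible_cases", "incident_matched", "death_matched")]
#> $eligible_cases   [1] 187
#> $incident_matched [1] 187
#> $death_matched    [1] 58
run$comparison[treatment_type == "Total"]
#>    treatment_type      phase matched_usd_pppm fe_usd_pppm
#> 1:          Total continuing         300.9954    286.7612
#> 2:          Total    initial        4196.4018   4013.1387
#> 3:          Total   terminal         537.3032   1245.6226
#>    proportional_difference_pct absolute_difference_usd
#> 1:                        -5.0                     -14
#> 2:                        -4.6                    -183
#> 3:                        56.9                     708
```

All 187 eligible cases found an exact-stratum control in the index month;
58 decedent cases found a control who died the same calendar month. The
initial- and continuing-phase net estimates agree between methods to
within a few percent, while the terminal-phase fixed-effects estimate
($1,246 PPPM) is far above the matched one ($537): the generator gives
*every* decedent a 3-fold baseline surge in the last 6 months of life,
which the matched comparison nets out (the control dies the same month and
surges too) but the within-patient estimator attributes to the disease —
the mechanism behind the methods' terminal-phase divergence.

The numbered scripts under `analysis/` run the same chain at the full
default conditions (stage by stage, with summary tables under `results/`):
`01_simulate` → `02_cohorts` → `03_match` → `04_estimate` → `05_compare` →
`06_surge_mechanism`.

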