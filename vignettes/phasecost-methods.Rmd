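---
title: "Estimating disease-associated expenditures by phase of care: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating disease-associated expenditures by phase of care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phasecost)
```

This vignette documents the statistical content of `phasecost`: the cohort
and phase conventions, the two estimators and their variance choices, the
price adjustment, the synthetic claims model behind the test suite, and
the design decisions taken where more than one reading was defensible.

## Cohort definition

A patient becomes a **case** at the **index month**: the first month
carrying an HCC diagnosis flag that is preceded by 12 fully observed
months with no cancer diagnosis flag of any kind, for a patient aged at
least 20 years at that month. The 12-month cancer-free lookback screens
out metastatic disease presenting as HCC; requiring the lookback to be
*observed* (patients entering observation later are ineligible) is the
conservative reading — a shorter observed history cannot certify
cancer-free status.

Cases with no anticancer-treatment flag between the month before the index
month and death/censoring are excluded (the design estimates expenditures
of treated disease), as are **recurrence-like trajectories**: a diagnosis
month preceded by at least 7 consecutive treatment-free months after the
initial treatment. Recurrences would otherwise overlay a second "initial
phase" onto the first episode's continuing phase and inflate it.

## Phases of care

With index month $i$ and death month $d$ (when observed):

* standard pattern ($d - i \ge 8$ or no death): initial
  $\{i-1, i, i+1\}$; terminal $\{d-5, \dots, d\}$; continuing the
  contiguous block between; months before $i-1$ are *pre*;
* death during the index month: initial $\{i-1\}$, terminal $\{i\}$;
* death one month after the index month: initial $\{i-1, i\}$, terminal
  $\{i+1\}$;
* death within 7 months of the index month ($2 \le d-i \le 7$): initial
  unchanged, terminal $\{i+2, \dots, d\}$, no continuing phase;
* censored cases: no terminal phase; continuing runs to the last observed
  month.

Three conventions deserve a note, because the verbal definitions ("the 6
months before death", "until 7 months before death", "within 7 months")
admit off-by-one readings:

1. **The death month is always terminal.** The terminal phase is read as
   the 6-month window *ending at* the death month, consistent with the
   fixed-effects description of the terminal phase "ending in the month of
   death". The continuing phase then ends at $d-6$, so the partition has
   no gap.
2. **Death one month after the index month** is not spelled out verbally
   anywhere; labelling the death month terminal and the two preceding
   months initial is the analogy to the death-in-index-month exception.
3. **"Within 7 months" is $d - i \le 7$**: the largest offset at which the
   standard rule would yield an empty continuing phase under convention 1.
   At $d-i = 8$ the standard pattern resumes with a one-month continuing
   phase.

Under these conventions the phase labels partition
$\{i-1, \dots, d\}$ exactly for every death offset; the test suite
verifies this by brute-force enumeration over offsets 0–60, together with
the block-length rule (terminal spans $\min(6, d-i-1)$ months outside the
two early-death exceptions).

## Treatment types

Cases are categorized by the set of treatment modalities flagged between
the month before the index month and death/censoring (the window is a
package decision; the source tables do not state one). The 16 labels are
resolved by precedence: any set containing surgical resection maps to one
of the four resection rows (`only`, `+ LRT`, `+ TACE/TAE`, `+ others`);
otherwise any set containing locoregional therapy maps to one of the four
LRT rows; otherwise the exact single/pair/triple combinations
(TACE/TAE/sorafenib/chemotherapy rows) are matched; everything else —
including radiotherapy alone and the unlisted TACE+TAE pair — falls into
`Others`. The `+ others` rows absorb any additional modality beyond the
named pair. The mapping is total and deterministic over all $2^7$ modality
subsets (tested exhaustively).

## Matching

The exact-match stratum is (sex, 5-year age band at the anchor month, 15
Charlson condition indicators). Malignancy categories are excluded from
the condition list because every case carries them by definition.
Condition indicators are evaluated over the 12-month window ending at the
anchor month — for controls this mirrors the case lookback; the symmetric
treatment is a package decision.

*Incident cohort*: the anchor is the case's index month; candidate
controls have no HCC flag ever, an identical stratum key, and healthcare
utilization (recorded expenditure > 0) in the anchor month. If the stratum
is empty the window expands month by month to the nearest utilization
month within 12 months of the index; equidistant ties resolve to the
*earlier* month (deterministic, and months before the index cannot be
contaminated by later secular trends). *Death cohort*: the anchor is the
death month, candidates must have died in the same calendar month, and no
expansion is allowed — the source describes none, and a month-shifted
death would misalign the end-of-life window that the terminal phase
exists to capture.

One control is drawn uniformly at random (seeded) from the chosen month's
candidates and removed from the pool; cases are processed in ascending
patient-id order, which makes the without-replacement competition
reproducible. Unmatched cases are reported, never silently dropped. By
construction, matched cases and controls are *identical* on every matching
variable — the balance test asserts key equality pair by pair.

## Price adjustment and units

Expenditures are deflated in yen, per service month, by the biennial
fee-schedule revision rates relative to 2018 (fiscal years run
April–March): 1.019 for fiscal 2010–2011, 1.004 for 2012–2013, 1.1001 for
2014–2015, 0.9916 for 2016–2017; months at or after fiscal 2018 are
already on the base. Aggregates are converted to US dollars once, at the
2017 purchasing-power parity of $1.00 = 102.5 yen. Deflate-then-convert
and convert-then-deflate commute (both are scalar multiplications), which
the tests assert. The printed 1.1001 rate for 2014–2015 sits oddly
against its neighbours (1.004, 0.9916) and may be a typographical artifact
of 1.001; the printed value is nevertheless the default, and every rate is
overridable in `price_adjustment()`.

## The estimators

**Matched comparison.** For pair $j$ with anchor offset $o_j$, the case's
phase months $M_j$ are averaged (zero-utilization months count as zero)
and compared with the control's months $M_j + o_j$, truncated to the
control's observation window; $\hat\Delta$ is the mean of the paired
differences with a paired-$t$ 95% interval. Strata with a single pair
report a point estimate and a flagged, undefined interval.

**Fixed effects.** Per cohort (and per treatment type, plus a pooled
Total), the panel stacks a **pre-disease reference window** — the 12
months ending at $i-2$, configurable — with the cohort's phase months
(incident: initial + continuing; death: terminal). Price-adjusted USD
expenditure is regressed on phase indicators, age in completed years and
the weighted Charlson score, both time-dependent, with patient fixed
effects removed by within-patient demeaning. The within estimator is
checked against dummy-variable least squares to $10^{-8}$ relative
tolerance on random panels. Residual degrees of freedom are
$N - G - k$.

Decisions worth recording:

* The reference window ends at $i-2$ because $i-1$ belongs to the initial
  phase. A single pre month (the literal "preceding month") would make the
  within estimator needlessly noisy; 12 months uses the clean lookback.
  The window length is exposed (`pre_window`).
* The Charlson score uses the original weights (1 for most conditions, 2
  for complicated diabetes, hemiplegia and renal disease, 3 for
  moderate/severe liver disease, 6 for AIDS), recomputed monthly from the
  flags; the source reports scores but not weights.
* Standard errors are conventional homoskedastic OLS on the demeaned data
  with the corrected degrees of freedom; cluster-robust (CR1 by patient)
  errors are available via `cluster = TRUE`. The null-calibration test
  shows the conventional intervals cover at 93–95% on the generator's
  panels, inside the binomial band for nominal 95%.
* Covariates with no within-patient variation anywhere in a fit (e.g. the
  comorbidity score when no condition onsets occur in a small stratum) are
  dropped from that fit rather than aborting it; `within_ols()` itself
  refuses singular designs and names the offending columns.

The comparison statistics are `1 - matched/fe` (undefined and flagged
when the fixed-effects estimate is 0, never silently 0) and
`fe - matched`. Report tables round percentages to one decimal and
dollars to whole units; internal computation is unrounded.

## The synthetic claims model

`generate_population()` draws, per patient: sex; age band (default: a
discretized normal, mean 72, SD 11, truncated to 20–99, matching the case
age structure of the emulated cohort); a latent severity uniform that
drives the 15 condition flags; HCC onset (constant monthly hazard);
competing background and post-onset death; and a lognormal frailty.
Monthly expenditure is

```
gamma(shape, mean = baseline * age_factor * cci_factor * frailty, normalized)
  * surge * utilized + increment
```

* **Gamma baseline** (default shape 0.5): right-skewed, non-negative —
  the canonical shape of monthly claims totals. The patient-level mean
  scales multiplicatively with age band (default 1.05 per band) and
  Charlson score (default 1.08 per point), then is normalized by the
  exact expectations of those factors under the configured distributions
  so the population mean equals `baseline_mean_yen` (default 66,000 yen
  ≈ $644 PPPM, the emulated cohort's pre-disease level). The scaling
  makes matching on age and comorbidity *informative*: discarding it
  would make any control as good as a matched one.
* **Comonotone condition flags**: one latent uniform per patient with
  per-condition thresholds equal to the target prevalences (defaults: the
  emulated cohort's matched-case prevalences). Marginal prevalences are
  preserved exactly, while profiles collapse onto nested severity
  patterns — a stylized but directionally realistic model of
  multimorbidity clustering, and the reason exact matching on 15
  conditions stays feasible at desk scale (independent flags would
  require a population-registry-sized pool for same-death-month exact
  matches). A small monthly onset hazard (default 2e-4 per condition)
  makes the score time-dependent, as the fixed-effects model assumes.
* **Injected increments**: each case's treatment type (drawn from the
  emulated cohort's published initial-phase mix) maps to yen/month
  increments added in every true initial/continuing/terminal month.
  Defaults take the published fixed-effects net estimates for the initial
  and continuing phases and the published matched net estimates for the
  terminal phase (negative printed values floored at 0) — the cleanest
  published estimate of each phase's disease-specific component.
* **End-of-life surge**: the baseline of *every* decedent — HCC or not —
  is multiplied by `eol_surge_multiplier` (default 3) in the last
  `eol_surge_months` (default 6) months of life. This is the mechanism
  that makes the two estimators diverge in the terminal phase: the
  matched decedent control surges identically (differencing it away),
  while the within-patient contrast against surge-free pre months
  attributes the entire surge to the disease.
* **Zero-utilization months** (default probability 0.05) zero out the
  baseline draw; injected treatment-phase increments still incur claims,
  so the injected truth passes through both estimators exactly.
* Maintenance treatment flags recur every third month, so non-recurrent
  cases never trip the 7-month recurrence rule; an optional
  `recurrence_prob` injects trajectories that do.

Identical configurations and seeds give bit-identical output.

**What passing tests show — and don't.** Parameter recovery, null
calibration and the surge-mechanism tests validate the *estimators and
pipeline logic* under a data-generating process whose assumptions they
share (month-level independence given patient mean, phase-constant
increments, exactly shared surge). Real claims have serial correlation,
provider-level batching, secular trends, treatment switching and
informative censoring, none of which the generator emulates; the absolute
dollar results of the emulated national study additionally depend on its
access-restricted data and cannot be reproduced here. What carries over
is arithmetic correctness, the matching algorithm's contracts, estimator
unbiasedness under the stated model, and the directional terminal-phase
divergence mechanism.

## Problem sizes in the test suite

Simulation tests are sized to keep the full suite within a normal
check run: parameter recovery uses 50 replicates of ~9,000 patients over
a 60-month window (≈500 eligible cases per replicate, matching the scale
at which the estimators are exercised together); the surge-mechanism grid
uses 50 + 15 + 15 replicates of 4,000 patients; null calibration uses 200
replicates of 1,200 patients. Recovery and calibration runs use
unit revision rates so the injected yen truths map to fixed USD targets;
the price adjustment itself is unit-tested separately. The analysis
scripts under `analysis/` run one full default-condition population
(20,000 patients, April 2010–March 2018).

## Known limitations

* Exact matching without calipers or propensity fallback: a case in an
  empty stratum is simply unmatched (reported); the death cohort's match
  rate is the binding constraint at small pool sizes.
* The matched estimator truncates a control's aligned months at the
  control's death/censoring rather than imputing; pairs whose control has
  no observed aligned month for a phase drop out of that phase's mean.
* Incident-cohort controls are screened for utilization in the anchor
  month, which conditions one in-phase month on being nonzero; on the
  generator this biases the matched initial estimate by under 2% of its
  value (visible in the recovery test's bias margins).
* Homoskedastic fixed-effects intervals are the default; with strongly
  patient-heteroskedastic costs the cluster-robust option is the safer
  choice.
* The generator's condition flags are comonotone at baseline; it cannot
  emulate populations where comorbidity profiles are close to
  independent, and match rates there would be far lower.
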