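---
title: "Model structure, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcea)
```

This vignette is the package's own account of the science: the state-transition
model and its assumptions, the parameters that matter and their defaults, the
conventions we had to choose where the published inputs are silent, and what
the validation machinery does and does not establish.

## The decision problem

Sacubitril-valsartan reduces cardiovascular (CV) death and heart-failure
hospitalization relative to enalapril in HFrEF, but costs more, even after
China's national price negotiation (patient-borne cost $17.12/month versus
$10.65/month for enalapril). Whether the clinical benefit is worth the extra
cost from the patient's perspective is a cost-effectiveness question: we
project lifetime-scale costs and quality-adjusted survival under each
treatment and compare the increments against willingness-to-pay (WTP)
thresholds of $10,276 (GDP per capita) and $30,828 (3× GDP) per QALY.

## Markov cohort model

Six health states: NYHA functional classes I–IV and two absorbing death
states (CV and non-CV). Keeping the two causes of death separate makes event
accounting and the microsimulation cross-check cleaner; any figure the model
reports as "death" is their sum. The cohort starts at age 64 distributed
4.5 / 71.6 / 23.1 / 0.8% over classes I–IV, and evolves in monthly cycles for
120 cycles (10 years) in the base case. Age advances deterministically,
`age(t) = 64 + (t − 1)/12`.

Per cycle, from each living class:

1. **CV death** with probability `p_cv`: exponential baseline
   `1 − exp(−0.00577)` per month, scaled by the arm hazard ratio 0.80
   (sacubitril-valsartan only) on the rate scale, then multiplied by the
   class relative risk (1.372 / 1.640 for III / IV).
2. **Non-CV death** among CV survivors: the age-specific annual probability
   from the life table, read as a left step function (greatest tabulated age
   ≤ attained age) and converted monthly, `1 − (1 − p)^(1/12)`. At age 100
   the table closes with probability 1.
3. **NYHA class change** among survivors of both death draws: probability
   0.0088 (enalapril) or 0.0068 (sacubitril-valsartan), destination split per
   the class-change matrix (e.g. a class-IV change can only land in III).
4. **Hospitalization**, evaluated independently among cycle survivors:
   Weibull baseline `1 − exp(λ(t^γ − (t−1)^γ))`, arm hazard ratio 0.79,
   class hazard ratio 1.71 / 3.4 for III / IV, all chained on the rate
   scale. Hospitalization does not move the patient between states; it
   generates a cost and a disutility.
5. **Readmission** (see conventions below).

This death-first sequencing, with probabilities combined conditionally
(multiplicatively), guarantees each transition-matrix row sums to one without
any renormalisation, which the matrix builder asserts to `1e-9` on every call.

### Treatment-effect scales

Rows labelled hazard ratios are applied as `p' = 1 − (1 − p)^HR` — the HR
multiplies the per-cycle log-survival, matching its epidemiological meaning —
while rows labelled relative risks multiply the probability directly. Both
the arm effect and the class effect are applied (multiplicative stacking);
`options$hr_scale = "probability"` switches HRs to probability-scale
multiplication for sensitivity of conclusions to this choice (at these event
rates the difference is below 0.1%).

## Economics

* **Utilities** 0.780 (I and II, which share inputs but remain distinct
  states because their class-change rows differ), 0.715 (III), 0.660 (IV),
  accrued as utility/12 per occupied month. Death accrues nothing.
* **One-time disutility** 0.1 per hospitalization and per readmission.
* **Costs** (2019 USD, patient perspective): monthly drug cost + $41.56
  outpatient cost per living patient-month; hospitalization $1,920.49 and
  readmission $1,340.05 per event, of which the patient bears the 0.3
  inpatient copay share. The drug copay works the other way: the Medicare
  ratio is the *reimbursed* share, so patients pay
  `monthly price × (1 − ratio)` — this reading is forced by the printed
  arithmetic ($85.61 × 0.2 = $17.12). Both interpretations sit behind
  config switches (`drug_copay_is_reimbursed`,
  `inpatient_copay_is_patient_share`).
* **Discounting** at 3.5% per year, applied at the cycle midpoint:
  `(1.035)^(−(t − 0.5)/12)`.
* **Half-cycle correction**: state-occupancy accruals use the trapezoid —
  the average of start- and end-of-cycle occupancy — so a patient dying
  within a cycle contributes half a month of utility and fixed cost.
  One-time event accruals are not half-cycle corrected (they already occur
  once, mid-cycle, at the midpoint discount factor).

## Conventions the published inputs leave open

Three conventions cannot be read off the input tables. Each is implemented
as a switch; the defaults were fixed once, during a calibration pass against
the published base-case outputs (`analysis/01_calibration.R` reruns the
comparison), and not revisited.

**Hospitalization baseline (`weibull_mode`).** The printed Weibull
coefficients imply a monthly hospitalization probability near 0.001, yet the
plausible range printed beside them is 0.00868–0.0145 — an order of
magnitude higher (its scale is consistent with an annualised rate). We
implement both readings: `"raw"` uses the printed coefficients directly;
`"calibrated"` rescales λ so the horizon-mean monthly probability equals an
anchor constrained to the printed band (root-finding on the scale factor,
shape and hence time-trend preserved). The calibration pass showed the raw
coefficients reproduce the published base case within ~5% on every
headline quantity, whereas *every* in-band anchor leaves errors of 13–20%,
so `"raw"` is the default. The printed band is still honoured where it is
unambiguous: as the one-way sensitivity range for the baseline
hospitalization probability, driven through the calibrated mode.

**Readmission (`readmission_mode`).** The monthly readmission probability
0.0147 annualises to 16.2%, the 30-day readmission rate reported for the
Chinese insurance population, and no conditioning rule is stated. Default
`"unconditional"`: every cycle survivor faces 0.0147/month, identical in
both arms (the source reports no arm difference). The `"conditional"`
alternative applies the annualised value as a per-hospitalization
conditional probability to the previous cycle's hospitalized fraction. The
unconditional reading fit the published cost totals decisively better
(conditional leaves both arms' costs 5–9% low) and was frozen as default.

**Disutility duration (`disutility_mode`).** A "one-time disutility of
−0.1" can mean 0.1 QALYs per event (default, `"per_event"`, the literal
reading) or a one-month decrement of 0.1/12 (`"per_month"`). The two differ
by under 2% on total QALYs; the literal reading also fit best.

## Sensitivity analyses

**One-way (tornado).** Every manifest parameter is pushed to its printed
low and high bound (95% CI where given, otherwise ±5/10/20% of the mean as
stated for utilities/probabilities/costs), both arms rerun, and entries
sorted by ICER span. Bounds that would produce an invalid model are recorded
as skipped rather than aborting. Drug prices dominate; no single excursion
pushes the ICER over the GDP-per-capita threshold (asserted as a regression
test).

**Two-way / threshold.** Net monetary benefit `NMB = WTP·ΔQALY − Δcost` is
affine and strictly decreasing in the intervention's patient-borne monthly
price (prices do not affect QALYs), so the break-even price is a bracketed
root on $0–$150 — $150 being roughly five times the top of the printed price
range, covering post-negotiation pricing. Tolerance $0.01; a bracket without
sign change returns the nearer boundary flagged `converged = FALSE`. The
search operates on the patient-borne cost, the quantity the price table
derives.

**Probabilistic.** 10,000 second-order Monte Carlo draws. Distribution
families follow the input table: beta for probabilities and utilities
(moment-matched, treating `(up − low)/3.92` as the standard deviation),
log-normal for HRs and RRs (median at the point estimate, `σ` from the CI on
the log scale), gamma for costs (moment-matched). Event disutilities are
beta on their printed magnitude range rescaled to [0.08, 0.13], since beta
needs bounded support. Parameters are sampled independently (no correlation
structure is published); the two arm-specific progression probabilities and
the two drug prices are sampled independently; arm HRs are sampled once and
applied to the intervention arm only. Inputs whose distribution column is
blank — the two survival baselines and the inpatient copay — stay fixed in
the PSA and move only in the one-way analysis. Draw `i` seeds its own
substream (`seed + i`), so any draw is reproducible in isolation and results
do not depend on execution order. A sampled value violating its kind's
bounds is redrawn (capped rejection); with these inputs rejection
essentially never triggers. The CEAC is per-draw NMB counting at each WTP.

One published PSA figure is internally inconsistent: the reported mean QALYs
per arm are transposed relative to every other result (the comparator cannot
gain more QALYs than the intervention while the CEAC sits above 99.9%). We
therefore treat only the PSA cost means and the acceptability probability as
reproducible quantities.

## Validation design

**Cohort vs microsimulation.** The microsimulation realises the identical
pathway patient by patient — same per-cycle probabilities, same death-first
sequencing, same trapezoid and midpoint-discount accrual (a class change
accrues the average of origin and destination utilities; a death cycle
accrues half a month) — so its population means estimate exactly the cohort
engine's quantities, not an approximation of them. The validation run
(200,000 patients per arm; `analysis/07_microsim_validation.R` and the
acceptance suite) requires agreement within 3 Monte Carlo standard errors
for total cost, total QALYs and the 10-year death fraction. The one
deliberate approximation runs the other way: in conditional readmission
mode the cohort engine applies the conditional probability to the full
previous-cycle hospitalized fraction, while simulated patients must survive
the current cycle to be readmitted — a discrepancy of order
`p_death × p_readmit` (< $1 and < 1e-4 QALYs), far inside the 3-SE band.

**Parameter recovery.** The microsimulation also emits per-patient first
hospitalization and CV-death times, censored at the horizon or at the last
fully observed cycle when death intervenes. Discrete-time maximum likelihood
(`P(event at t) = S(t−1) − S(t)` under `S(t) = exp(λ t^γ)`) recovers the
generating coefficients: closed form for the exponential rate, BFGS on
`(log(−λ), log γ)` for the Weibull. Recovery runs use a single-class cohort
(all NYHA II, no class changes) so the baseline hazards apply without class
multipliers; at 50,000 patients both the exponential rate and the Weibull
shape come back within a few percent (asserted at 10%). A likelihood-ratio
check confirms the exponential is not spuriously rejected when it is the
truth.

## Numerical choices and degenerate inputs

* Row sums and occupancy mass are asserted to `1e-9`; violations are
  internal errors, never silently renormalised.
* `apply_hazard_ratio` short-circuits HR = 1 exactly; `p = 1` with HR ≠ 1 is
  a domain error (a certain event cannot be rescaled on the rate scale).
* Calibration root-finding brackets the scale factor adaptively (doubling
  until the mean probability crosses the anchor) and solves to `1e-12`.
* A zero-cycle horizon returns zero totals and an empty trace; validation
  otherwise requires at least one cycle.
* Degenerate distribution ranges (low = up) collapse to point masses with a
  warning rather than an error, so frozen parameters can ride through the
  PSA machinery.
* Ties in the tornado ordering break alphabetically by parameter name.
* The ICER is flagged `undefined` when ΔQALY is exactly zero and a
  dominance label is reported when the increments' signs disagree; the
  base case never triggers either, so this is defensive completeness.

## Problem sizes

Default analysis sizes, chosen to put Monte Carlo error well below the
decision margins: 10,000 PSA draws (the published design), 200,000
microsimulated patients per arm for engine validation (cost SE ≈ $4.7, QALY
SE ≈ 0.005), 50,000 patients for hazard recovery. The deterministic engine
itself is exact up to floating point; a 120-cycle run takes ~2 ms.

## What passing tests do and do not show

The synthetic histories emulate the *modelled* world: constant treatment
effects, NYHA-independent readmission, no adverse events or treatment
discontinuation (excluded from scope), no correlation between inputs, and
trial-derived effects extrapolated to ten years. Agreement between the
cohort engine, the microsimulation and the published figures therefore
establishes internal consistency and faithful implementation — not that the
model predicts real-world Chinese HFrEF outcomes. Known limitations shared
with the source analysis: benefits taken from a single trial's
Asia-Pacific-consistent estimates, higher real-world severity mix than the
trial's, and price-period assumptions for the negotiated drug cost.
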