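---
title: "Methods: a patient-level cost-effectiveness model of insulin pump therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a patient-level cost-effectiveness model of insulin pump therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpcea)
```

## What the model is

`pumpcea` evaluates continuous subcutaneous insulin infusion (CSII, insulin
pump therapy) against multiple daily injections (MDI) for adult type 1
diabetes patients of the Mexican Institute of Social Security (IMSS), from
the payer perspective, in 2016 Mexican pesos. It is a patient-level
("first-order Monte Carlo") annual-cycle microsimulation: each synthetic
patient is stepped year by year through complication onset, acute events
and death; per-cycle costs and utilities are accumulated with discounting;
the two arms are compared as an incremental cost-effectiveness ratio
(ICER = ΔC/ΔE), and decision uncertainty is summarized as a
cost-effectiveness acceptability curve (CEAC) from second-order parameter
sampling.

The pipeline has five stages, each an exported function family:

1. **Cohort synthesis** (`default_imss_spec()`, `generate_cohort()`) —
   draws patients whose marginal statistics match the published IMSS
   baseline table (n = 192: 29.2% male, age 32.3 ± 10.8, diabetes duration
   18.5 ± 10.8, HbA1c 9.2 ± 2.2%, severe hypoglycemia 22.4 events/100
   patient-years, nineteen pre-existing-complication prevalences, three
   medication prevalences).
2. **Treatment effects** (`treatment_effects()`) — the two published
   meta-regression formulas: HbA1c change
   −(−3.60 + 0.52 × baseline HbA1c), giving −1.2 points at baseline 9.2%,
   and the severe-hypoglycemia rate ratio
   0.5 × rate + 0.016 × age − 1.18 = 10.5 at the cohort inputs, hence a
   CSII rate of 22.4/10.5 ≈ 2.1 events/100 patient-years.
3. **Disease simulation** (`simulate_arm()`) — the annual-cycle engine
   described below.
4. **Costing and utilities** (`cost_cycles()`, `utility_cycles()`) — the
   published unit costs and utility weights applied per patient-cycle.
5. **Economics and scenarios** (`aggregate_arm()`, `cea_compare()`,
   `ceac()`, `run_scenario()`, `run_suite()`, `run_pipeline()`).

## What is faithful and what is synthetic

Every number printed in the source tables is reproduced bit-for-bit in the
packaged defaults: the baseline cohort table, both regression formulas and
their worked arithmetic, every unit cost (including the derivation rules —
subsequent-year cost = event-year cost / 9, DRG inflation 0.0865, exchange
rate 18.390 MXN/USD, insulin 65.45 kg × 0.1 IU/kg × 365 = 2,388.925
IU/year), the salary inputs of the human-capital model, and the utility
table with its combination rules.

The disease-progression engine is a **structural stand-in** for the
proprietary CORE Diabetes Model: that model's transition probabilities,
risk equations and mortality tables are unpublished. The shapes are
re-implemented (sub-model-per-complication annual Markov processes with
HbA1c-dependent risk adjustment and first/second-order Monte Carlo); the
numbers are this package's own synthetic defaults of plausible magnitude
(`default_complications()`, `default_mortality()`), clearly labelled as
such and fully replaceable through a YAML config
(`read_disease_params()`; a template ships in
`inst/extdata/disease_params_synthetic.yaml`). Consequently the package
does not reproduce — and its tests do not claim — the published absolute
lifetime totals, complication-free times or the 43.9% CEAC probability;
what it reproduces exactly is the published arithmetic, and what it
verifies about the simulation are structural properties (closed-form
oracles, coupling monotonicity, discounting identities).

## The simulation engine

**States and cycles.** Cycles are one year with no half-cycle correction;
events occurring mid-cycle accrue that cycle's one-off costs and
disutilities. Eighteen complications are simulated, with predecessor
prerequisites (proliferative retinopathy requires background retinopathy;
gross proteinuria requires microalbuminuria; end-stage renal disease
requires gross proteinuria; foot ulcers require neuropathy; gangrene and
amputation require an ulcer). Foot ulcers and gangrene are transient —
active in their onset year, healed thereafter. Incident end-stage renal
disease is assigned a dialysis/transplant modality by configurable shares.
Depression, atrial fibrillation and left-ventricular hypertrophy are
carried as static baseline flags (costed/weighted but not simulated as
incident events).

**Hazard adjustment.** Each complication has an annual baseline hazard at
the reference HbA1c (9.2%, the cohort mean, so the MDI arm runs at
baseline risk) scaled log-linearly: h = h_ref · rr^(HbA1c − ref),
converted to a cycle probability as 1 − exp(−h). The treatment effect
enters as a single sustained HbA1c shift from cycle 1, and as the divisor
of the severe-hypoglycemia Poisson rate.

**Death.** Background mortality comes from a tabulated life table (ages
18–110, q forced to 1 at 110 so the lifetime horizon of 70 years always
suffices for 100% mortality). Some macrovascular events carry an in-cycle
fatality probability; onsets are evaluated before the death draw so a
fatal-event year still accrues its event cost (a fatal stroke is costed
with the stroke-death tariff).

**Common random numbers.** All stochastic inputs are pre-drawn with fixed
dimensions: one uniform per patient × cycle × complication, one fatality
uniform per patient × complication, one exponential threshold per patient
for background mortality, and one uniform per patient × cycle per acute
event type (inverted through the Poisson quantile function). Two arms run
with the same seed therefore share every draw. This makes the null-effect
comparison cancel *exactly* per patient, and makes hazard reductions
monotone: a lower onset probability with the same uniforms can only delay
onsets, and since the fatality uniform is attached to the complication
rather than the cycle, fatal deaths can only be delayed too — so
per-patient life-years never decrease when hazards decrease. Per-patient
complication *counts* are guaranteed monotone only when fatality
probabilities are zero: with differential survival, a longer-lived patient
can unmask late-life onsets. The tests assert each property under exactly
the conditions that guarantee it.

**Censoring convention.** `time_free_of()` averages years from baseline to
first onset; patients who die or reach the horizon without the
complication contribute their observed lifetime (the alternative —
restricting to patients with onsets — is biased toward early onsets).

## Costing

Costs are recorded in MXN (2016) as the canonical currency; USD is derived
only at reporting time at 18.390. Per cycle and patient: therapy
(CSII 53,568.00/year — pump amortized over its four-year warranty plus
consumables and insulin — or MDI 22,884.97/year), management (monthly
medications × 12 for the patient's baseline medication flags, plus annual
screening for retinopathy, microalbuminuria, proteinuria and depression —
the screening schedule is unstated in the source and applied annually to
all alive patients by default), event-year costs for incident
complications, subsequent-year costs for prevalent states, and acute-event
costs (severe hypoglycemia 37,000.53 each; minor 990.00). The
subsequent-year derivation is fixed to event-cost/9 because that, and not
the literal "10% of 90%" footnote wording, reproduces all five printed
subsequent-year rows to the centavo. Categories mirror the published
breakdown (treatment, management, cardiovascular, renal,
ulcer/amputation/neuropathy, eye, hypoglycemia) plus an `other_acute`
category for ketoacidosis, lactic acidosis and insulin edema, which the
published table prices but does not report as a separate category.
Macular edema is costed with the laser-treatment tariff (its treatment);
the amputation prosthesis is "not covered" and costed at zero.

Indirect costs use the human-capital approach: disability days per
incident event (capped at the 255-day working year) valued at the
sex-specific daily salary between ages 18 and 60. The source model's
disability durations are unpublished, so the default durations are zero —
indirect costs are opt-in via `disability_durations()`.

## Utilities

Baseline 0.785 with no complications. When several chronic conditions are
active the lowest per-condition utility applies (a literal reading of the
lowest-utility rule, not additive decrements); one-off event disutilities
(incident MI −0.055, stroke −0.164, amputation −0.28, cataract −0.016,
severe hypo −0.047 and minor hypo −0.014 per event) are subtracted on top
in the event cycle; the result is clamped at 0. Events with lasting impact
switch to post-event state values (post-MI 0.73, post-stroke 0.621,
kidney transplant 0.762, post-amputation 0.505). Chronic states whose
published entry is a decrement (angina, heart failure, dialysis, …) carry
it every active cycle through the min rule — applying it once would make a
lifetime on hemodialysis almost costless in utility terms. Gangrene,
ketoacidosis and lactic acidosis have no published utility entry and carry
none. The "background retinopathy wrongly treated" row has an undefined
trigger and is never auto-applied (it can be set via table overrides).

## Discounting and decision measures

5% per year for both costs and effects in the base case, cycle-start
convention: the first simulated year is undiscounted and cycle t carries
(1 + r)^(−t). `icer()` returns ΔC/ΔE with dominance flags instead of
numbers when ΔE ≤ 0. The CEAC samples, per outer draw, the HbA1c
regression coefficients from normal distributions with their published
standard errors (the rate-ratio coefficients have no published SEs and are
held fixed) and, optionally, a single moment-matched gamma multiplier on
all unit costs (CV 0.2 by default — the source states that "costs were
sampled" without giving distributions, so this is a conventional,
configurable choice); each draw simulates a fresh cohort with both arms
paired by common random numbers, and the curve is the fraction of draws
with positive net monetary benefit across the WTP grid (default 0–600,000
MXN in 10,000 steps, spanning the 1- and 3-GDP-per-capita thresholds of
153,000 and 459,000 MXN).

## The synthetic cohort: what it emulates and what it does not

Only univariate summaries are published, so marginals are sampled
independently: truncated normals for continuous traits (age ≥ 18 for an
adult cohort, HbA1c within 4–20%), with the location parameter solved so
the *truncated* mean matches the published mean (naive truncation would
inflate the age marginal by about two years); the scale parameter is kept,
so SDs match only approximately. Triglycerides (145.7 ± 185.2) would go
negative under a normal and are drawn from a moment-matched log-normal.
eGFR is printed without an SD; the default of 20 ml/min/1.73 m² is this
package's own choice. Diabetes duration is resampled until it does not
exceed age — this logical-consistency constraint pulls its realized mean
below the published 18.5 years, the one marginal deliberately allowed to
deviate. Binary traits are independent Bernoulli draws, which means the
cohort does not reproduce any real correlation structure (e.g. between
duration, retinopathy and nephropathy); passing tests therefore
demonstrate correctness of the machinery on marginally-matched cohorts,
not calibration to the joint distribution of real IMSS patients.

## Problem sizes and numerical choices

The test suite verifies Monte Carlo oracles at the sizes where their
closed-form bounds are sharp: 10^5 patients for the two-state occupancy
annuity (3 MC standard errors), 2 × 10^4 for marginal-mean checks
(4 standard errors), 10^5 patient-cycles for the Poisson event-rate check,
and 100 × 100 outer/inner samples for the full-model acceptability curve,
which preserves curve monotonicity while keeping a laptop-scale runtime;
the full published design (1000 × 1000) is a `ceac()` argument away.
Reported one-decimal figures use round-half-away-from-zero
(`report_rounded()`), which reproduces the published 10.5 from 10.5368 and
−1.2 from −1.184; all internal arithmetic keeps full precision (the
source computes 22.4/10.5 on the rounded ratio; the package divides at
full precision — both report 2.1).

## Known limitations

* Absolute lifetime outputs depend on the synthetic disease parameters and
  must not be read as reproductions of the published totals.
* No within-patient HbA1c drift, no intra-year event timing, no
  correlation between baseline marginals, exactly two comparators.
* The subsequent-year /9 rule is an interpretation fixed by the printed
  table against the footnote's ambiguous wording.
* Subgroup scenarios re-derive the treatment effect from the subgroup's
  own mean baseline HbA1c through the regression — this is the mechanism
  that makes the poorly-controlled subgroup more favourable, and it is an
  interpretation of how the published subgroup analyses were constructed.
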