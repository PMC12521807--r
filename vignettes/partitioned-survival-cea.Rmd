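---
title: "Methods: a partitioned survival cost-effectiveness model for first-line DLBCL therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned survival cost-effectiveness model for first-line DLBCL therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

This vignette is the package's own account of its model: what is being
computed, under which assumptions, which conventions were chosen where
several were defensible, and what the synthetic-data tests do and do not
demonstrate about real data.

## The decision problem

Two first-line regimens for treatment-naive diffuse large B-cell
lymphoma (DLBCL) are compared: the rituximab biosimilar Hanlikang plus
CHOP (H-CHOP) versus originator rituximab plus CHOP (R-CHOP), six 21-day
cycles each. The biosimilar's acquisition price is about 24% lower per
100 mg; the clinical question is whether the price difference, combined
with the arms' fitted survival differences and downstream
(post-progression, adverse-event, end-of-life) costs, makes H-CHOP
cost-effective at Chinese willingness-to-pay thresholds of one to three
times GDP per capita.

## Partitioned survival structure

The cohort model has three states. Occupancy is read directly off the
two survival curves at every cycle boundary rather than through
transition probabilities:

* progression-free: `min(S_PFS(t), S_OS(t))`
* dead: `1 − S_OS(t)`
* progressed: the remainder.

The min-clipping matters: OS and PFS are fitted independently, and the
R-CHOP log-normal parameters make the fitted PFS curve cross above the
OS curve at about year 12. A partitioned survival model cannot let
progressed occupancy go negative, so PFS is capped at OS wherever the
curves cross; within the default 10-year horizon the crossing is not
reached, but the engine is exercised against it in tests with an
extended horizon.

Because the model is partitioned rather than transition-based, the path
by which patients die (from PFS or from PD) is not identified. The only
place it matters is the count of incident progressions, which prices
entry into post-progression treatment: deaths in a cycle are attributed
to the two living states proportionally to their start-of-cycle
occupancy, the least-informative choice consistent with the curves.

## Survival inputs

Both endpoints in both arms are log-normal,
`S(t) = 1 − Φ((ln t − λ)/γ)`, with the trial-derived parameters carried
in the bundled configuration (H-CHOP OS λ = 3.284, γ = 1.938; R-CHOP OS
λ = 2.925, γ = 1.843; H-CHOP PFS λ = 2.998, γ = 1.884; R-CHOP PFS
λ = 3.007, γ = 2.195). **Time is in years.** The parameter source does
not state the unit; in years these parameters put 1-year OS near 0.955
and 10-year OS near 0.69 for H-CHOP, consistent with a low-to-
intermediate-risk DLBCL population, whereas a month scale would imply a
median OS around two years, contradicting the trial population. The unit
is a configuration field (`survival.time_unit`) so the choice stays
auditable.

### Curve reconstruction

When survival inputs arrive as digitised Kaplan-Meier coordinates
rather than parameters, `reconstruct_ipd()` inverts them into pseudo
individual-patient records. Published figures rarely include
numbers-at-risk tables, so the algorithm assumes the never-event mass
`n x S(t_last)` is censored at a constant rate over follow-up. Within
each digitised interval, censorings are placed before the interval's
first event (the order its risk-set arithmetic assumes), and the event
count at each coordinate is chosen against the *running reconstructed*
curve, so rounding errors do not accumulate — the reconstructed
Kaplan-Meier matches every digitised coordinate to about `1/n`. Event
times are spread log-uniformly up to each coordinate: survival for
positive-valued event times decays smoothly in log time, so this tracks
the within-interval path much better than placing all events on the
coordinate. Between coordinates the original curve still fluctuates
around the reconstruction like a bridge with standard deviation of
order `sqrt(events per interval)/n`; at 40 digitised points and n = 200
that bound is about 0.02, which is why the round-trip tests assert the
replicate-averaged sup-norm rather than a single draw.

### Fitting and selection

`fit_parametric()` maximises the right-censored likelihood (density for
events, survival for censored subjects) via `flexsurv::flexsurvreg`
with a relative convergence tolerance of 1e-10; Gompertz fits start
from a near-exponential shape with the crude event rate, and a negative
Gompertz shape is allowed. Six families are screened (exponential,
Weibull, log-normal, log-logistic, gamma, Gompertz) and
`select_model()` picks the lowest AIC, breaking ties by BIC and then by
parsimony. BIC uses the number of *subjects*, the common convention,
and the ranking table records it for transparency.

## Cycle accrual, discounting and the half-cycle correction

Cycles are 21 days with `365.25` days/year; 10 years is 173 full cycles
plus a final partial cycle truncated to the horizon and weighted by its
actual length. Each cycle contributes the *mean of its start- and
end-occupancy* — algebraically the trapezoid rule on the cycle grid,
which is the half-cycle correction — times the cycle length and a
discount factor `(1 + r)^(−t_mid)` at the cycle midpoint, with r = 0.05
per year for both costs and effects. At 21-day cycles this discrete sum
reproduces adaptive numerical integration of the underlying curves to
well under 0.2% relative error, and full occupancy over 10 undiscounted
years accrues exactly 10 life-years.

Event-like quantities follow their timing: one-off costs attached to
incident progressions and deaths are discounted at the midpoint of the
cycle in which they occur; treatment-phase costs (drug acquisition,
administration, monitoring) are applied at the start of each of the six
treatment cycles, weighted by start-of-cycle progression-free occupancy,
and discounted at the cycle start, since the regimen is administered on
day 1 of each cycle.

## Costing

All computation is in USD; CNY columns are derived at 7.2338 CNY/USD.

* **Drug acquisition.** Doses use a 1.73 m² body surface area:
  antibody 375 mg/m², cyclophosphamide 750 mg/m², doxorubicin 50 mg/m²,
  vincristine 1.4 mg/m² capped at 2 mg, prednisone 100 mg/day on days
  2-6. Vials are purchased whole (`ceiling(dose/vial)`, surplus
  discarded), so e.g. 648.75 mg of antibody needs seven 100 mg vials.
  Prednisone is priced as twenty 5 mg tablets per day for five days.
  The configuration prices doxorubicin with the price list's per-10-mg
  anthracycline entry (the only one its source prices), and the
  biosimilar at US$ 193.09 per 100 mg (its source also prints a 139.09
  figure in prose; the tabulated value, whose sensitivity bounds match
  it, is the default and the field is overridable).
* **Administration.** A per-cycle hospitalisation + preventive
  medication + infusion bundle (US$ 92.19). The itemised premedication
  drug prices are carried in the configuration but not costed
  separately — the preventive-medication line covers them, and costing
  both would double-count.
* **Monitoring.** Haematology, serum chemistry, hepatic/renal panel,
  urinalysis and ECG every treatment cycle; immunoglobulins,
  coagulation and echocardiography at cycle 1 only; contrast-enhanced
  CT every second treatment cycle while progression-free. The price
  list gives single unit prices; this cadence is the package's default
  and is configuration-driven.
* **Adverse events.** Seventeen events with arm-specific incidences are
  each costed once per patient at `incidence x unit cost`, assumed to
  occur in the first treatment cycle (discounted at its midpoint).
  Whether AE costs should recur per event is unknowable from the
  source; one-off per patient-at-risk is the default convention.
* **Post-progression pathways.** Five scenarios (DHAP±ASCT, novel
  agent + DHAP + ASCT, DHAP alone, R2+BTK or Pola-BR, CAR-T) are
  modelled as a one-off cost per incident progressor, plus an optional
  recurring per-cycle PD cost. **The pathway magnitudes are
  placeholders**: the trial publication reports no pathway prices. They
  were fixed once so that scenario totals preserve the qualitative
  ordering CAR-T >> novel+ASCT > ASCT > novel > DHAP, and nothing the
  package verifies numerically depends on them.
* **End-of-life care.** US$ 1,036.80 per incident death, discounted at
  the death cycle's midpoint; undiscounted this telescopes to the
  terminal cost times cumulative mortality.

## QALYs

Utility weights 0.83 (PFS), 0.63 (PD), 0 (dead) accrue with the same
half-cycle-corrected discounted sum. Adverse-event disutility (−0.42) is
applied as a one-off cycle-1 decrement equal to
`0.42 x P(any AE) x cycle length in years`, with `P(any AE)` computed
from the incidences under independence (≈ 1 in both arms). This is one
of several defensible conventions — applying it per event, or for a
longer duration, scales the decrement — and it is isolated in a single
function so alternatives are one-line changes. The headline QALY totals
are sensitive to such conventions (and to whether discounting starts at
time zero or mid-cycle); the package therefore anchors its correctness
on invariants — trapezoid identity, integration agreement, probability
conservation, scenario-invariance of incremental QALYs — rather than on
reproducing any particular published QALY total.

## Sensitivity analysis

Every unit price, incidence, utility and the discount rate becomes a
`param_spec` with base, bounds and a sampling family. Bounds default to
±20% of base; the discount rate is varied over its stated 0-0.08 range;
adverse-event incidence upper bounds above 1 truncate to 1.

For probabilistic analysis, bounds are read as a 95% interval, giving
`SD = (upper − lower)/3.92` (so ±20% bounds mean a CV of about 10.2%),
and method-of-moments distributions are built with mean equal to base:
gamma (shape/rate) for costs, beta (alpha/beta) for probabilities and
utilities, the disutility sampled as a beta on its magnitude and
negated, and the discount rate as a beta rescaled to [0, 0.08]. The two
state utilities are sampled independently, so a draw may invert their
ordering — the base-case validator enforces `u_PD <= u_PFS`, the
evaluator deliberately does not. Survival parameters have no published
uncertainty bounds: by default they are excluded from the probabilistic
analysis and varied ±20% in the one-way analysis only, where they are
by far the dominant drivers.

The one-way tornado records the signed incremental cost-effectiveness
ratio at each bound (negative when a bound makes the biosimilar
cost-saving) so it stays defined through dominance; the Monte Carlo
analysis draws all parameters simultaneously (default 10,000
iterations, mandatory seed, draws outside support are resampled with
bounded retries) and the acceptability curve counts draws with strictly
positive incremental net monetary benefit, ties counting against.

## The synthetic-data generator

`simulate_ipd()` draws event times from a declared truth distribution
and applies administrative censoring plus random censoring. Random
censoring must be *independent* of the event time for Kaplan-Meier and
likelihood methods to remain unbiased — censoring a subject at a
uniform point of their own event time is informative and measurably
biases the fitted location parameter — so a `2 x cens_frac` subset of
subjects receives a censoring time drawn independently from the truth
distribution, which censors the target fraction in expectation.
`digitize_km()` then emulates the graph-digitiser workflow: it reads
the Kaplan-Meier step function at survival-quantile-spaced times over
the *plotted* window (curves are truncated where fewer than 10 subjects
remain at risk, as published figures are), optionally adds truncated
Gaussian read-off jitter, and restores monotonicity by running-minimum
clipping.

What passing the synthetic round-trip tests shows: the reconstruction,
fitting and selection machinery recovers a known truth through the same
transformations a digitised publication figure undergoes. What it does
not show: robustness to real digitiser failure modes (axis
miscalibration, plateau misreads, mixed-up censoring ticks), to
non-proportional or cured-fraction survival, or to at-risk tables that
contradict the curve; none of those are modelled.

## Problem sizes and determinism

The test-suite simulations use cohorts of 200-500 subjects, 100
replicates for recovery/selection screens, and 10,000 Monte Carlo
iterations for the probabilistic analysis — the scale at which the
corresponding standard errors are small relative to the tolerances
asserted. At n = 500 the log-normal location MLE has a standard error
of about 0.087 (= γ/√n), a figure worth keeping in mind when judging
how tightly any single fit of that size should be expected to hug the
truth. All stochastic outputs take an explicit seed, and identical
seeds produce byte-identical outputs including the run manifest (which
records the seed, a configuration hash and the package version).

## Known limitations

* Survival beyond trial follow-up is pure log-normal extrapolation; no
  external or background-mortality constraint is applied.
* No covariate adjustment, cure fractions, or spline hazards; the six
  parametric families are the whole candidate set.
* Post-progression pathway costs are structural placeholders (above).
* The healthcare-system perspective excludes indirect and societal
  costs.
* A single average body surface area prices all doses; no patient-level
  dose distribution is modelled.
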