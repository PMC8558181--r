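---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tavicea)
```

## The decision problem

Severe aortic stenosis can be treated by surgical valve replacement
(sAVR), by transcatheter implantation (TAVI), or — when surgery is not an
option — managed medically. TAVI's device cost is high, but its
minimally invasive profile reduces peri-procedural complications and, in
inoperable patients, dramatically extends survival. `tavicea` implements
the standard decision-analytic answer to "is the extra cost worth it":
a Markov cohort model that accumulates discounted costs, life years (LY)
and quality-adjusted life years (QALY) for each strategy and reports the
incremental ratios ICER (euros/LY gained) and ICUR (euros/QALY).

Three patient populations are modelled, each with its own input columns:
intermediate surgical risk (TAVI vs sAVR), high risk (TAVI vs sAVR) and
inoperable (TAVI vs medical therapy).

## State space and cycle structure

Nine states: NYHA classes I–IV crossed with stroke history, plus death.
Severity of heart-failure symptoms (NYHA) drives utility; a major stroke
permanently flips the stroke flag and lowers utility further; death is
absorbing. The cycle length is one month and the default horizon 180
cycles (15 years).

Within a cycle the three competing mechanisms are applied in a fixed
order: death first, then stroke among survivors, then NYHA movement.
The ordering is a modelling choice (the mechanisms are reported
arm-level, not jointly), made so that arm-level mortality dominates and
each step remains individually testable; the composed matrix is checked
row-by-row in the unit tests. Non-stroke clinical events (bleeding,
atrial fibrillation, pacemaker implantation, hospitalisations, repeat
procedures, ...) do not change health state: they are *costed
incidences*, accumulated as expected counts per cycle. Whether stroke
survivors also change NYHA class in the stroke cycle is unspecified in
the source material; the default keeps the class and flips only the flag.

## Input conventions

**Interval probabilities.** Inputs arrive as probabilities over month
bands (1; 2–6; 7–12; 13–24; and for mortality through month 60). Bands
are closed, 1-based month ranges, contiguous from month 1, and a band's
probability is conditional on being alive at its start. The per-cycle
probability is the constant value that compounds back to the band total,
`1 − (1 − p)^(1/n)`; the round trip is exact to 1e−12 by construction.
For 1-month bands the value is used unchanged (reading the band as
per-interval and as per-month coincide there).

**Mortality extrapolation.** Beyond month 60 the annual death
probability follows a straight line fitted by ordinary least squares to
the annual interval probabilities of years 2–5 (year 1 is excluded
because the peri-procedural months dominate it), evaluated at each later
year, clamped to [0, 1] (clamping emits a warning record, not an error),
and converted to monthly. The alternative reading — fitting the
*cumulative* death probability — is available as
`extrapolation_mode = "cumulative"`; the fit window is configurable.

**Carry-forward.** Complication rates hold the last observed band's
monthly rate constant to the horizon.

**Costs.** Unit costs are 2019 euros. The index procedure is billed
once, undiscounted, at model start (tariffs €30,634 TAVI / €24,675 sAVR;
micro-costing scenario €26,985 / €14,802); medical therapy has no index
procedure. Each event category is billed at its tariff in the cycle of
occurrence; repeat procedures reuse the index tariffs. The acute
pulmonary oedema tariff has no incidence input of its own, so it is
loaded but unbilled by default (`oedema_with_hf = TRUE` attaches it to
each heart-failure hospitalisation). In the scenario, rehabilitation is
billed once at model start to the uptake fraction (64 % sAVR, 6.2 %
TAVI); its unit tariff is not published and is therefore a *required*
argument with no default.

## Accrual conventions

Occupancy after the cycle's transition earns that cycle's time: LY and
QALY accrue on end-of-cycle occupancy, at 1/12 year per cycle, discounted
by `(1 + r)^(−t/12)` with `r = 0.03` by default. Event incidences are
billed on the population at risk at cycle *start*. No half-cycle
correction is applied by default (`half_cycle = TRUE` averages start and
end occupancy). These conventions were fixed from first principles
before any tuning: end-of-cycle accrual is the common "count after
transition" cohort convention and reproduces the published inoperable
life-year totals closely; the initial NYHA distribution (not published)
defaults to uniform over classes II–IV without stroke history.

## Sensitivity analyses

*One-way*: every registered scalar input group is rerun at ×0.8 and ×1.2
with everything else at base. Interval probabilities are grouped as one
multiplier per event–arm pair, so tornado entries match the granularity
decision makers read ("mortality over the horizon", "HF hospitalisation
risk"), not individual band cells; costs and utilities are perturbed
singly. Probabilities and utilities are clamped to [0, 1] and flagged.
At zero perturbation every entry reproduces the base ICUR exactly (a test
asserts this identity).

*Probabilistic*: Beta distributions for probabilities and utilities,
Normal for tariff costs, sampled independently per draw (no correlation
structure is asserted anywhere in the source material), 1000 draws by
default, reproducible from a seed. The single largest inferential gap is
the unreported dispersion: the default standard error is 20 % of each
mean, chosen to mirror the one-way perturbation magnitude, and is
configurable (`se_frac`). Beta parameters come from the method of
moments with a point-mass fallback at infeasible variances; negative
Normal cost draws are resampled up to a cap. Interval probabilities of
one event–arm pair share a quantile per draw (`mode = "multiplier"`);
fully independent sampling is available. The acceptability curve is the
fraction of draws with positive net monetary benefit `λ·ΔQALY − ΔC`.

## Synthetic supplementary inputs

The NYHA-transition matrices and state utilities live in supplementary
tables that are not packaged; runs therefore default to synthetic
stand-ins that emulate their *structure* only: intervention arms move
toward NYHA I (more strongly in the first 12 cycles), medical therapy
progresses toward NYHA IV, utilities decrease strictly with NYHA class
and carry a stroke decrement (default gradient 0.85/0.74/0.62/0.50,
decrement 0.12 — values in the range typical of heart-failure utility
studies, chosen once and not calibrated to any output). Everything that
depends only on mortality and costs — life years, total costs, the ICER
per LYG — is unaffected by these stand-ins; QALYs and the ICUR are not
comparable to published values until real tables are supplied via
`utilities_file` / `transitions_file` (the CSV schemas are identical to
what `write_synthetic_inputs()` emits). Passing tests on synthetic
inputs therefore demonstrate correct mechanics, not agreement of
utility-dependent results with any external analysis.

The generator also produces degenerate ground-truth regimes — constant
hazards, identity NYHA dynamics, flat utilities — whose discounted LY,
QALY and cost have geometric-series closed forms; the full pipeline must
reproduce these to 1e−9, which is the backbone of the engine's
verification.

## Numerical choices and degenerate inputs

- Transition-matrix rows are exactly renormalised at construction; traces
  are validated to row sums within 1e−9 and monotone death occupancy.
- `p = 1` stays 1 under interval conversion at any cycle length.
- A zero-cycle horizon yields zero accruals and only the index cost.
- Incremental ratios are formed on unrounded deltas; a non-positive
  denominator flags the ratio `NA` rather than raising, and dominance is
  reported when the deltas have opposite beneficial signs.
- Cost breakdowns are exact partitions of the total (tested to 1e−6 €).

## Reproduction scope and known limitations

With the packaged main-text inputs the model reproduces published
discounted life years well for the high-risk (4.50/4.09 computed vs
4.49/4.08 published) and inoperable (3.23/1.60 vs 3.17/1.60) groups;
the intermediate group comes out ~6 % higher under every defensible
reading of "linear extrapolation", though the life-year *difference*
between arms agrees within ~4 % in all groups. Follow-up event costs
are only partially recoverable: the per-arm totals implied by the
published results cannot all be reconciled with the printed interval
inputs under any uniform billing rule we tested (carry-forward horizon,
at-risk convention, month-1 exclusion), which suggests the original
workbook used additional unprinted inputs. The computed cost per
life-year gained is within ~8 % of print for the intermediate group and
overstates the high-risk and inoperable ratios; the acceptance tests
encode the published values at a "few percent" tolerance and the
discrepancies are left visible rather than absorbed into recalibrated
inputs.

Other limitations: cohort expectations only (no microsimulation, no
individual-level heterogeneity); no NYHA-specific mortality (mortality
is arm-level); independence of all sampled parameters in the PSA; no
societal perspective or indirect costs.

## Problem sizes used in the test-suite

Unit and property tests run on 8–60-cycle chains (path enumeration is
exponential and is kept to ≤3 live states and 8 cycles); full-horizon
checks use the packaged 180-cycle inputs; the PSA recovery test uses the
default 1000 draws. These sizes were chosen as the smallest that
exercise every code path at full fidelity.
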