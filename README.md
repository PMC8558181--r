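# tavicea

A Markov cohort cost-effectiveness model for **transcatheter aortic valve
implantation (TAVI)** in severe aortic stenosis, from the perspective of a
national health system. The model compares TAVI with surgical aortic valve
replacement (sAVR) in intermediate- and high-surgical-risk patients and
with medical therapy in inoperable patients, and is aimed at health
economists and HTA analysts who want a transparent, fully tested
re-implementation of this class of decision model in R.

## The model

The cohort moves monthly through nine health states: NYHA functional
classes I–IV, each with and without a history of major stroke, plus death
(absorbing). Each cycle composes, in a fixed order,

1. death, at the arm's per-cycle mortality probability `p_t`;
2. major stroke among survivors, flipping the stroke flag within the same
   NYHA class;
3. NYHA redistribution by the arm's monthly transition matrix.

Published inputs are *interval* probabilities (e.g. "2–6 months: 3.9 %");
they are converted to the constant per-cycle probability
`p_cycle = 1 − (1 − p_interval)^(1/n)` that compounds back exactly.
Mortality is extended beyond the observed 60 months by an OLS line through
the annual probabilities of years 2–5; complication rates carry the last
observed band forward. Discounted outcomes accrue per cycle `t` with
factor `(1 + r)^(−t/12)` (default `r = 0.03`):

- life years `LY = Σ_t alive_t · d_t / 12`,
- QALYs `Σ_t Σ_s occ_{t,s} · u_s · d_t / 12`,
- costs = index procedure + `Σ_t` expected events × unit costs × `d_t`,

and the incremental ratios are `ICER = ΔC/ΔLY` (euros per life-year
gained) and `ICUR = ΔC/ΔQALY` (euros per QALY). One-way (±20 %, tornado)
and probabilistic sensitivity analyses (Beta for probabilities and
utilities, Normal for tariffs, 1000 draws) with cost-effectiveness
acceptability curves are included.

The NYHA-transition and utility tables the original analysis took from
supplementary material are not in the packaged inputs; a synthetic-data
module generates clearly labelled stand-ins with the right structure, and
real tables can be supplied as CSVs through the same schemas.

## Worked example

```r
library(tavicea)

ps <- load_parameter_set("inoperable_base")
ce <- compute_ce(run_arm(ps, "tavi"), run_arm(ps, "medical"))
ce
#> <ce_result> tavi vs medical: Δcost 15869, ΔQALY 1.749, ΔLY 1.633
#>   ICUR 9071 /QALY, ICER 9720 /LYG, dominance: none

glance(ce)   # one-row tibble with deltas, ICER/ICUR, dominance
tidy(ce)     # per-arm discounted cost / QALY / LY
```

The inoperable cohort gains 1.63 discounted life years from TAVI at an
extra discounted cost of €15,869, i.e. €9,720 per life-year gained; the
€9,071/QALY figure uses the *synthetic* utility and NYHA inputs and shifts
when real tables are supplied. Tabulated runs:

```r
run_base_case("all")                      # per-arm totals + deltas, all groups
run_scenario("all", rehab_cost = 2500)    # micro-costing + rehabilitation
sens <- run_sensitivity("intermediate", n_draws = 1000, seed = 1)
autoplot(sens$ceac); autoplot(sens$psa); autoplot(sens$tornado)
```

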