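---
title: "Modelling the net human-health effect of schizophrenia maintenance treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the net human-health effect of schizophrenia maintenance treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdaly)
```

## What the package computes

`netdaly` couples two calculi that are usually kept apart. A Markov cohort
model produces the clinical outcomes of maintaining 1000 patients with
schizophrenia on long-acting paliperidone palmitate — once-monthly (PP1M)
or three-monthly (PP3M) injections — against treatment interruption (TI).
The same cohort trace yields the health-care *consumption profile*
(syringes, visits, bed days), which per-unit endpoint factors convert into
environmental Human Health DALYs. Both sides land in the same unit, so
they merge into a net score:

$$\mathrm{DALY}_{patient} = \mathrm{YLD} + \mathrm{YLL}, \qquad
  \mathrm{DALY}_{net} = \mathrm{DALY}_{patient} + \mathrm{DALY}_{env}.$$

## The cohort model and its assumptions

The state space has five clinical states — *Stable: Adherent*, *Stable:
Non-adherent*, *Relapse: Hospitalization*, *Relapse: Ambulatory care*,
*Death* — with each relapse month expanded into a tunnel state
(`expand_tunnel_states()`, depth `K = 8` by default, 19 states). Tunnel
states exist because hospital discharge is strongly time-dependent: the
observed distribution of stays is right-skewed, with most patients leaving
before the mean stay. The 8th tunnel month self-loops, so longer stays are
representable.

Cycles are monthly over a 1-year horizon; patients start adherent
(post-initiation) at a weighted mean age of 41.61 years. The monthly
transition probabilities are the published point estimates (relapse
0.0086/0.0075 adherent, 0.0639/0.0282 non-adherent for PP1M/PP3M; 69%
of relapses hospitalized; 72% of recoveries return to adherence;
discontinuation 0.1200 per month for PP1M and 0.2816 per 3 months for
PP3M; restart 0.1489 per month; SMR 2.58 stable, 6.2 in relapse).
Design choices the sources leave open, resolved here once:

- **Event ordering within a cycle**: death is resolved first (with the
  SMR of the state at cycle start), relapse competes among survivors, and
  discontinuation/restart applies to survivors who did not relapse. This
  keeps every row stochastic without renormalization and lets each
  published probability enter linearly.
- **Tunnel mortality**: every relapse month uses the relapse SMR (6.2);
  the sources attach that SMR to "patients in relapse" without a time
  qualifier.
- **TI recoveries**: recovered TI patients enter the non-adherent state
  (the 72/28 split is disabled, restart is off). TI patients do not seek
  medication on their own initiative and consume no syringes; routing
  recoveries to adherence would contradict both. TI patients are adherent
  only in cycle 1, from remaining drug coverage.
- **Ambulatory relapse** shares the hospital discharge hazards (relapse
  length was assumed equal across settings).
- **No half-cycle correction**: the occupancy in force during month `t`
  is the post-transition distribution at the start of the month; month 1
  is the initial distribution. Accumulation (YLD, QALY, consumption) uses
  these monthly counts divided by 12 for person-years.
- **PP3M discontinuation** applies only in cycles divisible by 3; restart
  is evaluated monthly (re-initiation runs on the once-monthly product).

Probabilities are clamped to [0, 1] after SMR multiplication;
row-stochasticity is validated to 1e-9 before iteration
(`validate_schedule()`).

## Outcome calculus

YLD weights occupancy with the Global Burden of Disease weights (residual
state 0.588, acute state 0.778). The death state is excluded from YLD
even though the source table lists disability 1.000 for it: counting
death both as disability and as YLL would double-count fatal burden.
YLL weights each death with the residual life expectancy at the attained
age of the death month (the cohort ages 1/12 year per cycle); the
`linear` option instead decrements the starting value by 1/12 per month,
an alternative reading of the same adjustment. No discounting or
age-weighting anywhere. QALYs use the layperson utilities (0.865 stable,
0.916 for PP3M adherent, 0.479 relapse) with adverse-event decrements
(EPS 0.291, weight gain 0.086, diabetes 0.153) subtracted in both stable
states, weighted by monthly incidence.

## Synthetic inputs and what they do (and do not) show

Three inputs the sources use are not published, so the package generates
them; each is labelled synthetic and is a free parameter:

- **Life table** (`make_life_table()`): Gompertz–Makeham hazard
  `mu(x) = A + B e^{Cx}` (A = 5e-4, C = 0.095 per year), with `B`
  calibrated so that the residual life expectancy at age 41.61 equals the
  published anchor 39.54 years (within 0.01). Only the anchor is a
  published constraint; the curve family is a modelling choice.
- **Discharge schedule** (`make_discharge_schedule()`): a lognormal
  length-of-stay distribution (mean 60 days, sdlog 0.8 by default)
  discretized into monthly hazards `d_1..d_8` with a geometric tail. The
  60-day mean is a configurable placeholder chosen for order-of-magnitude
  consistency with published bed-day totals; the true hospital value is
  withheld in the sources. The lognormal reproduces the documented
  right-skew (median < mean).
- **Adverse-event incidence** (`make_ae_incidence()`): monthly
  probabilities 0.010 (EPS), 0.018 (weight gain), 0.0025 (diabetes) —
  trial-plausible magnitudes, flagged `synthetic`.

Consequently the engine's default YLD/YLL totals characterize the model
under these synthetic conditions, not the source study's exact table;
reproducing those exactly would require the unpublished transition
matrices. What the defaults *do* preserve — and what the test suite
asserts — is the structural behaviour: mass conservation, monotone
absorption into death, agreement with an individual-level
microsimulation, the stable-cohort limits (588 YLD, 865 QALY per 1000
patient-years), and the scenario ordering YLD(PP3M) ≤ YLD(PP1M) ≤
YLD(TI) that follows from the ordered relapse probabilities.

One parsing note: the published consumption table flattens the stable-state
row ambiguously; the package adopts 0.33 GP visits and 3 psychiatrist
visits per stable patient-month, because the accompanying text states
"three psychiatrist visits per month" explicitly. The whole consumption
matrix is user-overridable.

## Environmental factors

The per-scenario endpoint burden table (resource type × pathway element,
three scenario blocks) ships as a plain-CSV transcription; per-unit
factors are derived at load time (`derive_unit_factors()`), never
hard-coded. Care-provider factors (per visit, per bed day) are taken from
the TI block, which has the largest counts and therefore the least
rounding error; supply-chain factors are per syringe from the PP1M block
(805 syringes). The PP3M block covers 594 once-monthly re-initiation
syringes and 2564 three-monthly syringes in one printed block; the
default stores it as a blended per-syringe factor over all 3158 syringes
(reproducing the block sum exactly), with a two-scenario linear solve
available via `attribution = "solve"` — no attribution is verifiable from
the printed blocks alone, since they do not scale with API mass.
Non-determined cells are stored as zero. Negative cells (waste
incineration with energy recovery) are kept as credits; scenario totals
remain positive. Hospital resource shares are reported excluding patient
transport, i.e. on on-site resource use. The end-of-life mass flow
`dose × (1 − 0.41) × (1 − 0.64)` is exposed separately
(`eol_emitted_mass()`); its toxicity characterization is out of scope —
the end-of-life DALY column is carried as a per-syringe factor like any
other.

## Sensitivity analysis

`one_way_sweep()` reruns the *entire* pipeline at each parameter's low
and high bound (± one standard deviation when available, else ±20%,
truncated to valid domains) and sorts by outcome spread.
`probabilistic_sa()` draws parameter sets — beta for probabilities
(method of moments), gamma for durations, truncated normal for ratios;
standard deviations default to reading the ±20% range as a 95% interval —
and runs every scenario per draw with common random numbers (the same
uniform quantile per parameter across scenarios), which stabilizes the
scenario deltas. `conclusion_robustness()` reports the fraction of paired
draws in which treatment remains net-favourable. All draws are
reproducible from the seed.

## Numerical choices and problem sizes

Residual life expectancy integrates survival on a monthly grid with
trapezoidal accumulation; calibration uses `uniroot` on `log B` to 1e-12.
Stochasticity tolerance is 1e-9, mass-conservation tolerance 1e-6 per
cycle. The test suite runs the cohort engine at the study size (1000
patients, 12 cycles, 19 states), checks it against a 100,000-walker
microsimulation, and sizes Monte-Carlo checks (10,000–100,000 draws for
distribution moments and length-of-stay means; 24–200 draws for
probabilistic-analysis properties) so the full suite completes in a few
seconds.

## Known limitations

- The engine cannot reproduce the sources' exact patient totals without
  the unpublished transition matrices; `run_cohort()` accepts a
  user-built `transition_schedule`, so supplying a transcription of those
  matrices is supported.
- The environmental side is factor-based: it inherits the published
  endpoint characterization and cannot re-derive it from inventories.
- The published psychiatric-hospital resource-share percentages differ by
  about 1 point from any recomputation of the printed columns (with or
  without transport); the package reports the recomputed values.
- Whether relapse risk in the cycle of discontinuation should use the
  pre- or post-discontinuation adherence state is unresolved in the
  sources; the event ordering above uses the state at cycle start.
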