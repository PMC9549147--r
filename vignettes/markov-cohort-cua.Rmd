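---
title: "A Markov cohort cost-utility model for sequential knee osteoarthritis care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for sequential knee osteoarthritis care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oacua)
```

## The decision problem

Knee osteoarthritis is managed as an escalating care sequence: an analgesic
first, then an NSAID with gastroprotection, possibly a symptomatic
slow-acting drug (crystalline glucosamine sulfate) or a selective COX-2
inhibitor (etoricoxib), then intra-articular triamcinolone injection, and
finally total knee arthroplasty (TKA). Where a payer places glucosamine or
etoricoxib in that sequence — or whether it reimburses them at all — is an
economic question: the cheaper drugs buy time before the rungs with heavy
cardiovascular and gastrointestinal adverse-event burdens, at the price of
their own drug cost.

`oacua` models this as a Markov cohort state-transition model. Each
treatment is a state; each 6-month cycle, a patient either has their pain
relieved (probability $p_i$, staying in state $i$) or does not, in which
case the treatment has failed and they move irreversibly to the next rung.
Background mortality can strike from any state; death is absorbing. Six
strategies — the standard sequence and five insertions of glucosamine
and/or etoricoxib — are compared on discounted lifetime cost (THB) and
QALYs via the dominance/extended-dominance frontier and ICERs, with
one-way and probabilistic sensitivity analysis on top.

## Model structure and its two debatable edges

**What happens when the last rung fails.** The care chain ends
"... triamcinolone injection, TKA, death": the state after the terminal
treatment *is* the death state, so a cycle in which the terminal
treatment fails to control pain absorbs into death. This is a strong
reading, and we adopted it deliberately (`economics$terminal_failure =
"death"`, the default). The alternative — TKA failures surviving
indefinitely in a moderate-pain compartment — is available as
`terminal_failure = "persist"` and is exercised in the test-suite, but as
a base case it gives every strategy essentially the same discounted
life expectancy (~12+ QALYs at ages 45+), which makes the strategies
nearly indistinguishable on effectiveness and is irreconcilable with
lifetime-horizon QALY totals in the 2–5 range for this population. Under
the death reading, longer care sequences literally buy survival time,
which is what gives the add-on strategies their QALY gains.

**Where etoricoxib sits.** The sequences only say etoricoxib is "added"
to standard care. The fixture places it after the NSAID block (after
diclofenac+PPI, and after any glucosamine inserted behind diclofenac),
before the injection rung — the conventional second-line position for a
selective COX-2 inhibitor after non-selective NSAID failure.

## Adverse events

Five adverse events attach to treatment states as per-cycle incidences,
constant while the patient occupies the state:

* **Transient** (GI discomfort, symptomatic ulcer): resolve within the
  cycle. They are accrued in expectation — occupancy × incidence × acute
  cost, and the matching disutility decrement — rather than as
  compartments, since a one-cycle condition needs no memory.
* **Chronic** (stroke, MI, heart failure): the first event flags the
  patient permanently. Chronic conditions are compartments, crossed with
  every treatment state, carrying a *condition-phase* counter that encodes
  time since the event in the only resolution the cost data need:
  phase 1 (the event cycle's acute cost, e.g. 56,133 THB for stroke),
  phases 2–3 (the first-year cost split over two half-year cycles), and
  phase 4+ (the subsequent-year cost per half-year, indefinitely). The
  chronic disutility subtracts every cycle from the first post-event
  cycle onward. Only patients with no prior chronic event are at risk
  (one chronic condition per patient); competing chronic onsets are
  scaled proportionally in the unlikely case their incidences sum past 1.
* **Perioperative risks** (`ae_entry_only`, used for TKA): incidences
  apply only in the entry cycle. Such states are split into an entry and
  a post stage so that the risk, the one-time cost and the per-cycle
  drug cost attach to the entry cycle only.

Background mortality deliberately carries the *only* death risk —
adverse events are morbid and costly but not fatal here. That is the main
acknowledged fidelity gap of the model, and one reason absolute totals
are not expected to reproduce any published set exactly.

## Accrual conventions

Per cycle $t$ (length $\ell = 0.5$ years, discount rate $r = 3\%$/year):

* **Utility**: occupants of state $i$ accrue
  $p_i u_{np} + (1-p_i) u_{mp}$ — responders get the no-pain utility
  (0.62), the fraction whose pain persists gets the moderate-pain
  utility (0.56) for the cycle spent in the failing state. Exhausted
  ("persist"-mode failed) compartments accrue $u_{mp}$. Disutilities
  subtract; a utility pushed below 0 is floored with a warning.
  QALYs are $\ell \times$ occupancy-weighted utility.
* **Cost**: per-cycle treatment cost plus outpatient visit cost
  (travel 143 + food 53 THB per visit, one visit per cycle by default)
  plus indirect cost (0 by default: productivity losses are declared in
  the source cost list but unpublished) for every live compartment;
  one-time costs on state entrants; transient expected costs; chronic
  phase costs.
* **Discounting**: start-of-cycle, factor $(1+r)^{-\ell t}$;
  `discount_timing = "mid"` shifts accrual to mid-cycle. Both streams
  use the same rate, as the Thai HTA guideline prescribes.
* **Ordering of competing risks**: background death first, then the
  survivors split between chronic-condition evolution and
  stay/progress — so rows of the cycle transition matrix are stochastic
  without renormalisation.

The cohort recursion stops when the live fraction falls below $10^{-9}$
or at age 100 (whichever first; the latter sets a truncation flag). From
age 45 that is at most 110 cycles.

## Mortality

No published background-mortality input exists for this model, so the
packaged life table (`life_table_synthetic.csv`) is **synthetic**: a
Gompertz-shaped annual schedule $q(x) = 0.004\,e^{0.085 (x - 45)}$
evaluated at 5-year band midpoints and capped at 1 — a plausible shape
for a middle-aged cohort, chosen once and not calibrated to anything.
Annual probabilities convert to cycles as $1-(1-q)^{\ell}$. A constant
per-cycle mode exists for tests and closed-form oracles.

## Parameter uncertainty

`build_param_table()` enumerates every uncertain scalar with a
distribution family assigned by class, following the source's stated
rule literally even where it is unconventional:

| class | family | note |
|---|---|---|
| costs | gamma | method of moments: shape $(m/s)^2$, scale $s^2/m$ |
| AE probabilities, utilities, disutility magnitudes | beta | $\nu = m(1-m)/s^2 - 1$; infeasible moments ($s^2 \ge m(1-m)$) are an error |
| pain-relief (transition) probabilities | log-normal | $\sigma^2 = \ln(1+s^2/m^2)$; draws clamped to $[0,1]$ |

Parameters with no published standard error (all pain-relief and AE
probabilities, and the treatment costs) default to $s = 0.2m$,
configurable per parameter; zero-mean or zero-SE parameters are fixed.
Each parameter draws from its own RNG substream (a string hash of its id
mixed with the root seed), so adding a parameter never perturbs the
others' draws and the whole PSA is byte-reproducible given a seed. All
strategies are evaluated on the same draw (common random parameters).

One-way (tornado) ranges use published bounds where they exist (utility
of moderate pain 0.35–0.77; TKA cost 78,533–79,316 THB) and ±20% of base
otherwise, clamped to $[0,1]$ for probabilities; the default range of the
registry for unlisted parameters is mean ± 2 SE. The tornado's output
metric is the incremental net monetary benefit of the headline pair
(etoricoxib + early glucosamine vs early glucosamine alone) at 160,000
THB/QALY, configurable to the ICER. Two consequences of that comparison
are worth knowing before reading the diagram: parameters shared by both
arms at the same sequence position (e.g. the glucosamine cycle cost)
cancel and produce a zero-width bar, and the NSAID transition
probability's default range touches 1.0 — a boundary where no patient
ever progresses and the increment collapses — which is why it can top
the diagram ahead of the moderate-pain utility.

## Frontier and decision rules

Strict dominance (cost no higher, QALYs no lower, one strict) is removed
first, then extended dominance (a point whose incremental ratio exceeds
the next segment's) by iterative removal; surviving points are annotated
with pairwise ICERs in QALY order, which are strictly increasing by
construction. Ties on (cost, QALY) are kept and flagged. The designated
reference keeps the label `reference`; a frontier strategy that strictly
dominates it is labelled `dominant`. Deterministic tie rules elsewhere:
CE-plane points on an axis count toward the favourable (lower-right)
quadrant; the pairwise CEAC uses $\ge$ (so a riskless pair steps from 0
to 1 exactly at its ICER); the multi-way CEAC awards exact ties to the
first strategy in order, keeping the curves a partition of 1.

## The synthetic generator

`generate_model()` emits random but structurally valid models — 2 to 8
states with random relief probabilities, sparse adverse-event profiles,
cost schedules, utility pairs, Gompertz-like or constant mortality, both
terminal-failure modes — for the property tests: mass conservation and
monotone death occupancy across 1,000 models, equality with exhaustive
path enumeration on small models, and closed-form geometric-series
totals for two-state chains. It emulates the *shape* of the inputs, not
their epidemiology: passing those tests shows the recursion and accrual
arithmetic are right, not that any particular parameterisation is
clinically faithful. A negative-mode generator deliberately violates the
beta moment condition to exercise the sampling layer's error paths.

## Problem sizes and numerical tolerances

The packaged analyses run six strategies over at most 110 cycles;
`analysis/03_psa.R` and the acceptance script use 1,000 Monte-Carlo
iterations, the published iteration count. Conservation is checked to
$10^{-12}$ per row, oracle equivalence to $10^{-9}$, moment roundtrips
to $10^{-9}$, sampled means to 3 Monte-Carlo standard errors at
$10^{5}$ draws.

## Known limitations

* Absolute cost/QALY totals are not expected to match any published
  table: background mortality, indirect costs and several accrual
  conventions are this package's own choices where the sources are
  silent. Orderings (which strategy dominates, which ICERs clear the
  threshold) are the reproducible content, and are what the acceptance
  checks assert.
* Under the default uncertainty configuration the early-glucosamine
  sequence dominates standard care in roughly 85% of PSA draws
  (run `analysis/03_psa.R` or `scripts/acceptance.R` to recompute): its
  base-case cost saving is thin relative to total cost, and draws in
  which the NSAID transition probability clamps at 1 erase the
  progression delay that generates the saving. A published claim of
  dominance in 100% of iterations is therefore not reproduced under
  these defaults.
* Adverse events carry no excess mortality; multiple chronic conditions
  per patient are not modelled; there is no treatment re-challenge, no
  revision surgery, no half-cycle correction by default.
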