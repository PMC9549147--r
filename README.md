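# oacua

Markov cohort cost-utility analysis of sequential knee-osteoarthritis
care in Thailand.

## What it does

Knee OA is treated by escalation: acetaminophen → diclofenac + PPI →
triamcinolone injection → total knee arthroplasty, with death the
absorbing final state. Health-economic questions about this pathway are
questions about *sequence design*: does inserting crystalline
glucosamine sulfate before the NSAID rung, or adding etoricoxib after
it, buy QALYs cheaply enough?

`oacua` implements the standard machinery for answering them:

* a **cohort state-transition model** over a care sequence: each cycle
  (6 months), occupants of treatment state $i$ stay with the pain-relief
  probability $p_i$ or progress irreversibly with $1-p_i$; background
  mortality applies first each cycle. Adverse events enter as
  expected-value accruals (transient GI events) or as chronic substates
  with phased cost schedules (stroke, MI, heart failure);
* **discounted accrual**: cost and QALY streams discounted at
  $(1+r)^{-t}$, $r=3\%$/year, with the no-pain utility (0.62) for
  responders and the moderate-pain utility (0.56) for the cycle in which
  a treatment fails;
* **frontier analysis**: strict and extended dominance, ICERs
  $\Delta C/\Delta E$ along the frontier, net monetary benefit
  $\lambda E - C$, THB→USD conversion at 36.16;
* **sensitivity analysis**: one-way tornado, and Monte-Carlo PSA with
  method-of-moments gamma (costs), beta (probabilities/utilities) and
  truncated log-normal (transition probabilities) sampling, CE-plane
  quadrants and cost-effectiveness acceptability curves.

The packaged configuration (`inst/extdata/thailand_oa_2022.yaml`)
carries the published per-cycle probabilities, costs, utilities and
disutilities for six care-sequence strategies; the background-mortality
life table is synthetic (no published value exists) and is labelled as
such. The numbered scripts under `analysis/` chain the pieces into the
full study; the methods vignette (`vignettes/markov-cohort-cua.Rmd`)
documents the model, its conventions and its limitations.

## Worked example

```r
library(oacua)
model <- example_model()
res   <- run_all_strategies(model)
dominance_frontier(res)
```

```
                      strategy   cost qaly       label   icer
                      standard 184902 3.02   reference
            glucosamine_before 183222 3.40    dominant
             glucosamine_after 192118 3.38   dominated
                    etoricoxib 213565 3.52   dominated
 glucosamine_before_etoricoxib 210967 3.89 on_frontier 56,853
  glucosamine_after_etoricoxib 220017 3.86   dominated
```

Reading: starting glucosamine *before* the NSAID rung costs less
(183,222 vs 184,902 THB discounted) and yields more QALYs (3.40 vs 3.02)
than standard care — it is dominant. Every sequence that delays
glucosamine or adds etoricoxib without the early glucosamine is
dominated. The only other efficient sequence adds etoricoxib on top of
early glucosamine at 56,853 THB per extra QALY, well under the Thai
willingness-to-pay threshold of 160,000 THB/QALY. (Absolute totals
depend on this package's own mortality and accrual choices — see the
vignette — so orderings and threshold comparisons, not totals, are the
reproducible content.)

The same pipeline drives the sensitivity analyses:

```r
tornado_analysis(model, comparison = c("glucosamine_before_etoricoxib",
                                       "glucosamine_before"))
psa <- run_psa(model, n_iter = 1000, seed = 1)
ce_plane(psa, "glucosamine_before", "standard")$proportions
ceac(psa, strategy = "glucosamine_before_etoricoxib",
     comparator = "glucosamine_before")
```

or, as ready-made reports with CSV outputs and JSON run manifests:

```r
report_basecase(model, "results/basecase")
report_dsa(model, "results/dsa")
report_psa(model, "results/psa", n_iter = 1000, seed = 1)
```

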