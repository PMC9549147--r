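Package: oacua
Title: Markov Cohort Cost-Utility Analysis of Knee Osteoarthritis Care Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov cohort state-transition model for cost-utility analysis
    of sequential knee osteoarthritis treatment strategies. Care sequences are
    chains of treatment states (analgesics, NSAIDs plus gastroprotection,
    SYSADOA, intra-articular injection, arthroplasty) with an absorbing death
    state; adverse events enter as transient expected-value accruals or as
    chronic substates with phased cost schedules. The package accrues
    discounted costs and quality-adjusted life-years per cycle, builds the
    dominance/extended-dominance frontier with incremental cost-effectiveness
    ratios, and runs one-way deterministic and probabilistic sensitivity
    analyses (method-of-moments gamma/beta/log-normal sampling,
    cost-effectiveness plane and acceptability curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
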