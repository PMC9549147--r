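# Base-case model configuration: Thai knee-osteoarthritis care sequences.
# Probabilities are per 6-month cycle; all money in THB.
# Treatment costs are per cycle at the stated daily dose, except TKA
# (one-time cost at state entry) and TA injection (two 3-monthly
# injections of 114 THB per cycle). Diclofenac is co-prescribed with
# omeprazole: 128 + 94 = 222 THB per cycle.
# The mortality life table is SYNTHETIC (no published source value): a
# Gompertz-shaped schedule supplied with the package for completeness.

states:
  acetaminophen:
    pain_relief_prob: 0.3380
    ae: {gi_discomfort: 0.2382, symptomatic_ulcer: 0.0007, stroke: 0.0005, mi: 0.0013, heart_failure: 0.0000}
    cycle_cost: 213
  glucosamine:
    pain_relief_prob: 0.3857
    ae: {gi_discomfort: 0.1093, symptomatic_ulcer: 0.0000, stroke: 0.0019, mi: 0.0019, heart_failure: 0.0000}
    cycle_cost: 1874
  diclofenac_ppi:
    pain_relief_prob: 0.8647
    ae: {gi_discomfort: 0.1013, symptomatic_ulcer: 0.0044, stroke: 0.1012, mi: 0.2289, heart_failure: 0.0007}
    cycle_cost: 222
  etoricoxib:
    pain_relief_prob: 0.5657
    ae: {gi_discomfort: 0.0556, symptomatic_ulcer: 0.0014, stroke: 0.1071, mi: 0.2107, heart_failure: 0.0010}
    cycle_cost: 5213
  ta_injection:
    pain_relief_prob: 0.0392
    ae: {gi_discomfort: 0.0000, symptomatic_ulcer: 0.0000, stroke: 0.0000, mi: 0.0000, heart_failure: 0.0000}
    cycle_cost: 228
  tka:
    pain_relief_prob: 0.5122
    ae: {gi_discomfort: 0.0000, symptomatic_ulcer: 0.0899, stroke: 0.0000, mi: 0.0469, heart_failure: 0.0100}
    cycle_cost: 0
    one_time_cost: 78925
    is_terminal_treatment: true
    ae_entry_only: true   # perioperative risks, entry cycle only

strategies:
  standard:
    label: "Standard treatment"
    sequence: [acetaminophen, diclofenac_ppi, ta_injection, tka]
  glucosamine_before:
    label: "Standard treatment + Glucosamine (before diclofenac plus PPI)"
    sequence: [acetaminophen, glucosamine, diclofenac_ppi, ta_injection, tka]
  glucosamine_after:
    label: "Standard treatment + Glucosamine (after diclofenac plus PPI)"
    sequence: [acetaminophen, diclofenac_ppi, glucosamine, ta_injection, tka]
  etoricoxib:
    label: "Standard treatment + Etoricoxib"
    sequence: [acetaminophen, diclofenac_ppi, etoricoxib, ta_injection, tka]
  glucosamine_before_etoricoxib:
    label: "Standard treatment + Etoricoxib + Glucosamine (before diclofenac plus PPI)"
    sequence: [acetaminophen, glucosamine, diclofenac_ppi, etoricoxib, ta_injection, tka]
  glucosamine_after_etoricoxib:
    label: "Standard treatment + Etoricoxib + Glucosamine (after diclofenac plus PPI)"
    sequence: [acetaminophen, diclofenac_ppi, glucosamine, etoricoxib, ta_injection, tka]

adverse_events:
  gi_discomfort:
    acute_cost: 436
    acute_cost_se: 11
    disutility: -0.0228
    disutility_se: 0.0001
  symptomatic_ulcer:
    acute_cost: 3734
    acute_cost_se: 95
    disutility: -0.0269
    disutility_se: 0.0002
  stroke:
    acute_cost: 56133          # in the 6 months of the event
    acute_cost_se: 1432
    first_year_cost: 7173
    first_year_cost_se: 183
    subsequent_year_cost: 10029
    subsequent_year_cost_se: 256
    disutility: -0.0524
    disutility_se: 0.0001
  mi:
    acute_cost: 138916
    acute_cost_se: 3544
    first_year_cost: 4706
    first_year_cost_se: 120
    subsequent_year_cost: 13588
    subsequent_year_cost_se: 347
    disutility: -0.0409
    disutility_se: 0.0002
  heart_failure:
    acute_cost: 15347
    acute_cost_se: 392
    first_year_cost: 3974
    first_year_cost_se: 101
    subsequent_year_cost: 7948
    subsequent_year_cost_se: 203
    disutility: -0.0635
    disutility_se: 0.0002

utilities:
  no_pain: 0.62
  no_pain_se: 0.0036
  moderate_pain: 0.56
  moderate_pain_se: 0.0152

economics:
  annual_discount_rate: 0.03
  cycle_length_years: 0.5
  wtp_per_qaly: 160000
  fx_thb_per_usd: 36.16
  start_age_years: 45
  max_age_years: 100
  travel_cost: 143           # per outpatient visit
  travel_cost_se: 12
  food_cost: 53              # per outpatient visit
  food_cost_se: 5
  visits_per_cycle: 1
  indirect_cost_per_cycle: 0 # productivity loss: declared but unpublished; default 0
  discount_timing: start
  terminal_failure: death    # exhausting the care sequence absorbs into death

mortality:
  mode: age_table
  age_table_file: life_table_synthetic.csv

# One-way sensitivity ranges. Published ranges are used where stated
# (utility of moderate pain, TKA cost); the remainder default to +/-20%
# of the base value, clamped to [0, 1] for probabilities.
dsa:
  - {param: utility.moderate_pain, low: 0.35, high: 0.77}
  - {param: state.tka.one_time_cost, low: 78533, high: 79316}
  - {param: state.glucosamine.cycle_cost, low: 1499.2, high: 2248.8}
  - {param: state.diclofenac_ppi.pain_relief_prob, low: 0.69176, high: 1.0}
  - {param: state.ta_injection.pain_relief_prob, low: 0.03136, high: 0.04704}
  - {param: state.tka.pain_relief_prob, low: 0.40976, high: 0.61464}

uncertainty:
  default_se_frac: 0.2   # parameters without a reported SE
  overrides: {}
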