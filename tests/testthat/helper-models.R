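# Small hand-specified models shared across tests.

# One terminal state, configurable relief/AEs/costs, constant mortality.
single_state_model <- function(pain_relief = 1, ae = NULL, cycle_cost = 0,
                               one_time_cost = 0, q = 0, rate = 0,
                               travel = 0, food = 0, utilities = NULL,
                               adverse_events = list(),
                               terminal_failure = "death",
                               ae_entry_only = FALSE) {
  oa_model(
    states = list(treatment_state("only", pain_relief_prob = pain_relief,
                                  ae_incidence = ae, cycle_cost = cycle_cost,
                                  one_time_cost = one_time_cost,
                                  is_terminal_treatment = TRUE,
                                  ae_entry_only = ae_entry_only)),
    strategies = list(solo = list(label = "single state",
                                  sequence = "only")),
    adverse_events = adverse_events,
    utilities = utilities %||% list(no_pain = 0.62, moderate_pain = 0.56),
    economics = list(annual_discount_rate = rate, travel_cost = travel,
                     food_cost = food, terminal_failure = terminal_failure),
    mortality = list(mode = "constant", per_cycle_death_prob = q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Published base-case (cost THB, QALY) pairs used by the frontier tests.
published_basecase_pairs <- function() {
  data.frame(
    strategy = c("standard", "glucosamine_before", "glucosamine_after",
                 "etoricoxib", "glucosamine_before_etoricoxib",
                 "glucosamine_after_etoricoxib"),
    cost = c(161282, 150878, 192561, 418268, 366819, 431478),
    qaly = c(2.39, 3.26, 3.26, 4.44, 4.98, 4.98),
    stringsAsFactors = FALSE)
}
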