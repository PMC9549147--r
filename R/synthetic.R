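# Synthetic model generator: random but structurally valid care-sequence
# models for property testing, plus the fixed hand-enumerable toy models
# used by the oracle tests.

#' Generate a random, structurally valid model
#'
#' Draws a care sequence of `n_states` treatment states with random
#' per-cycle pain-relief probabilities, adverse-event incidences, cost
#' schedules and utility pairs, a background-mortality schedule (constant
#' or a Gompertz-shaped age table capped at 1), and one or two strategies
#' over the sequence. Deterministic given `seed`; the result passes
#' [validate_model()] and round-trips through [write_model()] /
#' [load_model()].
#'
#' @param n_states Number of treatment states (2--8), last one terminal.
#' @param seed Integer seed.
#' @param mortality_mode `"constant"`, `"age_table"`, or `"random"`.
#' @param terminal_failure `"death"`, `"persist"`, or `"random"`.
#' @param no_ae Force all adverse-event incidences to zero (used by the
#'   closed-form oracle tests).
#' @param infeasible_se Deliberately give one adverse-event probability a
#'   standard error violating the beta moment condition
#'   (`se^2 < mean(1-mean)`), for negative tests of the sampling layer.
#' @return An `oa_model`.
#' @export
generate_model <- function(n_states = 4, seed = 1,
                           mortality_mode = c("random", "constant", "age_table"),
                           terminal_failure = c("random", "death", "persist"),
                           no_ae = FALSE, infeasible_se = FALSE) {
  stopifnot(n_states >= 2, n_states <= 8)
  mortality_mode <- match.arg(mortality_mode)
  terminal_failure <- match.arg(terminal_failure)
  set.seed(seed)
  if (mortality_mode == "random")
    mortality_mode <- sample(c("constant", "age_table"), 1)
  if (terminal_failure == "random")
    terminal_failure <- sample(c("death", "persist"), 1)
  nm <- paste0("treat_", seq_len(n_states))
  states <- lapply(seq_len(n_states), function(i) {
    terminal <- i == n_states
    inc <- if (no_ae) NULL else {
      x <- stats::runif(length(ae_kinds()), 0, 0.12)
      names(x) <- names(ae_kinds())
      x[stats::runif(length(x)) < 0.3] <- 0  # sparse risk profiles
      x
    }
    treatment_state(
      name = nm[i],
      pain_relief_prob = stats::runif(1, 0.05, 0.9),
      ae_incidence = inc,
      cycle_cost = round(stats::runif(1, 50, 8000), 2),
      one_time_cost = if (terminal) round(stats::runif(1, 0, 90000), 2) else 0,
      is_terminal_treatment = terminal,
      ae_entry_only = terminal && stats::runif(1) < 0.5)
  })
  ae <- lapply(names(ae_kinds()), function(k) {
    chronic <- ae_kinds()[[k]] == "chronic"
    list(acute_cost = round(stats::runif(1, 100, 60000), 2),
         first_year_cost = if (chronic) round(stats::runif(1, 100, 10000), 2) else 0,
         subsequent_year_cost = if (chronic) round(stats::runif(1, 100, 15000), 2) else 0,
         disutility = -round(stats::runif(1, 0.005, 0.08), 4),
         acute_cost_se = round(stats::runif(1, 10, 1500), 2),
         disutility_se = round(stats::runif(1, 1e-4, 1e-3), 6))
  })
  names(ae) <- names(ae_kinds())
  u_np <- round(stats::runif(1, 0.5, 0.9), 4)
  u_mp <- round(u_np - stats::runif(1, 0.01, 0.2), 4)
  strategies <- list(full = list(label = "all states", sequence = nm))
  if (n_states >= 3) {
    drop <- sample(seq_len(n_states - 1)[-1], 1)
    strategies$short <- list(label = "one state skipped", sequence = nm[-drop])
  }
  start_age <- 45
  mort <- if (mortality_mode == "constant") {
    list(mode = "constant",
         per_cycle_death_prob = round(stats::runif(1, 0.01, 0.2), 4))
  } else {
    bands <- seq(start_age, 110, by = 5)
    a <- stats::runif(1, 0.002, 0.01); b <- stats::runif(1, 0.06, 0.11)
    list(mode = "age_table",
         age_table = data.frame(
           age_from = bands,
           age_to = c(bands[-1], 120),
           annual_prob = round(pmin(a * exp(b * (bands + 2.5 - start_age)), 1), 5)))
  }
  ovr <- list()
  if (infeasible_se) {
    # pick a nonzero AE incidence and break the beta moment condition
    for (s in states) for (k in names(ae_kinds())) {
      p <- s$ae_incidence[[k]]
      if (p > 0 && p < 1) {
        ovr[[paste0("state.", s$name, ".ae.", k)]] <-
          list(se = 2 * sqrt(p * (1 - p)))
        break
      }
    }
    if (!length(ovr)) stop("no nonzero adverse-event incidence to break")
  }
  oa_model(
    states = states, strategies = strategies, adverse_events = ae,
    utilities = list(no_pain = u_np, moderate_pain = u_mp,
                     no_pain_se = round(stats::runif(1, 0.001, 0.02), 5),
                     moderate_pain_se = round(stats::runif(1, 0.001, 0.02), 5)),
    economics = list(annual_discount_rate = round(stats::runif(1, 0, 0.05), 3),
                     start_age_years = start_age, max_age_years = 100,
                     travel_cost = round(stats::runif(1, 0, 300), 2),
                     food_cost = round(stats::runif(1, 0, 100), 2),
                     terminal_failure = terminal_failure),
    mortality = mort,
    uncertainty = list(default_se_frac = round(stats::runif(1, 0.05, 0.3), 3),
                       overrides = ovr))
}

#' Fixed two-treatment toy model for the path-enumeration oracle
#'
#' A hand-checkable model used to cross-validate the cohort recursion
#' against exhaustive enumeration of individual trajectories over a few
#' cycles. All values are fixed and printed here: treatment `first` has
#' pain-relief probability 0.6, a per-cycle stroke incidence of 0.2 and a
#' cycle cost of 100; terminal treatment `last` has pain-relief
#' probability 0.3, no adverse events, cycle cost 50 and a one-time entry
#' cost of 500. Background mortality is a constant 0.1 per cycle;
#' utilities are 0.62 (no pain) / 0.56 (moderate pain); stroke costs
#' 1,000 acutely, 400 over the first year, 600 per subsequent year, with
#' disutility -0.05. Sequence exhaustion absorbs into death.
#'
#' @return An `oa_model`.
#' @export
toy_model_3cycle <- function() {
  oa_model(
    states = list(
      treatment_state("first", pain_relief_prob = 0.6,
                      ae_incidence = c(stroke = 0.2), cycle_cost = 100),
      treatment_state("last", pain_relief_prob = 0.3, cycle_cost = 50,
                      one_time_cost = 500, is_terminal_treatment = TRUE)),
    strategies = list(toy = list(label = "toy sequence",
                                 sequence = c("first", "last"))),
    adverse_events = list(stroke = list(acute_cost = 1000,
                                        first_year_cost = 400,
                                        subsequent_year_cost = 600,
                                        disutility = -0.05)),
    utilities = list(no_pain = 0.62, moderate_pain = 0.56),
    economics = list(annual_discount_rate = 0.03),
    mortality = list(mode = "constant", per_cycle_death_prob = 0.1))
}
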