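# Parameter schema: treatment states, adverse-event schedules, utilities,
# economic settings, mortality, strategy definitions.

#' Adverse-event kinds recognised by the model
#'
#' Five adverse events are tracked: gastrointestinal discomfort and
#' symptomatic ulcer resolve within the cycle of occurrence (transient);
#' stroke, myocardial infarction and heart failure are chronic conditions
#' that persist until death.
#'
#' @return Named character vector mapping event name to persistence
#'   (`"transient"` or `"chronic"`).
#' @export
ae_kinds <- function() {
  c(gi_discomfort = "transient",
    symptomatic_ulcer = "transient",
    stroke = "chronic",
    mi = "chronic",
    heart_failure = "chronic")
}

chronic_ae_kinds <- function() names(ae_kinds())[ae_kinds() == "chronic"]
transient_ae_kinds <- function() names(ae_kinds())[ae_kinds() == "transient"]

#' Construct a treatment state
#'
#' One rung of a care sequence: a per-cycle pain-relief probability,
#' per-cycle adverse-event incidences, a recurring per-cycle cost and an
#' optional one-time cost paid at state entry.
#'
#' @param name Identifier (no spaces).
#' @param pain_relief_prob Probability of pain relief per 6-month cycle;
#'   patients whose pain persists advance to the next state.
#' @param ae_incidence Named numeric vector of per-cycle adverse-event
#'   probabilities; names must be a subset of `names(ae_kinds())`.
#' @param cycle_cost Treatment cost per cycle while in the state (THB).
#' @param one_time_cost Cost paid once at state entry (THB), e.g. surgery.
#' @param is_terminal_treatment Logical; the last rung of every sequence.
#' @param ae_entry_only Logical; if `TRUE` adverse-event incidences apply
#'   only in the entry cycle (perioperative risks), not on every cycle.
#' @return An object of class `oa_state`.
#' @export
treatment_state <- function(name, pain_relief_prob, ae_incidence = NULL,
                            cycle_cost = 0, one_time_cost = 0,
                            is_terminal_treatment = FALSE,
                            ae_entry_only = FALSE) {
  inc <- stats::setNames(numeric(length(ae_kinds())), names(ae_kinds()))
  if (length(ae_incidence)) {
    bad <- setdiff(names(ae_incidence), names(ae_kinds()))
    if (length(bad))
      stop("unknown adverse-event kind in state '", name, "': ",
           paste(bad, collapse = ", "))
    inc[names(ae_incidence)] <- as.numeric(ae_incidence)
  }
  structure(list(name = name,
                 pain_relief_prob = as.numeric(pain_relief_prob),
                 ae_incidence = inc,
                 cycle_cost = as.numeric(cycle_cost),
                 one_time_cost = as.numeric(one_time_cost),
                 is_terminal_treatment = isTRUE(is_terminal_treatment),
                 ae_entry_only = isTRUE(ae_entry_only)),
            class = "oa_state")
}

ae_schedule <- function(kind, acute_cost, first_year_cost = 0,
                        subsequent_year_cost = 0, disutility = 0,
                        acute_cost_se = 0, first_year_cost_se = 0,
                        subsequent_year_cost_se = 0, disutility_se = 0) {
  list(kind = kind,
       persistence = unname(ae_kinds()[kind]),
       acute_cost = as.numeric(acute_cost),
       first_year_cost = as.numeric(first_year_cost),
       subsequent_year_cost = as.numeric(subsequent_year_cost),
       disutility = as.numeric(disutility),
       acute_cost_se = as.numeric(acute_cost_se),
       first_year_cost_se = as.numeric(first_year_cost_se),
       subsequent_year_cost_se = as.numeric(subsequent_year_cost_se),
       disutility_se = as.numeric(disutility_se))
}

default_economics <- function() {
  list(annual_discount_rate = 0.03,
       cycle_length_years = 0.5,
       wtp_per_qaly = 160000,
       fx_thb_per_usd = 36.16,
       start_age_years = 45,
       max_age_years = 100,
       travel_cost = 0, travel_cost_se = 0,
       food_cost = 0, food_cost_se = 0,
       visits_per_cycle = 1,
       indirect_cost_per_cycle = 0,
       discount_timing = "start",
       terminal_failure = "death")
}

#' Assemble a model specification
#'
#' Collects treatment states, adverse-event schedules, utilities, strategy
#' definitions, economic settings and a mortality schedule into a validated
#' model object.
#'
#' @param states List of [treatment_state()] objects.
#' @param strategies Named list; each element a list with `label` (display
#'   name) and `sequence` (character vector of state names, terminal state
#'   last).
#' @param adverse_events Named list of adverse-event schedules (see the
#'   packaged fixture for the fields); missing kinds get zero-cost defaults.
#' @param utilities List with `no_pain`, `moderate_pain` and their `_se`s.
#' @param economics List overriding the defaults (3% annual discount,
#'   6-month cycles, WTP 160,000 THB/QALY, 36.16 THB/USD, ages 45--100).
#' @param mortality List with `mode` (`"constant"` or `"age_table"`) and
#'   either `per_cycle_death_prob` or `age_table` (data.frame with columns
#'   `age_from`, `age_to`, `annual_prob`).
#' @param uncertainty List with `default_se_frac` (standard error assumed
#'   for parameters without a reported one, as a fraction of the mean) and
#'   optional per-parameter `overrides`.
#' @param dsa Optional list of one-way sensitivity ranges, each a list with
#'   `param`, `low`, `high`.
#' @param validate Run [validate_model()] before returning.
#' @return An object of class `oa_model`.
#' @export
oa_model <- function(states, strategies, adverse_events = list(),
                     utilities = list(no_pain = 0.62, moderate_pain = 0.56,
                                      no_pain_se = 0, moderate_pain_se = 0),
                     economics = list(), mortality = list(mode = "constant",
                                                          per_cycle_death_prob = 0),
                     uncertainty = list(default_se_frac = 0.2, overrides = list()),
                     dsa = list(), validate = TRUE) {
  st <- stats::setNames(states, vapply(states, `[[`, "", "name"))
  ae <- stats::setNames(vector("list", length(ae_kinds())), names(ae_kinds()))
  for (k in names(ae_kinds())) {
    ae[[k]] <- if (!is.null(adverse_events[[k]])) {
      do.call(ae_schedule, c(list(kind = k),
                             adverse_events[[k]][setdiff(names(adverse_events[[k]]),
                                                         c("kind", "persistence"))]))
    } else ae_schedule(k, acute_cost = 0)
  }
  econ <- utils::modifyList(default_economics(), economics)
  if (is.null(utilities$no_pain_se)) utilities$no_pain_se <- 0
  if (is.null(utilities$moderate_pain_se)) utilities$moderate_pain_se <- 0
  if (is.null(uncertainty$default_se_frac)) uncertainty$default_se_frac <- 0.2
  if (is.null(uncertainty$overrides)) uncertainty$overrides <- list()
  m <- structure(list(states = st, strategies = strategies,
                      adverse_events = ae, utilities = utilities,
                      economics = econ, mortality = mortality,
                      uncertainty = uncertainty, dsa = dsa),
                 class = "oa_model")
  if (validate) validate_model(m)
  m
}

#' Per-cycle outpatient visit cost
#'
#' Travel plus food cost per visit, times visits per cycle.
#' @param model An `oa_model`.
#' @return Cost in THB per cycle.
#' @export
visit_cost_per_cycle <- function(model) {
  e <- model$economics
  (e$travel_cost + e$food_cost) * e$visits_per_cycle
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("validation error: ", what, " must be a probability in [0, 1] (got ",
         paste(signif(x, 6), collapse = ", "), ")")
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("validation error: ", what, " must be >= 0")
  invisible(x)
}

#' Validate a model specification
#'
#' Checks every probability, cost, utility and schedule invariant and the
#' internal consistency of strategies against the state registry. Called by
#' [load_model()] and [oa_model()].
#'
#' @param model An `oa_model`.
#' @return The model, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  if (!length(model$states)) stop("schema error: field 'states' is empty")
  for (s in model$states) {
    check_prob(s$pain_relief_prob, paste0("states.", s$name, ".pain_relief_prob"))
    for (k in names(s$ae_incidence))
      check_prob(s$ae_incidence[[k]], paste0("states.", s$name, ".ae.", k))
    check_nonneg(s$cycle_cost, paste0("states.", s$name, ".cycle_cost"))
    check_nonneg(s$one_time_cost, paste0("states.", s$name, ".one_time_cost"))
  }
  term <- vapply(model$states, `[[`, FALSE, "is_terminal_treatment")
  if (!any(term)) stop("schema error: no state has is_terminal_treatment = true")
  for (k in names(ae_kinds())) {
    a <- model$adverse_events[[k]]
    if (is.null(a)) stop("schema error: missing adverse_events entry '", k, "'")
    check_nonneg(c(a$acute_cost, a$first_year_cost, a$subsequent_year_cost),
                 paste0("adverse_events.", k, " costs"))
    if (a$disutility > 0 || a$disutility < -1)
      stop("validation error: adverse_events.", k, ".disutility must lie in [-1, 0]")
    if (ae_kinds()[[k]] == "transient" &&
        (a$first_year_cost != 0 || a$subsequent_year_cost != 0))
      stop("validation error: transient event '", k,
           "' cannot carry first-year/subsequent-year costs")
  }
  u <- model$utilities
  if (is.null(u$no_pain) || is.null(u$moderate_pain))
    stop("schema error: utilities must define 'no_pain' and 'moderate_pain'")
  check_prob(c(u$no_pain, u$moderate_pain), "utilities")
  if (u$moderate_pain > u$no_pain)
    stop("validation error: utilities.moderate_pain must not exceed utilities.no_pain")
  e <- model$economics
  check_nonneg(e$annual_discount_rate, "economics.annual_discount_rate")
  if (e$cycle_length_years <= 0) stop("validation error: economics.cycle_length_years must be > 0")
  if (e$fx_thb_per_usd <= 0) stop("validation error: economics.fx_thb_per_usd must be > 0")
  if (!e$discount_timing %in% c("start", "mid"))
    stop("validation error: economics.discount_timing must be 'start' or 'mid'")
  if (!e$terminal_failure %in% c("death", "persist"))
    stop("validation error: economics.terminal_failure must be 'death' or 'persist'")
  validate_mortality(model)
  if (!length(model$strategies)) stop("schema error: field 'strategies' is empty")
  for (nm in names(model$strategies)) {
    sq <- model$strategies[[nm]]$sequence
    ok <- validate_strategy(sq, model$states)
    if (!isTRUE(ok)) stop("strategy '", nm, "': ", ok)
  }
  invisible(model)
}

validate_mortality <- function(model) {
  mt <- model$mortality
  if (identical(mt$mode, "constant")) {
    check_prob(mt$per_cycle_death_prob, "mortality.per_cycle_death_prob")
  } else if (identical(mt$mode, "age_table")) {
    tab <- mt$age_table
    if (is.null(tab) || !all(c("age_from", "age_to", "annual_prob") %in% names(tab)))
      stop("schema error: mortality.age_table needs columns age_from, age_to, annual_prob")
    tab <- tab[order(tab$age_from), ]
    check_prob(tab$annual_prob, "mortality.age_table.annual_prob")
    if (any(tab$age_to <= tab$age_from))
      stop("validation error: mortality age bands must have age_to > age_from")
    if (nrow(tab) > 1 && any(abs(tab$age_from[-1] - tab$age_to[-nrow(tab)]) > 1e-9))
      stop("validation error: mortality age bands must be contiguous and non-overlapping")
    e <- model$economics
    if (e$start_age_years < min(tab$age_from) || e$max_age_years > max(tab$age_to))
      stop("validation error: mortality.age_table does not cover ages ",
           e$start_age_years, "..", e$max_age_years)
  } else stop("schema error: mortality.mode must be 'constant' or 'age_table'")
  invisible(model)
}

#' Validate a care-sequence definition
#'
#' Confirms that the sequence is non-empty, has no repeats, references only
#' known states, and places the terminal treatment (and nothing else
#' terminal) last.
#'
#' @param sequence Character vector of state names in care order.
#' @param states Named list of `oa_state` objects (the state registry).
#' @return `TRUE` if valid, otherwise a character string describing the
#'   first problem found.
#' @export
validate_strategy <- function(sequence, states) {
  if (!length(sequence)) return("sequence is empty")
  unknown <- setdiff(sequence, names(states))
  if (length(unknown))
    return(paste0("reference error: unknown state(s) ",
                  paste(unknown, collapse = ", ")))
  if (anyDuplicated(sequence)) {
    d <- sequence[duplicated(sequence)][1]
    return(paste0("duplicate state '", d, "' at position ",
                  which(sequence == d)[2]))
  }
  last <- sequence[length(sequence)]
  if (!states[[last]]$is_terminal_treatment)
    return(paste0("last state '", last, "' is not the terminal treatment"))
  mid_term <- sequence[-length(sequence)][vapply(sequence[-length(sequence)],
                                                 function(s) states[[s]]$is_terminal_treatment,
                                                 FALSE)]
  if (length(mid_term))
    return(paste0("terminal treatment '", mid_term[1],
                  "' must be the last entry"))
  TRUE
}

#' Load a model configuration from YAML
#'
#' Reads one YAML document with sections `states`, `strategies`,
#' `adverse_events`, `utilities`, `economics`, `mortality`, `uncertainty`
#' and optional `dsa`, resolves any external mortality table (path relative
#' to the YAML file), and validates the result. All money is in THB.
#'
#' @param path Path to the YAML configuration.
#' @return A validated `oa_model`.
#' @seealso [example_model()] for the packaged Thai knee-OA fixture.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (f in c("states", "strategies")) {
    if (is.null(cfg[[f]])) stop("schema error: missing field '", f, "'")
  }
  states <- lapply(names(cfg$states), function(nm) {
    s <- cfg$states[[nm]]
    if (is.null(s$pain_relief_prob))
      stop("schema error: states.", nm, " missing field 'pain_relief_prob'")
    treatment_state(name = nm,
                    pain_relief_prob = s$pain_relief_prob,
                    ae_incidence = unlist(s$ae),
                    cycle_cost = s$cycle_cost %||% 0,
                    one_time_cost = s$one_time_cost %||% 0,
                    is_terminal_treatment = s$is_terminal_treatment %||% FALSE,
                    ae_entry_only = s$ae_entry_only %||% FALSE)
  })
  strategies <- lapply(cfg$strategies, function(x) {
    if (is.null(x$sequence)) stop("schema error: strategy missing field 'sequence'")
    list(label = x$label %||% NA_character_,
         sequence = as.character(unlist(x$sequence)))
  })
  mort <- cfg$mortality %||% list(mode = "constant", per_cycle_death_prob = 0)
  if (identical(mort$mode, "age_table")) {
    if (!is.null(mort$age_table_file)) {
      f <- file.path(dirname(path), mort$age_table_file)
      if (!file.exists(f)) stop("mortality age_table_file not found: ", f)
      mort$age_table <- utils::read.csv(f)
      mort$age_table_file <- NULL
    } else if (!is.null(mort$age_table)) {
      mort$age_table <- do.call(rbind.data.frame, mort$age_table)
    }
  }
  oa_model(states = states, strategies = strategies,
           adverse_events = cfg$adverse_events %||% list(),
           utilities = cfg$utilities %||% list(no_pain = 0.62, moderate_pain = 0.56),
           economics = cfg$economics %||% list(),
           mortality = mort,
           uncertainty = cfg$uncertainty %||% list(default_se_frac = 0.2),
           dsa = cfg$dsa %||% list())
}

#' Write a model configuration to YAML
#'
#' Inverse of [load_model()]: the written file reloads to an equivalent
#' model (field-by-field). The mortality age table is inlined.
#'
#' @param model An `oa_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cfg <- list(
    states = lapply(model$states, function(s)
      list(pain_relief_prob = s$pain_relief_prob,
           ae = as.list(s$ae_incidence),
           cycle_cost = s$cycle_cost,
           one_time_cost = s$one_time_cost,
           is_terminal_treatment = s$is_terminal_treatment,
           ae_entry_only = s$ae_entry_only)),
    strategies = lapply(model$strategies, function(x)
      list(label = if (is.na(x$label)) NULL else x$label,
           sequence = as.list(x$sequence))),
    adverse_events = lapply(model$adverse_events, function(a)
      a[setdiff(names(a), c("kind", "persistence"))]),
    utilities = model$utilities,
    economics = model$economics,
    mortality = local({
      mt <- model$mortality
      if (!is.null(mt$age_table))
        mt$age_table <- lapply(seq_len(nrow(mt$age_table)), function(i)
          as.list(mt$age_table[i, c("age_from", "age_to", "annual_prob")]))
      mt
    }),
    uncertainty = model$uncertainty,
    dsa = model$dsa)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Packaged Thai knee-osteoarthritis model fixture
#'
#' Loads the base-case configuration shipped with the package: per-cycle
#' pain-relief and adverse-event probabilities, treatment and adverse-event
#' cost schedules with standard errors, utilities for controlled and
#' uncontrolled pain, the six care-sequence strategies, and Thai economic
#' settings (3% discounting, 6-month cycles, WTP 160,000 THB/QALY,
#' 36.16 THB/USD). The background-mortality life table is synthetic (the
#' one model input with no published source value).
#'
#' @return A validated `oa_model`.
#' @export
example_model <- function() {
  load_model(system.file("extdata", "thailand_oa_2022.yaml",
                         package = "oacua", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.oa_model <- function(x, ...) {
  cat("<oa_model>\n")
  cat("  states:    ", paste(names(x$states), collapse = ", "), "\n")
  cat("  strategies:", paste(names(x$strategies), collapse = ", "), "\n")
  cat(sprintf("  economics: %.0f%% annual discount, %g-year cycles, ages %g-%g\n",
              100 * x$economics$annual_discount_rate,
              x$economics$cycle_length_years,
              x$economics$start_age_years, x$economics$max_age_years))
  cat("  mortality: ", x$mortality$mode, "\n")
  invisible(x)
}
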