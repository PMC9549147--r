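test_that("packaged fixture reproduces the published inputs exactly", {
  m <- example_model()
  s <- m$states
  # per-cycle pain-relief probabilities
  expect_identical(s$acetaminophen$pain_relief_prob, 0.3380)
  expect_identical(s$diclofenac_ppi$pain_relief_prob, 0.8647)
  expect_identical(s$etoricoxib$pain_relief_prob, 0.5657)
  expect_identical(s$glucosamine$pain_relief_prob, 0.3857)
  expect_identical(s$ta_injection$pain_relief_prob, 0.0392)
  expect_identical(s$tka$pain_relief_prob, 0.5122)
  # adverse-event incidences (spot rows)
  expect_identical(unname(s$acetaminophen$ae_incidence[c("gi_discomfort",
    "symptomatic_ulcer", "stroke", "mi", "heart_failure")]),
    c(0.2382, 0.0007, 0.0005, 0.0013, 0))
  expect_identical(unname(s$diclofenac_ppi$ae_incidence[c("stroke", "mi")]),
                   c(0.1012, 0.2289))
  expect_identical(unname(s$tka$ae_incidence[c("symptomatic_ulcer", "mi",
                                               "heart_failure")]),
                   c(0.0899, 0.0469, 0.0100))
  # treatment costs per cycle; TA is two 3-monthly injections of 114
  expect_identical(s$acetaminophen$cycle_cost, 213)
  expect_identical(s$diclofenac_ppi$cycle_cost, 222)  # 128 diclofenac + 94 PPI
  expect_identical(s$etoricoxib$cycle_cost, 5213)
  expect_identical(s$glucosamine$cycle_cost, 1874)
  expect_identical(s$ta_injection$cycle_cost, 2 * 114)
  expect_identical(s$tka$one_time_cost, 78925)
  expect_true(s$tka$is_terminal_treatment)
  # adverse-event cost schedules and standard errors
  ae <- m$adverse_events
  expect_identical(c(ae$gi_discomfort$acute_cost, ae$gi_discomfort$acute_cost_se),
                   c(436, 11))
  expect_identical(c(ae$symptomatic_ulcer$acute_cost,
                     ae$symptomatic_ulcer$acute_cost_se), c(3734, 95))
  expect_identical(c(ae$stroke$acute_cost, ae$stroke$first_year_cost,
                     ae$stroke$subsequent_year_cost), c(56133, 7173, 10029))
  expect_identical(c(ae$mi$acute_cost, ae$mi$first_year_cost,
                     ae$mi$subsequent_year_cost), c(138916, 4706, 13588))
  expect_identical(c(ae$heart_failure$acute_cost, ae$heart_failure$first_year_cost,
                     ae$heart_failure$subsequent_year_cost),
                   c(15347, 3974, 7948))
  expect_identical(vapply(ae, `[[`, 0, "disutility"),
                   c(gi_discomfort = -0.0228, symptomatic_ulcer = -0.0269,
                     stroke = -0.0524, mi = -0.0409, heart_failure = -0.0635))
  # utilities and economic settings
  expect_identical(c(m$utilities$no_pain, m$utilities$moderate_pain),
                   c(0.62, 0.56))
  expect_identical(c(m$utilities$no_pain_se, m$utilities$moderate_pain_se),
                   c(0.0036, 0.0152))
  e <- m$economics
  expect_equal(c(e$annual_discount_rate, e$cycle_length_years,
                 e$wtp_per_qaly, e$fx_thb_per_usd, e$start_age_years),
               c(0.03, 0.5, 160000, 36.16, 45))
  expect_equal(c(e$travel_cost, e$food_cost), c(143, 53))
  expect_equal(visit_cost_per_cycle(m), 196)
  # six strategies, standard care order, terminal treatment always last
  expect_length(m$strategies, 6)
  expect_identical(m$strategies$standard$sequence,
                   c("acetaminophen", "diclofenac_ppi", "ta_injection", "tka"))
  expect_true(all(vapply(m$strategies, function(x)
    utils::tail(x$sequence, 1) == "tka", TRUE)))
})

test_that("transient and chronic adverse-event kinds are fixed", {
  k <- ae_kinds()
  expect_identical(unname(k[c("gi_discomfort", "symptomatic_ulcer")]),
                   c("transient", "transient"))
  expect_identical(unname(k[c("stroke", "mi", "heart_failure")]),
                   c("chronic", "chronic", "chronic"))
})

test_that("validation rejects out-of-range and inconsistent configs", {
  base <- single_state_model()
  # probability outside [0, 1], named in the error
  expect_error(single_state_model(pain_relief = 1.2), "pain_relief_prob")
  expect_error(single_state_model(ae = c(stroke = -0.1)), "ae.stroke")
  expect_error(single_state_model(cycle_cost = -5), "cycle_cost")
  # transient events cannot carry long-run costs
  expect_error(
    single_state_model(adverse_events = list(
      gi_discomfort = list(acute_cost = 100, first_year_cost = 50))),
    "transient")
  # utility ordering
  expect_error(
    single_state_model(utilities = list(no_pain = 0.5, moderate_pain = 0.6)),
    "moderate_pain")
  # disutility must be a decrement
  expect_error(
    single_state_model(adverse_events = list(stroke = list(acute_cost = 1,
                                                           disutility = 0.2))),
    "disutility")
  # mortality table must cover the horizon
  expect_error(oa_model(
    states = list(treatment_state("x", 0.5, is_terminal_treatment = TRUE)),
    strategies = list(s = list(label = "s", sequence = "x")),
    mortality = list(mode = "age_table",
                     age_table = data.frame(age_from = 45, age_to = 60,
                                            annual_prob = 0.01))),
    "does not cover")
  expect_silent(validate_model(base))
})

test_that("strategy validation flags duplicates, gaps and unknown states", {
  m <- example_model()
  expect_true(validate_strategy(
    c("acetaminophen", "diclofenac_ppi", "ta_injection", "tka"), m$states))
  err <- validate_strategy(c("acetaminophen", "acetaminophen", "tka"), m$states)
  expect_match(err, "duplicate state 'acetaminophen' at position 2")
  expect_match(validate_strategy(c("glucosamine_sulphate", "tka"), m$states),
               "unknown state")
  expect_match(validate_strategy(character(), m$states), "empty")
  expect_match(validate_strategy(c("acetaminophen", "glucosamine"), m$states),
               "not the terminal treatment")
  expect_match(validate_strategy(c("tka", "acetaminophen", "tka"), m$states),
               "duplicate|last")
})

test_that("load_model reports missing fields and broken references", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.yaml")
  writeLines(c("states:", "  a:", "    cycle_cost: 1",
               "strategies:", "  s: {sequence: [a]}"), f)
  expect_error(load_model(f), "pain_relief_prob")
  writeLines("states: {}", f)
  expect_error(load_model(f), "strategies")
  writeLines(c("states:",
               "  a: {pain_relief_prob: 0.5, is_terminal_treatment: true}",
               "strategies:",
               "  s: {sequence: [a, ghost]}"), f)
  expect_error(load_model(f), "unknown state")
  expect_error(load_model(file.path(dir, "missing.yaml")), "not found")
})

test_that("models round-trip through the YAML writer unchanged", {
  for (m in list(example_model(), generate_model(3, seed = 7),
                 generate_model(5, seed = 11))) {
    f <- withr::local_tempfile(fileext = ".yaml")
    write_model(m, f)
    m2 <- load_model(f)
    expect_equal(m2$states, m$states, tolerance = 1e-12)
    expect_equal(m2$adverse_events, m$adverse_events, tolerance = 1e-12)
    expect_equal(m2$utilities, m$utilities, tolerance = 1e-12)
    expect_equal(m2$economics, m$economics, tolerance = 1e-12)
    expect_equal(lapply(m2$strategies, `[[`, "sequence"),
                 lapply(m$strategies, `[[`, "sequence"))
    if (m$mortality$mode == "age_table")
      expect_equal(m2$mortality$age_table$annual_prob,
                   m$mortality$age_table$annual_prob, tolerance = 1e-12)
    else
      expect_equal(m2$mortality$per_cycle_death_prob,
                   m$mortality$per_cycle_death_prob)
  }
})

test_that("distribution family assignment is total and follows the class rule", {
  tab <- build_param_table(example_model())
  expect_true(all(tab$family %in% c("gamma", "beta", "lognormal", "fixed")))
  expect_true(all(tab$family[tab$class == "cost" & tab$mean > 0] == "gamma"))
  expect_true(all(tab$family[tab$class == "transition"] == "lognormal"))
  expect_true(all(tab$family[tab$class %in% c("probability", "utility") &
                               tab$mean > 0] == "beta"))
  expect_true(all(tab$family[tab$mean == 0] == "fixed"))
  # printed standard errors are picked up; unreported ones default to 20%
  expect_equal(tab$se[tab$id == "ae_cost.stroke.acute"], 1432)
  expect_equal(tab$se[tab$id == "utility.moderate_pain"], 0.0152)
  expect_equal(tab$se[tab$id == "state.acetaminophen.cycle_cost"], 0.2 * 213)
  # configured one-way ranges override the defaults
  expect_equal(unlist(tab[tab$id == "utility.moderate_pain",
                          c("dsa_low", "dsa_high")], use.names = FALSE),
               c(0.35, 0.77))
  expect_equal(unlist(tab[tab$id == "state.tka.one_time_cost",
                          c("dsa_low", "dsa_high")], use.names = FALSE),
               c(78533, 79316))
})
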