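# Independent oracles used to cross-validate the cohort engine and the
# accrual arithmetic. These deliberately avoid the package's matrix
# machinery: trajectories are enumerated as explicit branching
# distributions over individual-level states, and small chains are summed
# in closed form.

# Exhaustive enumeration of individual trajectories. Represents the cohort
# as a table of individual states (treatment index, stage, chronic
# condition and its phase) and branches every cycle over death, chronic
# onset, phase ageing and treatment progression.
enumerate_trace <- function(model, strategy_name, n_cycles) {
  sq <- model$strategies[[strategy_name]]$sequence
  K <- length(sq)
  chronic <- c("stroke", "mi", "heart_failure")
  term_mode <- model$economics$terminal_failure
  stage0 <- function(i) if (model$states[[sq[i]]]$ae_entry_only) "entry" else "active"
  pop <- data.frame(i = 1L, stage = stage0(1L), type = "none", phase = 0L,
                    prob = 1, stringsAsFactors = FALSE)
  dead <- 0
  lab <- function(p) ifelse(p$type == "none",
                            paste(sq[p$i], p$stage, "none", sep = "."),
                            paste(sq[p$i], p$stage,
                                  paste0(p$type, p$phase), sep = "."))
  snapshot <- function() {
    agg <- stats::aggregate(prob ~ l, data.frame(l = lab(pop), prob = pop$prob),
                            sum)
    out <- stats::setNames(agg$prob, agg$l)
    c(out, death = dead)
  }
  rows <- list(snapshot())
  for (t in seq_len(n_cycles)) {
    age <- model$economics$start_age_years +
      (t - 1) * model$economics$cycle_length_years
    q <- mortality_per_cycle(model, age)
    nxt <- list()
    emit <- function(i, stage, type, phase, prob) {
      if (prob > 0)
        nxt[[length(nxt) + 1L]] <<- data.frame(i = i, stage = stage,
                                               type = type, phase = phase,
                                               prob = prob,
                                               stringsAsFactors = FALSE)
    }
    for (r in seq_len(nrow(pop))) {
      p <- pop[r, ]
      dead <- dead + p$prob * q
      alive <- p$prob * (1 - q)
      if (alive == 0) next
      # chronic-condition branches
      if (p$type == "none" && p$stage %in% c("active", "entry")) {
        inc <- model$states[[sq[p$i]]]$ae_incidence[chronic]
        if (sum(inc) > 1) inc <- inc / sum(inc)
        ae_branch <- rbind(data.frame(type = "none", phase = 0L,
                                      w = 1 - sum(inc)),
                          data.frame(type = chronic, phase = 1L,
                                     w = unname(inc)))
      } else if (p$type == "none") {
        ae_branch <- data.frame(type = "none", phase = 0L, w = 1)
      } else {
        ae_branch <- data.frame(type = p$type, phase = min(p$phase + 1L, 4L),
                                w = 1)
      }
      for (ab in seq_len(nrow(ae_branch))) {
        w <- alive * ae_branch$w[ab]
        if (w == 0) next
        ty <- ae_branch$type[ab]; ph <- ae_branch$phase[ab]
        if (p$stage == "failed") {
          emit(p$i, "failed", ty, ph, w)
        } else {
          pr <- model$states[[sq[p$i]]]$pain_relief_prob
          stay_stage <- if (p$stage == "entry") "post" else p$stage
          emit(p$i, stay_stage, ty, ph, w * pr)
          if (p$i < K) {
            emit(p$i + 1L, stage0(p$i + 1L), ty, ph, w * (1 - pr))
          } else if (term_mode == "persist") {
            emit(p$i, "failed", ty, ph, w * (1 - pr))
          } else {
            dead <- dead + w * (1 - pr)
          }
        }
      }
    }
    pop <- do.call(rbind, nxt)
    pop <- stats::aggregate(prob ~ i + stage + type + phase, pop, sum)
    rows[[t + 1L]] <- snapshot()
  }
  rows
}

# Compare an enumerated trace with a run_cohort occupancy matrix.
expect_trace_matches_enumeration <- function(model, strategy, n_cycles,
                                             tol = 1e-12) {
  tr <- run_cohort(model, strategy, max_cycles = n_cycles, tol_alive = 0)
  en <- enumerate_trace(model, strategy, n_cycles)
  for (t in seq_len(n_cycles + 1L)) {
    got <- tr$occupancy[t, ]
    want <- en[[t]]
    for (nm in names(want))
      expect_equal(unname(got[[nm]]), unname(want[[nm]]), tolerance = tol,
                   info = paste("cycle", t - 1L, "compartment", nm))
    expect_equal(sum(got[setdiff(names(got), names(want))]), 0,
                 tolerance = tol)
  }
  invisible(tr)
}

# Closed-form discounted totals for a two-state, no-adverse-event chain
# with constant background mortality and sequence exhaustion into death:
# occupancy of the first state is a^t, of the second f (a^t - b^t)/(a - b),
# and all accrual streams are geometric series summed to infinity.
two_state_closed_form <- function(model) {
  sq <- model$strategies$full$sequence
  stopifnot(length(sq) == 2, model$mortality$mode == "constant",
            model$economics$terminal_failure == "death")
  s1 <- model$states[[sq[1]]]; s2 <- model$states[[sq[2]]]
  stopifnot(!s2$ae_entry_only)
  e <- model$economics
  q <- model$mortality$per_cycle_death_prob
  d <- (1 + e$annual_discount_rate)^(-e$cycle_length_years)
  a <- (1 - q) * s1$pain_relief_prob
  f <- (1 - q) * (1 - s1$pain_relief_prob)
  b <- (1 - q) * s2$pain_relief_prob
  stopifnot(abs(a - b) > 1e-9)
  v <- visit_cost_per_cycle(model) + e$indirect_cost_per_cycle
  u <- model$utilities
  u1 <- s1$pain_relief_prob * u$no_pain + (1 - s1$pain_relief_prob) * u$moderate_pain
  u2 <- s2$pain_relief_prob * u$no_pain + (1 - s2$pain_relief_prob) * u$moderate_pain
  geom <- function(disc) {
    SA <- 1 / (1 - a * disc)
    SB <- f / (a - b) * (a * disc / (1 - a * disc) - b * disc / (1 - b * disc))
    SE <- disc * f / (1 - a * disc)
    list(cost = (s1$cycle_cost + v) * SA + (s2$cycle_cost + v) * SB +
           s2$one_time_cost * SE,
         qaly = e$cycle_length_years * (u1 * SA + u2 * SB))
  }
  list(disc = geom(d), undisc = geom(1))
}

# Brute-force extended-dominance check: a point is on the efficiency
# frontier iff it lies on the lower-left convex hull of the undominated
# (qaly, cost) set, tested by pairwise-segment membership.
hull_frontier_strategies <- function(df) {
  keep <- vapply(seq_len(nrow(df)), function(j) {
    !any(df$cost <= df$cost[j] & df$qaly >= df$qaly[j] &
           (df$cost < df$cost[j] | df$qaly > df$qaly[j]))
  }, TRUE)
  und <- df[keep, ]
  und <- und[order(und$qaly), ]
  on_hull <- vapply(seq_len(nrow(und)), function(j) {
    below <- und[und$qaly < und$qaly[j], ]
    above <- und[und$qaly > und$qaly[j], ]
    if (!nrow(below) || !nrow(above)) return(TRUE)
    # j is extendedly dominated if some chord (l, r) passes below it
    for (l in seq_len(nrow(below))) for (r in seq_len(nrow(above))) {
      w <- (und$qaly[j] - below$qaly[l]) / (above$qaly[r] - below$qaly[l])
      chord <- below$cost[l] + w * (above$cost[r] - below$cost[l])
      if (chord < und$cost[j] - 1e-9) return(FALSE)
    }
    TRUE
  }, TRUE)
  und$strategy[on_hull]
}
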