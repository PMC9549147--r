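# Markov cohort engine: compartment enumeration, per-cycle transition
# structure, and the cohort recursion to the absorbing death state.

# Chronic conditions are tracked as substates with a condition-phase counter:
# phase 1 = the first cycle with the condition (acute-care costs), phases
# 2-3 = the two first-year half-cycles, phase 4 = maintenance thereafter.
N_AE_PHASES <- 4L

#' Per-cycle probability of advancing to the next treatment
#'
#' Treatment failure is the persistence of pain, so the progression
#' probability is the complement of the per-cycle pain-relief probability.
#'
#' @param state An `oa_state`.
#' @return Probability per cycle.
#' @export
progression_prob <- function(state) {
  check_prob(state$pain_relief_prob, "pain_relief_prob")
  1 - state$pain_relief_prob
}

ae_substates <- function() {
  data.frame(
    ae_type = c("none", rep(chronic_ae_kinds(), each = N_AE_PHASES)),
    ae_phase = c(0L, rep(seq_len(N_AE_PHASES), times = length(chronic_ae_kinds()))),
    stringsAsFactors = FALSE)
}

#' Enumerate the live compartments of a strategy
#'
#' Each treatment state is crossed with a chronic-condition substate
#' (none, or one of the chronic adverse events with a condition-phase
#' counter). States whose adverse events are perioperative
#' (`ae_entry_only`) are split into an entry stage and a post stage; in
#' `terminal_failure = "persist"` mode the last state additionally gets an
#' absorbing failed (uncontrolled pain) stage.
#'
#' @param sequence Character vector of state names.
#' @param model An `oa_model`.
#' @return Data frame with columns `state`, `state_index`, `stage`,
#'   `ae_type`, `ae_phase`, `label`; the death compartment is implicit
#'   (appended as the last column of transition matrices and traces).
#' @export
compartment_table <- function(sequence, model) {
  subs <- ae_substates()
  rows <- list()
  K <- length(sequence)
  for (i in seq_len(K)) {
    s <- model$states[[sequence[i]]]
    stages <- if (s$ae_entry_only) c("entry", "post") else "active"
    if (i == K && model$economics$terminal_failure == "persist")
      stages <- c(stages, "failed")
    for (stg in stages) {
      d <- subs
      d$state <- s$name; d$state_index <- i; d$stage <- stg
      rows[[length(rows) + 1L]] <- d
    }
  }
  comps <- do.call(rbind, rows)
  comps <- comps[, c("state", "state_index", "stage", "ae_type", "ae_phase")]
  comps$label <- ifelse(comps$ae_type == "none",
                        paste(comps$state, comps$stage, "none", sep = "."),
                        paste(comps$state, comps$stage,
                              paste0(comps$ae_type, comps$ae_phase), sep = "."))
  rownames(comps) <- NULL
  comps
}

entry_stage <- function(state) if (state$ae_entry_only) "entry" else "active"

# Chronic-event incidences that apply to a compartment this cycle: only
# unaffected (ae_type == "none") occupants of an at-risk stage can have a
# first chronic event; subsequent events are not modelled.
chronic_onset_probs <- function(comp_row, model) {
  if (comp_row$ae_type != "none" || !comp_row$stage %in% c("active", "entry"))
    return(stats::setNames(numeric(length(chronic_ae_kinds())), chronic_ae_kinds()))
  inc <- model$states[[comp_row$state]]$ae_incidence[chronic_ae_kinds()]
  tot <- sum(inc)
  if (tot > 1) inc <- inc / tot  # proportional allocation of competing risks
  inc
}

# Transition structure conditional on surviving background mortality:
# a (n+1) x (n+1) row-stochastic matrix over live compartments plus death.
# Death here receives only care-sequence exhaustion (terminal failure in
# "death" mode); background mortality is layered on per cycle.
# (Kept free of per-row data-frame allocation: this is rebuilt for every
# Monte-Carlo draw of the probabilistic sensitivity analysis.)
survivor_matrix <- function(sequence, model, comps = NULL) {
  if (is.null(comps)) comps <- compartment_table(sequence, model)
  n <- nrow(comps)
  death <- n + 1L
  idx <- new.env(parent = emptyenv(), size = n)
  for (r in seq_len(n)) assign(comps$label[r], r, envir = idx)
  K <- length(sequence)
  A <- matrix(0, death, death,
              dimnames = list(c(comps$label, "death"), c(comps$label, "death")))
  A[death, death] <- 1
  persist <- model$economics$terminal_failure == "persist"
  lab <- function(state, stage, type, phase) {
    if (type == "none") paste(state, stage, "none", sep = ".")
    else paste0(state, ".", stage, ".", type, phase)
  }
  states <- model$states
  next_state <- c(sequence[-1], NA)
  for (r in seq_len(n)) {
    c_state <- comps$state[r]; c_stage <- comps$stage[r]
    c_type <- comps$ae_type[r]; c_i <- comps$state_index[r]
    # chronic-condition evolution: (type, phase) outcomes with weights
    if (c_type == "none") {
      onset <- if (c_stage %in% c("active", "entry")) {
        inc <- states[[c_state]]$ae_incidence[chronic_ae_kinds()]
        if (sum(inc) > 1) inc / sum(inc) else inc
      } else stats::setNames(numeric(length(chronic_ae_kinds())),
                             chronic_ae_kinds())
      keep <- onset > 0
      ae_type <- c("none", names(onset)[keep])
      ae_phase <- c(0L, rep(1L, sum(keep)))
      ae_p <- c(1 - sum(onset), unname(onset[keep]))
    } else {
      ae_type <- c_type
      ae_phase <- min(comps$ae_phase[r] + 1L, N_AE_PHASES)
      ae_p <- 1
    }
    # treatment progression: (target stage/state, weight)
    if (c_stage == "failed") {
      tgt_kind <- "self"; tgt_p <- 1
    } else {
      p_stay <- states[[c_state]]$pain_relief_prob
      adv <- if (c_i < K) "next" else if (persist) "failed" else "death"
      tgt_kind <- c("stay", adv); tgt_p <- c(p_stay, 1 - p_stay)
    }
    stay_stage <- if (c_stage == "entry") "post" else c_stage
    for (a in seq_along(ae_p)) for (g in seq_along(tgt_p)) {
      pr <- ae_p[a] * tgt_p[g]
      if (pr == 0) next
      j <- switch(tgt_kind[g],
        self  = get(lab(c_state, c_stage, ae_type[a], ae_phase[a]), idx),
        stay  = get(lab(c_state, stay_stage, ae_type[a], ae_phase[a]), idx),
        "next" = {
          nxt <- states[[next_state[c_i]]]
          get(lab(nxt$name, entry_stage(nxt), ae_type[a], ae_phase[a]), idx)
        },
        failed = get(lab(c_state, "failed", ae_type[a], ae_phase[a]), idx),
        death = death)
      A[r, j] <- A[r, j] + pr
    }
  }
  A
}

#' Background mortality per cycle at a given age
#'
#' Annual probabilities from the age table are converted to per-cycle
#' probabilities as `1 - (1 - q)^cycle_length_years`.
#'
#' @param model An `oa_model`.
#' @param age Age in years.
#' @return Per-cycle death probability.
#' @export
mortality_per_cycle <- function(model, age) {
  mt <- model$mortality
  if (identical(mt$mode, "constant")) return(mt$per_cycle_death_prob)
  tab <- mt$age_table
  hit <- which(age >= tab$age_from & age < tab$age_to)
  if (!length(hit)) {
    if (age >= max(tab$age_to)) stop("mortality lookup outside table: age ", age)
    if (age < min(tab$age_from)) stop("mortality lookup outside table: age ", age)
  }
  q_ann <- tab$annual_prob[hit[1]]
  1 - (1 - q_ann)^model$economics$cycle_length_years
}

#' Full one-cycle transition matrix at a given age
#'
#' Background mortality is applied first; survivors are allocated among
#' staying (pain relieved), advancing to the next treatment, and
#' chronic-condition substate changes. Rows are stochastic and the death
#' column is absorbing; no mass flows to an earlier treatment state.
#'
#' @param strategy Strategy name or character sequence of state names.
#' @param model An `oa_model`.
#' @param age Age in years (for the mortality lookup).
#' @return Row-stochastic matrix over compartments plus `death`.
#' @export
build_cycle_transition <- function(strategy, model, age) {
  sequence <- resolve_sequence(strategy, model)
  A <- survivor_matrix(sequence, model)
  q <- mortality_per_cycle(model, age)
  n <- nrow(A) - 1L
  M <- A
  M[seq_len(n), ] <- (1 - q) * A[seq_len(n), , drop = FALSE]
  M[seq_len(n), n + 1L] <- M[seq_len(n), n + 1L] + q
  M
}

resolve_sequence <- function(strategy, model) {
  if (length(strategy) == 1 && strategy %in% names(model$strategies))
    return(model$strategies[[strategy]]$sequence)
  ok <- validate_strategy(strategy, model$states)
  if (!isTRUE(ok)) stop("invalid strategy: ", ok)
  strategy
}

#' Run the cohort recursion for one strategy
#'
#' The whole cohort starts in the first treatment state at `start_age` and
#' is propagated cycle by cycle until the live fraction falls below
#' `tol_alive` or `max_age` is reached (in which case the trace carries a
#' truncation flag). Occupancy rows are start-of-cycle fractions.
#'
#' @param model An `oa_model`.
#' @param strategy Strategy name (or explicit state-name sequence).
#' @param max_cycles Optional hard cap on the number of cycles (used by the
#'   small hand-checkable oracle models).
#' @param tol_alive Live-fraction threshold below which the run stops.
#' @return An object of class `oa_trace`: occupancy matrix (cycles+1 rows,
#'   one column per compartment plus `death`), `ages`, per-cycle expected
#'   adverse-event incidence (`events`), per-cycle state entrants
#'   (`entrants`), the compartment table, and a `truncated` flag.
#' @export
run_cohort <- function(model, strategy, max_cycles = NULL, tol_alive = 1e-9) {
  sequence <- resolve_sequence(strategy, model)
  comps <- compartment_table(sequence, model)
  A <- survivor_matrix(sequence, model, comps)
  n <- nrow(comps)
  A_live <- A[seq_len(n), seq_len(n), drop = FALSE]
  a_death <- A[seq_len(n), n + 1L]
  e <- model$economics
  T_max <- ceiling((e$max_age_years - e$start_age_years) / e$cycle_length_years)
  if (!is.null(max_cycles)) T_max <- max_cycles
  K <- length(sequence)
  state_cols <- lapply(seq_len(K), function(i)
    which(comps$state_index == i & comps$stage != "failed"))
  phase1_cols <- lapply(chronic_ae_kinds(), function(k)
    which(comps$ae_type == k & comps$ae_phase == 1L))
  names(phase1_cols) <- chronic_ae_kinds()
  trans_inc <- sapply(transient_ae_kinds(), function(k)
    ifelse(comps$stage %in% c("active", "entry"),
           vapply(comps$state, function(s) model$states[[s]]$ae_incidence[[k]], 0), 0))
  occ <- matrix(0, T_max + 1L, n + 1L,
                dimnames = list(NULL, c(comps$label, "death")))
  entrants <- matrix(0, T_max + 1L, K, dimnames = list(NULL, sequence))
  events <- matrix(0, T_max, length(ae_kinds()),
                   dimnames = list(NULL, names(ae_kinds())))
  start_lab <- comps$label[comps$state_index == 1L &
                           comps$stage == entry_stage(model$states[[sequence[1]]]) &
                           comps$ae_type == "none"]
  v <- stats::setNames(numeric(n), comps$label)
  v[start_lab] <- 1
  occ[1L, seq_len(n)] <- v
  entrants[1L, 1L] <- 1
  p_relief <- vapply(sequence, function(s) model$states[[s]]$pain_relief_prob, 0)
  truncated <- FALSE
  t_end <- 0L
  for (t in seq_len(T_max)) {
    age <- e$start_age_years + (t - 1L) * e$cycle_length_years
    q <- mortality_per_cycle(model, age)
    events[t, transient_ae_kinds()] <- as.numeric(v %*% trans_inc)
    vn <- (1 - q) * as.numeric(v %*% A_live)
    if (K > 1L) for (i in 2L:K)
      entrants[t + 1L, i] <- (1 - q) * (1 - p_relief[i - 1L]) *
        sum(v[state_cols[[i - 1L]]])
    occ[t + 1L, seq_len(n)] <- vn
    occ[t + 1L, n + 1L] <- occ[t, n + 1L] + q * sum(v) +
      (1 - q) * sum(v * a_death)
    for (k in chronic_ae_kinds())
      events[t, k] <- sum(vn[phase1_cols[[k]]])
    v <- vn
    t_end <- t
    if (sum(v) < tol_alive) break
  }
  if (sum(v) >= tol_alive && t_end == T_max && is.null(max_cycles)) truncated <- TRUE
  occ <- occ[seq_len(t_end + 1L), , drop = FALSE]
  entrants <- entrants[seq_len(t_end + 1L), , drop = FALSE]
  events <- events[seq_len(t_end), , drop = FALSE]
  structure(list(strategy = if (length(strategy) == 1) strategy else "custom",
                 sequence = sequence, comps = comps,
                 occupancy = occ, entrants = entrants, events = events,
                 ages = e$start_age_years +
                   (seq_len(t_end + 1L) - 1L) * e$cycle_length_years,
                 n_cycles = t_end, truncated = truncated),
            class = "oa_trace")
}

#' @export
print.oa_trace <- function(x, ...) {
  cat(sprintf("<oa_trace> strategy '%s': %d cycles, final death occupancy %.6f%s\n",
              x$strategy, x$n_cycles, x$occupancy[nrow(x$occupancy), "death"],
              if (x$truncated) " (truncated at max age)" else ""))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle: age, every compartment occupancy, death, and the
#' per-cycle expected adverse-event incidences.
#'
#' @param trace An `oa_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  n <- nrow(trace$occupancy)
  ev <- rbind(trace$events, NA)
  colnames(ev) <- paste0("events.", colnames(ev))
  df <- data.frame(cycle = seq_len(n) - 1L, age = trace$ages,
                   trace$occupancy, ev, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
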