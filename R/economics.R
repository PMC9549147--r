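# Discounted cost/QALY accrual, ICER and dominance-frontier analysis.

#' Discount factor
#'
#' @param t_years Time in years (>= 0).
#' @param rate Annual discount rate as a fraction.
#' @return `(1 + rate)^(-t_years)`; 1 at `t_years = 0`.
#' @export
discount_factor <- function(t_years, rate) {
  if (any(t_years < 0)) stop("discount_factor: negative time")
  if (any(rate < 0)) stop("discount_factor: negative rate")
  (1 + rate)^(-t_years)
}

# Static per-compartment accrual vectors for one strategy.
comp_accrual_vectors <- function(comps, model) {
  u <- model$utilities
  ae <- model$adverse_events
  p_relief <- vapply(comps$state,
                     function(s) model$states[[s]]$pain_relief_prob, 0)
  base_u <- ifelse(comps$stage == "failed", u$moderate_pain,
                   p_relief * u$no_pain + (1 - p_relief) * u$moderate_pain)
  chronic_dis <- ifelse(comps$ae_phase >= 1L,
                        vapply(comps$ae_type, function(k)
                          if (k == "none") 0 else abs(ae[[k]]$disutility), 0), 0)
  at_risk <- comps$stage %in% c("active", "entry")
  trans_dis <- numeric(nrow(comps))
  trans_cost <- numeric(nrow(comps))
  for (k in transient_ae_kinds()) {
    inc <- ifelse(at_risk,
                  vapply(comps$state,
                         function(s) model$states[[s]]$ae_incidence[[k]], 0), 0)
    trans_dis <- trans_dis + inc * abs(ae[[k]]$disutility)
    trans_cost <- trans_cost + inc * ae[[k]]$acute_cost
  }
  chronic_cost <- vapply(seq_len(nrow(comps)), function(r) {
    k <- comps$ae_type[r]
    if (k == "none") return(0)
    ph <- comps$ae_phase[r]
    if (ph == 1L) ae[[k]]$acute_cost
    else if (ph %in% c(2L, 3L)) ae[[k]]$first_year_cost / 2
    else ae[[k]]$subsequent_year_cost / 2
  }, 0)
  treat_cost <- ifelse(comps$stage %in% c("active", "entry"),
                       vapply(comps$state,
                              function(s) model$states[[s]]$cycle_cost, 0), 0)
  living_cost <- visit_cost_per_cycle(model) + model$economics$indirect_cost_per_cycle
  u_raw <- base_u - chronic_dis - trans_dis
  list(cost = treat_cost + living_cost + trans_cost + chronic_cost,
       utility = pmax(u_raw, 0),
       n_floored = sum(u_raw < 0))
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Per cycle, cost is occupancy times (treatment + visit + indirect cost)
#' plus one-time costs for state entrants, expected transient adverse-event
#' costs, and phased chronic-condition costs (acute in the event cycle,
#' first-year costs split over the next two cycles, maintenance per
#' half-year thereafter). QALYs weight occupancy by cycle length and a
#' utility in which per-cycle responders accrue the no-pain utility,
#' patients whose pain persists accrue the moderate-pain utility in their
#' current state, and adverse-event disutilities subtract per their
#' persistence. Both streams are discounted at start-of-cycle time by
#' default (`economics$discount_timing = "mid"` shifts accrual to
#' mid-cycle). Utilities driven below zero by disutilities are floored at
#' zero with a warning.
#'
#' @param trace An `oa_trace` from [run_cohort()].
#' @param model The `oa_model` that produced it.
#' @return An object of class `oa_cea` with discounted and undiscounted
#'   `cost` and `qaly` totals and discounted life years.
#' @export
accrue <- function(trace, model) {
  comps <- trace$comps
  vec <- comp_accrual_vectors(comps, model)
  if (vec$n_floored > 0)
    warning(vec$n_floored, " compartment utilities floored at 0 after disutility subtraction")
  e <- model$economics
  n <- nrow(trace$occupancy)
  cyc <- seq_len(n - 1L) - 1L  # accrual cycles 0..n-2; last row is a snapshot
  t_years <- cyc * e$cycle_length_years +
    if (e$discount_timing == "mid") e$cycle_length_years / 2 else 0
  disc <- discount_factor(t_years, e$annual_discount_rate)
  live <- trace$occupancy[seq_len(n - 1L), seq_len(ncol(trace$occupancy) - 1L),
                          drop = FALSE]
  one_time <- vapply(trace$sequence,
                     function(s) model$states[[s]]$one_time_cost, 0)
  cost_t <- as.numeric(live %*% vec$cost) +
    as.numeric(trace$entrants[seq_len(n - 1L), , drop = FALSE] %*% one_time)
  qaly_t <- e$cycle_length_years * as.numeric(live %*% vec$utility)
  ly_t <- e$cycle_length_years * rowSums(live)
  structure(list(strategy = trace$strategy,
                 cost = sum(cost_t * disc), qaly = sum(qaly_t * disc),
                 cost_undisc = sum(cost_t), qaly_undisc = sum(qaly_t),
                 life_years = sum(ly_t * disc),
                 n_cycles = trace$n_cycles, truncated = trace$truncated),
            class = "oa_cea")
}

#' @export
print.oa_cea <- function(x, ...) {
  cat(sprintf("<oa_cea> %s: %.0f THB, %.4f QALYs (discounted; %.0f THB / %.4f undiscounted)\n",
              x$strategy, x$cost, x$qaly, x$cost_undisc, x$qaly_undisc))
  invisible(x)
}

#' Run one strategy end-to-end
#'
#' @param model An `oa_model`.
#' @param strategy Strategy name.
#' @return An `oa_cea` result (see [accrue()]).
#' @export
run_cea <- function(model, strategy) {
  accrue(run_cohort(model, strategy), model)
}

#' Evaluate every strategy of a model
#'
#' @param model An `oa_model`.
#' @param strategies Strategy names (default: all).
#' @return Data frame with one row per strategy: discounted and
#'   undiscounted cost and QALY totals.
#' @export
run_all_strategies <- function(model, strategies = names(model$strategies)) {
  res <- lapply(strategies, function(s) run_cea(model, s))
  data.frame(strategy = strategies,
             cost = vapply(res, `[[`, 0, "cost"),
             qaly = vapply(res, `[[`, 0, "qaly"),
             cost_undisc = vapply(res, `[[`, 0, "cost_undisc"),
             qaly_undisc = vapply(res, `[[`, 0, "qaly_undisc"),
             stringsAsFactors = FALSE)
}

cea_pair <- function(x) {
  if (inherits(x, "oa_cea")) c(cost = x$cost, qaly = x$qaly)
  else if (is.numeric(x) && length(x) == 2) c(cost = x[[1]], qaly = x[[2]])
  else stop("expected an oa_cea or a (cost, qaly) pair")
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)`. With equal QALYs the ratio is
#' undefined; `NA` is returned with a warning to compare costs directly.
#' A negative ratio with `qaly_a > qaly_b` and `cost_a < cost_b` means `a`
#' dominates `b` and should be reported as dominance, not as a ratio.
#'
#' @param a,b `oa_cea` results or `(cost, qaly)` numeric pairs.
#' @return Money per QALY.
#' @export
icer <- function(a, b) {
  a <- cea_pair(a); b <- cea_pair(b)
  if (a[["qaly"]] == b[["qaly"]]) {
    warning("ICER undefined for equal QALYs; compare costs directly")
    return(NA_real_)
  }
  (a[["cost"]] - b[["cost"]]) / (a[["qaly"]] - b[["qaly"]])
}

#' Net monetary benefit
#'
#' @param result An `oa_cea` or `(cost, qaly)` pair.
#' @param wtp Willingness to pay per QALY (>= 0).
#' @return `wtp * qaly - cost`.
#' @export
nmb <- function(result, wtp) {
  if (any(wtp < 0)) stop("nmb: wtp must be >= 0")
  r <- cea_pair(result)
  wtp * r[["qaly"]] - r[["cost"]]
}

#' Convert THB to USD
#'
#' @param amount Amount in THB.
#' @param fx THB per USD exchange rate (default 36.16).
#' @return Amount in USD (unrounded; tables round to integers).
#' @export
thb_to_usd <- function(amount, fx = 36.16) {
  if (fx <= 0) stop("thb_to_usd: fx must be > 0")
  amount / fx
}

#' Dominance and extended-dominance frontier
#'
#' Strictly dominated strategies (another strategy costs no more and yields
#' at least as many QALYs, one strictly) are removed first; remaining
#' points off the convex cost-QALY frontier are removed as extendedly
#' dominated (their incremental ratio exceeds that of the next segment).
#' Frontier strategies are annotated with pairwise ICERs in QALY order; a
#' frontier strategy that strictly dominates the reference is labelled
#' `dominant`. Duplicate (cost, QALY) pairs are kept and flagged as ties.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly` (or a
#'   list of `oa_cea` objects).
#' @param reference Strategy name used as the comparator for the
#'   `dominant` label; defaults to the first row.
#' @return Data frame with columns `strategy`, `cost`, `qaly`, `label`
#'   (`reference`, `dominant`, `dominated`, `extended_dominated`,
#'   `on_frontier`), `icer` (vs the previous frontier point), and
#'   `dominated_by`/`tie` annotations; of class `oa_frontier`.
#' @export
dominance_frontier <- function(results, reference = NULL) {
  if (inherits(results, "oa_cea")) results <- list(results)
  if (is.list(results) && !is.data.frame(results))
    results <- data.frame(strategy = vapply(results, `[[`, "", "strategy"),
                          cost = vapply(results, `[[`, 0, "cost"),
                          qaly = vapply(results, `[[`, 0, "qaly"),
                          stringsAsFactors = FALSE)
  df <- results[, c("strategy", "cost", "qaly")]
  if (is.null(reference)) reference <- df$strategy[1]
  n <- nrow(df)
  df$label <- "on_frontier"
  df$icer <- NA_real_
  df$dominated_by <- NA_character_
  df$tie <- FALSE
  for (j in seq_len(n)) {
    dup <- which(df$cost == df$cost[j] & df$qaly == df$qaly[j])
    if (length(dup) > 1) df$tie[j] <- TRUE
    dom <- which(df$cost <= df$cost[j] & df$qaly >= df$qaly[j] &
                   (df$cost < df$cost[j] | df$qaly > df$qaly[j]))
    if (length(dom)) {
      df$label[j] <- "dominated"
      df$dominated_by[j] <- df$strategy[dom[order(df$cost[dom])][1]]
    }
  }
  cand <- which(df$label != "dominated")
  cand <- cand[order(df$qaly[cand], df$cost[cand])]
  repeat {
    if (length(cand) < 3) break
    ic <- diff(df$cost[cand]) / diff(df$qaly[cand])
    bad <- which(ic[-length(ic)] > ic[-1])[1]
    if (is.na(bad)) break
    df$label[cand[bad + 1]] <- "extended_dominated"
    cand <- cand[-(bad + 1)]
  }
  if (length(cand) > 1) {
    for (m in 2:length(cand)) {
      dq <- df$qaly[cand[m]] - df$qaly[cand[m - 1]]
      df$icer[cand[m]] <- if (dq == 0) NA_real_ else
        (df$cost[cand[m]] - df$cost[cand[m - 1]]) / dq
    }
  }
  ref_row <- match(reference, df$strategy)
  if (!is.na(ref_row)) {
    beats_ref <- df$cost <= df$cost[ref_row] & df$qaly >= df$qaly[ref_row] &
      (df$cost < df$cost[ref_row] | df$qaly > df$qaly[ref_row])
    df$label[df$label == "on_frontier" & beats_ref] <- "dominant"
    df$label[ref_row] <- "reference"
  }
  class(df) <- c("oa_frontier", "data.frame")
  df
}

#' @export
print.oa_frontier <- function(x, ...) {
  y <- as.data.frame(x)
  y$cost <- round(y$cost)
  y$qaly <- round(y$qaly, 2)
  y$icer <- ifelse(is.na(y$icer), "", format(round(y$icer), big.mark = ","))
  print(y[, c("strategy", "cost", "qaly", "label", "icer")], row.names = FALSE)
  invisible(x)
}
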