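# Sensitivity analysis: method-of-moments distribution fits, one-way
# deterministic analysis (tornado), Monte-Carlo probabilistic analysis,
# cost-effectiveness plane and acceptability curves.

#' Gamma distribution from mean and standard error
#'
#' Method of moments: `shape = (mean/se)^2`, `scale = se^2/mean`, so the
#' fitted distribution has exactly the requested mean and SD.
#'
#' @param mean Mean (> 0).
#' @param se Standard error (> 0; `se = 0` is the degenerate "fixed" case
#'   and is rejected here).
#' @return List with `shape` and `scale`.
#' @export
gamma_from_moments <- function(mean, se) {
  if (mean <= 0) stop("gamma_from_moments: mean must be > 0")
  if (se <= 0) stop("gamma_from_moments: se must be > 0 (use family 'fixed' for se = 0)")
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Beta distribution from mean and standard error
#'
#' Method of moments: `nu = mean(1-mean)/se^2 - 1`, `alpha = mean*nu`,
#' `beta = (1-mean)*nu`. Infeasible moments (`se^2 >= mean(1-mean)`) are an
#' error.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error (> 0).
#' @return List with `alpha` and `beta`.
#' @export
beta_from_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("beta_from_moments: mean must lie in (0, 1)")
  if (se <= 0) stop("beta_from_moments: se must be > 0 (use family 'fixed' for se = 0)")
  if (se^2 >= mean * (1 - mean))
    stop("beta_from_moments: infeasible moments, se^2 >= mean*(1-mean)")
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Log-normal distribution from mean and standard error
#'
#' Method of moments on the natural scale: `sigma^2 = log(1 + se^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2`. Draws used as probabilities are truncated
#' to [0, 1] after sampling (the analytic moments hold before truncation).
#'
#' @param mean Mean (> 0).
#' @param se Standard error (> 0).
#' @return List with `mu` (meanlog) and `sigma` (sdlog).
#' @export
lognormal_from_moments <- function(mean, se) {
  if (mean <= 0) stop("lognormal_from_moments: mean must be > 0")
  if (se <= 0) stop("lognormal_from_moments: se must be > 0 (use family 'fixed' for se = 0)")
  sigma2 <- log(1 + se^2 / mean^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Parameter uncertainty registry of a model
#'
#' Enumerates every uncertain scalar of the model with its mean, standard
#' error, one-way (DSA) range and sampling family. Families follow the
#' class rule: costs are gamma; adverse-event probabilities, utilities and
#' disutility magnitudes are beta; pain-relief (transition) probabilities
#' are log-normal, truncated to [0, 1] at sampling. Parameters with no
#' reported standard error get `default_se_frac * mean` (a per-parameter
#' override in `model$uncertainty$overrides` wins); zero-mean or zero-se
#' parameters are `fixed`.
#'
#' @param model An `oa_model`.
#' @return Data frame with columns `id`, `class`, `mean`, `se`,
#'   `dsa_low`, `dsa_high`, `family`.
#' @export
build_param_table <- function(model) {
  def <- model$uncertainty$default_se_frac
  ovr <- model$uncertainty$overrides
  rows <- list()
  add <- function(id, class, mean, se = NA_real_) {
    if (!is.na(se) && se == 0) se <- NA_real_
    if (is.na(se)) se <- if (!is.null(ovr[[id]]$se)) ovr[[id]]$se else def * mean
    family <- if (mean == 0 || se == 0) "fixed" else
      switch(class, cost = "gamma", probability = "beta", utility = "beta",
             transition = "lognormal", "fixed")
    if (class %in% c("probability", "utility") && family == "beta" && mean >= 1)
      family <- "fixed"
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, class = class, mean = mean, se = se,
      family = family, stringsAsFactors = FALSE)
  }
  for (s in model$states) {
    add(paste0("state.", s$name, ".pain_relief_prob"), "transition",
        s$pain_relief_prob)
    for (k in names(ae_kinds()))
      add(paste0("state.", s$name, ".ae.", k), "probability",
          s$ae_incidence[[k]])
    add(paste0("state.", s$name, ".cycle_cost"), "cost", s$cycle_cost)
    add(paste0("state.", s$name, ".one_time_cost"), "cost", s$one_time_cost)
  }
  for (k in names(ae_kinds())) {
    a <- model$adverse_events[[k]]
    add(paste0("ae_cost.", k, ".acute"), "cost", a$acute_cost, a$acute_cost_se)
    if (ae_kinds()[[k]] == "chronic") {
      add(paste0("ae_cost.", k, ".first_year"), "cost",
          a$first_year_cost, a$first_year_cost_se)
      add(paste0("ae_cost.", k, ".subsequent_year"), "cost",
          a$subsequent_year_cost, a$subsequent_year_cost_se)
    }
    add(paste0("disutility.", k), "utility", abs(a$disutility), a$disutility_se)
  }
  u <- model$utilities
  add("utility.no_pain", "utility", u$no_pain, u$no_pain_se)
  add("utility.moderate_pain", "utility", u$moderate_pain, u$moderate_pain_se)
  e <- model$economics
  add("econ.travel_cost", "cost", e$travel_cost, e$travel_cost_se)
  add("econ.food_cost", "cost", e$food_cost, e$food_cost_se)
  tab <- do.call(rbind, rows)
  tab$dsa_low <- pmax(tab$mean - 2 * tab$se, 0)
  tab$dsa_high <- tab$mean + 2 * tab$se
  bounded <- tab$class %in% c("probability", "utility", "transition")
  tab$dsa_high[bounded] <- pmin(tab$dsa_high[bounded], 1)
  if (length(model$dsa)) for (d in model$dsa) {
    j <- match(d$param, tab$id)
    if (!is.na(j)) { tab$dsa_low[j] <- d$low; tab$dsa_high[j] <- d$high }
  }
  rownames(tab) <- NULL
  tab[, c("id", "class", "mean", "se", "dsa_low", "dsa_high", "family")]
}

#' Pin parameter values into a model
#'
#' Takes a named vector of registry ids (see [build_param_table()]) and
#' returns the model with those scalars replaced. Probabilities and
#' utilities are clamped to [0, 1]; cross-parameter constraints (e.g. the
#' utility ordering) are deliberately not re-imposed so that sensitivity
#' ranges wider than the base-case ordering can be explored.
#'
#' @param model An `oa_model`.
#' @param values Named numeric vector, names are registry ids.
#' @return The modified model.
#' @export
apply_params <- function(model, values) {
  for (id in names(values)) {
    v <- as.numeric(values[[id]])
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    ok <- TRUE
    if (parts[1] == "state" && length(parts) >= 3) {
      nm <- parts[2]
      if (is.null(model$states[[nm]])) ok <- FALSE
      else if (parts[3] == "pain_relief_prob")
        model$states[[nm]]$pain_relief_prob <- min(max(v, 0), 1)
      else if (parts[3] == "ae" && length(parts) == 4 &&
               parts[4] %in% names(ae_kinds()))
        model$states[[nm]]$ae_incidence[[parts[4]]] <- min(max(v, 0), 1)
      else if (parts[3] %in% c("cycle_cost", "one_time_cost"))
        model$states[[nm]][[parts[3]]] <- max(v, 0)
      else ok <- FALSE
    } else if (parts[1] == "ae_cost" && length(parts) == 3 &&
               parts[2] %in% names(ae_kinds())) {
      fld <- switch(parts[3], acute = "acute_cost",
                    first_year = "first_year_cost",
                    subsequent_year = "subsequent_year_cost", NA)
      if (is.na(fld)) ok <- FALSE
      else model$adverse_events[[parts[2]]][[fld]] <- max(v, 0)
    } else if (parts[1] == "disutility" && length(parts) == 2 &&
               parts[2] %in% names(ae_kinds())) {
      model$adverse_events[[parts[2]]]$disutility <- -min(max(v, 0), 1)
    } else if (parts[1] == "utility" && length(parts) == 2 &&
               parts[2] %in% c("no_pain", "moderate_pain")) {
      model$utilities[[parts[2]]] <- min(max(v, 0), 1)
    } else if (parts[1] == "econ" && length(parts) == 2 &&
               parts[2] %in% c("travel_cost", "food_cost")) {
      model$economics[[parts[2]]] <- max(v, 0)
    } else ok <- FALSE
    if (!ok) stop("unknown parameter id: ", id)
  }
  model
}

# Deterministic per-parameter RNG substream seed: a string hash of the id
# mixed with the root seed, so adding a parameter never perturbs the draws
# of the others.
param_stream_seed <- function(root_seed, id) {
  h <- 0
  for (b in utf8ToInt(id)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (root_seed %% 2147483647) * 7919) %% 2147483647)
}

sample_param <- function(row, n, root_seed) {
  set.seed(param_stream_seed(root_seed, row$id))
  x <- switch(row$family,
    fixed = rep(row$mean, n),
    gamma = {
      f <- gamma_from_moments(row$mean, row$se)
      stats::rgamma(n, shape = f$shape, scale = f$scale)
    },
    beta = {
      f <- tryCatch(beta_from_moments(row$mean, row$se),
                    error = function(e) stop("parameter '", row$id, "': ",
                                             conditionMessage(e)))
      stats::rbeta(n, f$alpha, f$beta)
    },
    lognormal = {
      f <- lognormal_from_moments(row$mean, row$se)
      stats::rlnorm(n, f$mu, f$sigma)
    },
    stop("parameter '", row$id, "': unknown family ", row$family))
  if (row$class %in% c("probability", "utility", "transition"))
    x <- pmin(pmax(x, 0), 1)
  x
}

#' Sample all uncertain parameters
#'
#' @param param_table Registry from [build_param_table()].
#' @param n Number of iterations.
#' @param seed Root seed; each parameter draws from its own deterministic
#'   substream.
#' @return Matrix `n x nrow(param_table)` with registry ids as column
#'   names.
#' @export
sample_params <- function(param_table, n, seed) {
  draws <- vapply(seq_len(nrow(param_table)),
                  function(j) sample_param(param_table[j, ], n, seed),
                  numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- param_table$id
  draws
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Reruns the full base-case pipeline twice with the parameter pinned at
#' its low and high value (all other parameters at base values) and
#' reports the designated comparison's output at each end.
#'
#' @param model An `oa_model`.
#' @param param Registry id (see [build_param_table()]).
#' @param low,high Pinned values (`low <= high`).
#' @param comparison Character pair `c(strategy, comparator)`.
#' @param metric `"inmb"` (incremental net monetary benefit at `wtp`) or
#'   `"icer"`.
#' @param wtp Willingness to pay used by the NMB metric (default: the
#'   model's).
#' @return One-row data frame: parameter, low/high value, output at each,
#'   and the bar width `|output_high - output_low|`.
#' @export
one_way_dsa <- function(model, param, low, high,
                        comparison = utils::tail(names(model$strategies), 1),
                        metric = c("inmb", "icer"), wtp = NULL) {
  metric <- match.arg(metric)
  if (is.null(wtp)) wtp <- model$economics$wtp_per_qaly
  if (length(comparison) == 1)
    comparison <- c(comparison, names(model$strategies)[1])
  ptab <- build_param_table(model)
  j <- match(param, ptab$id)
  if (is.na(j))
    stop("unknown parameter '", param, "'; valid ids include: ",
         paste(utils::head(ptab$id, 8), collapse = ", "), ", ...")
  if (low > high) stop("one_way_dsa: low > high")
  if (ptab$class[j] %in% c("probability", "utility", "transition") &&
      (low < 0 || high > 1))
    stop("one_way_dsa: pinned value for '", param, "' outside [0, 1]")
  out <- vapply(c(low, high), function(v) {
    m <- apply_params(model, stats::setNames(v, param))
    a <- run_cea(m, comparison[1]); b <- run_cea(m, comparison[2])
    if (metric == "inmb") nmb(a, wtp) - nmb(b, wtp)
    else suppressWarnings(icer(a, b))
  }, 0)
  data.frame(parameter = param, low = low, high = high,
             output_at_low = out[1], output_at_high = out[2],
             bar_width = abs(out[2] - out[1]), stringsAsFactors = FALSE)
}

#' Tornado analysis over a set of parameters
#'
#' Runs [one_way_dsa()] for each entry (default: the model's configured
#' `dsa` ranges) and sorts by descending bar width. Duplicate parameters
#' are deduplicated with a warning.
#'
#' @inheritParams one_way_dsa
#' @param params Data frame or list with `param`, `low`, `high`; defaults
#'   to `model$dsa`.
#' @return Data frame of tornado entries sorted by `bar_width`.
#' @export
tornado_analysis <- function(model, params = NULL,
                             comparison = utils::tail(names(model$strategies), 1),
                             metric = c("inmb", "icer"), wtp = NULL) {
  metric <- match.arg(metric)
  if (is.null(params)) params <- model$dsa
  if (is.data.frame(params))
    params <- lapply(seq_len(nrow(params)), function(i) as.list(params[i, ]))
  if (!length(params))
    return(data.frame(parameter = character(), low = numeric(),
                      high = numeric(), output_at_low = numeric(),
                      output_at_high = numeric(), bar_width = numeric()))
  ids <- vapply(params, `[[`, "", "param")
  if (anyDuplicated(ids)) {
    warning("duplicate DSA parameter(s) removed: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    params <- params[!duplicated(ids)]
  }
  rows <- lapply(params, function(p)
    one_way_dsa(model, p$param, p$low, p$high, comparison, metric, wtp))
  out <- do.call(rbind, rows)
  out[order(-out$bar_width), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation: each iteration samples every uncertain
#' parameter once from its class-based distribution and evaluates every
#' strategy on that same draw (common random parameters), recording the
#' discounted (cost, QALY) pair. Deterministic given the seed.
#'
#' @param model An `oa_model`.
#' @param n_iter Number of iterations (>= 1).
#' @param seed Root RNG seed.
#' @param strategies Strategy names (default: all).
#' @return An object of class `oa_psa`: `results` (data frame with
#'   `iteration`, `strategy`, `cost`, `qaly`), the parameter registry and
#'   the draw matrix.
#' @export
run_psa <- function(model, n_iter, seed = 1,
                    strategies = names(model$strategies)) {
  if (n_iter < 1) stop("run_psa: n_iter must be >= 1")
  ptab <- build_param_table(model)
  draws <- sample_params(ptab, n_iter, seed)
  res <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    m <- apply_params(model, draws[i, ])
    cea <- lapply(strategies, function(s) run_cea(m, s))
    res[[i]] <- data.frame(iteration = i, strategy = strategies,
                           cost = vapply(cea, `[[`, 0, "cost"),
                           qaly = vapply(cea, `[[`, 0, "qaly"),
                           stringsAsFactors = FALSE)
  }
  structure(list(results = do.call(rbind, res), params = ptab,
                 draws = draws, seed = seed, n_iter = n_iter),
            class = "oa_psa")
}

#' @export
print.oa_psa <- function(x, ...) {
  cat(sprintf("<oa_psa> %d iterations x %d strategies (seed %s)\n",
              x$n_iter, length(unique(x$results$strategy)),
              format(x$seed)))
  invisible(x)
}

psa_pair_deltas <- function(psa, strategy, comparator) {
  r <- psa$results
  a <- r[r$strategy == strategy, ]
  b <- r[r$strategy == comparator, ]
  a <- a[order(a$iteration), ]; b <- b[order(b$iteration), ]
  if (nrow(a) != nrow(b) || !nrow(a))
    stop("both strategies must be present in every draw")
  data.frame(iteration = a$iteration,
             delta_cost = a$cost - b$cost, delta_qaly = a$qaly - b$qaly)
}

#' Incremental cost-effectiveness plane
#'
#' Classifies each iteration's (delta QALY, delta cost) point into the
#' four quadrants. Points on an axis count toward the favourable quadrant
#' (lower-right: cheaper and at least as effective), deterministically.
#'
#' @param psa An `oa_psa`.
#' @param strategy,comparator Strategy names to difference
#'   (strategy minus comparator).
#' @return List with `points` (per-iteration deltas and quadrant) and
#'   `proportions` (named shares over `upper_right`, `lower_right`,
#'   `lower_left`, `upper_left`).
#' @export
ce_plane <- function(psa, strategy, comparator) {
  d <- psa_pair_deltas(psa, strategy, comparator)
  quad <- ifelse(d$delta_qaly >= 0 & d$delta_cost <= 0, "lower_right",
          ifelse(d$delta_qaly > 0 & d$delta_cost > 0, "upper_right",
          ifelse(d$delta_qaly <= 0 & d$delta_cost >= 0, "upper_left",
                 "lower_left")))
  d$quadrant <- quad
  lev <- c("upper_right", "lower_right", "lower_left", "upper_left")
  prop <- vapply(lev, function(l) mean(quad == l), 0)
  list(points = d, proportions = prop,
       strategy = strategy, comparator = comparator)
}

#' Cost-effectiveness acceptability curve
#'
#' Pairwise: the fraction of iterations in which the strategy's net
#' monetary benefit is at least the comparator's, per willingness-to-pay
#' grid point. Multi-way (no comparator): the fraction of iterations in
#' which each strategy attains the maximal net monetary benefit (first
#' strategy wins exact ties), so probabilities sum to 1 at each grid
#' point.
#'
#' @param psa An `oa_psa`.
#' @param wtp_grid Willingness-to-pay grid (default 0 to 320,000 THB in
#'   5,000 steps).
#' @param strategy For the pairwise curve, the strategy of interest.
#' @param comparator Pairwise comparator; `NULL` for the multi-way curve.
#' @return Data frame: `wtp` and one probability column per strategy (or
#'   `prob` for the pairwise curve).
#' @export
ceac <- function(psa, wtp_grid = seq(0, 320000, by = 5000),
                 strategy = NULL, comparator = NULL) {
  if (!length(wtp_grid)) stop("ceac: empty wtp grid")
  r <- psa$results
  if (!is.null(comparator)) {
    d <- psa_pair_deltas(psa, strategy, comparator)
    prob <- vapply(wtp_grid,
                   function(w) mean(w * d$delta_qaly - d$delta_cost >= 0), 0)
    return(data.frame(wtp = wtp_grid, prob = prob))
  }
  strategies <- unique(r$strategy)
  iter <- sort(unique(r$iteration))
  cost <- matrix(r$cost[order(match(r$strategy, strategies), r$iteration)],
                 nrow = length(iter), dimnames = list(NULL, strategies))
  qaly <- matrix(r$qaly[order(match(r$strategy, strategies), r$iteration)],
                 nrow = length(iter), dimnames = list(NULL, strategies))
  out <- data.frame(wtp = wtp_grid)
  win <- matrix(0, length(wtp_grid), length(strategies),
                dimnames = list(NULL, strategies))
  for (i in seq_along(wtp_grid)) {
    nb <- wtp_grid[i] * qaly - cost
    best <- apply(nb, 1, which.max)
    for (s in seq_along(strategies)) win[i, s] <- mean(best == s)
  }
  cbind(out, as.data.frame(win))
}
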