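# Report assembly: base-case frontier table, tornado table, PSA exports,
# each with a JSON run manifest.

write_manifest <- function(out_dir, model, config_path = NULL, seed = NULL,
                           subcommand = "", options = list()) {
  manifest <- list(
    subcommand = subcommand,
    config_path = if (is.null(config_path)) NA else config_path,
    config_md5 = if (is.null(config_path)) NA else
      unname(tools::md5sum(config_path)),
    seed = if (is.null(seed)) NA else seed,
    package_version = as.character(utils::packageVersion("oacua")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    options = options)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(subcommand, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

resolve_model <- function(model) {
  if (inherits(model, "oa_model")) list(model = model, path = NULL)
  else list(model = load_model(model), path = model)
}

#' Base-case report: frontier table and narrative
#'
#' Evaluates every strategy, builds the dominance frontier, and writes
#' `basecase_frontier.csv` (strategy, THB and USD costs, QALYs, label,
#' ICER) plus a JSON manifest to `out_dir`.
#'
#' @param model An `oa_model` or a path to a YAML configuration.
#' @param out_dir Output directory (created if missing).
#' @return The frontier data frame, invisibly.
#' @export
report_basecase <- function(model, out_dir) {
  m <- resolve_model(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_all_strategies(m$model)
  fr <- dominance_frontier(res)
  fx <- m$model$economics$fx_thb_per_usd
  out <- data.frame(strategy = fr$strategy,
                    label = vapply(fr$strategy, function(s)
                      m$model$strategies[[s]]$label %||% s, ""),
                    cost_thb = round(fr$cost),
                    cost_usd = round(thb_to_usd(fr$cost, fx)),
                    qalys = round(fr$qaly, 2),
                    status = fr$label,
                    icer_thb_per_qaly = round(fr$icer),
                    icer_usd_per_qaly = round(thb_to_usd(fr$icer, fx)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(out_dir, "basecase_frontier.csv"),
                   row.names = FALSE, na = "")
  write_manifest(out_dir, m$model, m$path, subcommand = "basecase")
  on_front <- fr$strategy[fr$label %in% c("on_frontier", "dominant") |
                            (fr$label == "reference" & is.na(fr$dominated_by))]
  message("Base case: ", nrow(out), " strategies; frontier: ",
          paste(on_front, collapse = ", "))
  invisible(fr)
}

#' One-way sensitivity report: tornado table
#'
#' Runs the configured one-way analyses and writes `tornado.csv` (sorted
#' by descending bar width) plus a manifest to `out_dir`.
#'
#' @inheritParams report_basecase
#' @param params Optional override of `model$dsa` (list of
#'   `param`/`low`/`high` entries).
#' @param comparison Character pair `c(strategy, comparator)` for the
#'   output metric (default: last strategy vs first).
#' @param metric `"inmb"` or `"icer"` (see [one_way_dsa()]).
#' @return The tornado data frame, invisibly.
#' @export
report_dsa <- function(model, out_dir, params = NULL,
                       comparison = NULL, metric = "inmb") {
  m <- resolve_model(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(comparison))
    comparison <- c(utils::tail(names(m$model$strategies), 1),
                    names(m$model$strategies)[1])
  tor <- tornado_analysis(m$model, params, comparison, metric)
  utils::write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE)
  write_manifest(out_dir, m$model, m$path, subcommand = "dsa",
                 options = list(comparison = comparison, metric = metric))
  invisible(tor)
}

#' Probabilistic sensitivity report: draws, CE plane, CEAC
#'
#' Runs the Monte-Carlo analysis and writes `psa_draws.csv` (iteration,
#' strategy, cost, QALY), `ce_plane.csv` (per-iteration deltas and
#' quadrant for the designated pair), `ceac_pairwise.csv`,
#' `ceac_multiway.csv` and a manifest recording the seed. Outputs are
#' byte-identical across runs with the same configuration and seed.
#'
#' @inheritParams report_basecase
#' @param n_iter Number of Monte-Carlo iterations.
#' @param seed Root RNG seed.
#' @param comparison Character pair `c(strategy, comparator)` for the
#'   pairwise plane/curve (default: last strategy vs first).
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @return The `oa_psa` object, invisibly.
#' @export
report_psa <- function(model, out_dir, n_iter = 1000, seed = 1,
                       comparison = NULL,
                       wtp_grid = seq(0, 320000, by = 5000)) {
  m <- resolve_model(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(comparison))
    comparison <- c(utils::tail(names(m$model$strategies), 1),
                    names(m$model$strategies)[1])
  psa <- run_psa(m$model, n_iter, seed)
  utils::write.csv(psa$results, file.path(out_dir, "psa_draws.csv"),
                   row.names = FALSE)
  plane <- ce_plane(psa, comparison[1], comparison[2])
  utils::write.csv(plane$points, file.path(out_dir, "ce_plane.csv"),
                   row.names = FALSE)
  utils::write.csv(ceac(psa, wtp_grid, comparison[1], comparison[2]),
                   file.path(out_dir, "ceac_pairwise.csv"), row.names = FALSE)
  utils::write.csv(ceac(psa, wtp_grid),
                   file.path(out_dir, "ceac_multiway.csv"), row.names = FALSE)
  write_manifest(out_dir, m$model, m$path, seed = seed, subcommand = "psa",
                 options = list(n_iter = n_iter, comparison = comparison))
  invisible(psa)
}
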