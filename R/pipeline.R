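# End-to-end pipeline: base case across scenarios, optional DSA/PSA, and
# all file outputs plus a reproducibility manifest.

# deterministic 32-bit FNV-1a hash of a string (for the config manifest);
# state kept as a double, xor applied to the low 16 bits to stay inside
# R's 32-bit integer range
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full cost-effectiveness pipeline
#'
#' Computes both arms' occupancy traces, per-scenario cost breakdowns,
#' QALYs and ICERs, an internal-consistency check of the results table
#' (incremental QALYs must be scenario-invariant), and optionally a
#' one-way deterministic sensitivity analysis and a probabilistic
#' sensitivity analysis with CEAC. When `output_dir` is given, writes the
#' trace, breakdown, results, tornado, PSA scatter and CEAC CSVs plus a
#' JSON run manifest (seed, configuration hash, package version).
#'
#' @param config A validated configuration (see [default_config()],
#'   [make_fixture()]).
#' @param scenarios Scenario ids to sweep (default 1:5).
#' @param output_dir Optional output directory (created if needed).
#' @param dsa Run the one-way DSA for `dsa_scenario`?
#' @param psa_iter Monte Carlo iterations for the PSA (0 = skip).
#' @param dsa_scenario,psa_scenario Scenario id used for DSA / PSA.
#' @param seed RNG seed for the PSA.
#' @param wtp_grid WTP grid for the CEAC (USD/QALY).
#' @return List with `results` (Table-2-style data frame), `traces`,
#'   `breakdowns`, `consistency`, and (if requested) `tornado`, `psa`,
#'   `ceac`, plus the `manifest`.
#' @export
run_pipeline <- function(config, scenarios = 1:5, output_dir = NULL,
                         dsa = FALSE, psa_iter = 0,
                         dsa_scenario = scenarios[1], psa_scenario = scenarios[1],
                         seed = 1, wtp_grid = seq(0, 75000, by = 1500)) {
  stopifnot(inherits(config, "psmcea_config"))
  traces <- compute_traces(config)
  rate <- config$costbook$exchange_rate_cny_per_usd

  rows <- list(); breakdowns <- list()
  for (sid in scenarios) {
    ev <- build_evaluator(config, sid)
    res <- ev()
    sc <- scenario_from_config(config, sid)
    rows[[as.character(sid)]] <- data.frame(
      scenario = sid, label = sc$label, arm = c("hchop", "rchop"),
      total_cost_usd = c(res$cost_a, res$cost_b),
      qalys = c(res$qaly_a, res$qaly_b),
      icer_usd_per_qaly = c(res$icer, NA)
    )
    breakdowns[[as.character(sid)]] <- res$breakdowns
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  consistency <- check_results_consistency(results, tol = 1e-9)

  out <- list(results = results, traces = traces, breakdowns = breakdowns,
              consistency = consistency)

  if (dsa) {
    ev <- build_evaluator(config, dsa_scenario)
    out$tornado <- one_way_dsa(ev, build_param_specs(config, dsa_scenario))
  }
  if (psa_iter > 0) {
    ev <- build_evaluator(config, psa_scenario)
    out$psa <- run_psa(ev, build_param_specs(config, psa_scenario),
                       n_iter = psa_iter, seed = seed)
    out$ceac <- ceac(out$psa, wtp_grid)
  }

  manifest <- list(
    package = "psmcea",
    version = as.character(utils::packageVersion("psmcea")),
    seed = seed,
    scenarios = scenarios,
    psa_iterations = psa_iter,
    config_hash = .fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                          digits = NA))
  )
  out$manifest <- manifest

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(output_dir, ...)
    for (arm in names(traces)) write_trace(traces[[arm]], fp(sprintf("trace_%s.csv", arm)))
    write_results_table(results, fp("results.csv"), rate)
    for (sid in names(breakdowns)) {
      write_breakdown(breakdowns[[sid]], fp(sprintf("breakdown_scenario%s.csv", sid)))
    }
    if (!is.null(out$tornado)) write_tornado(out$tornado, fp("tornado.csv"))
    if (!is.null(out$psa)) write_psa_scatter(out$psa, fp("psa_scatter.csv"))
    if (!is.null(out$ceac)) write_ceac(out$ceac, fp("ceac.csv"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               fp("manifest.json"))
  }
  out
}
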