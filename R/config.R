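# Configuration: schema validation, path-based access, fixtures and the
# model evaluation closure used by the base case, DSA and PSA.

#' Load the bundled default configuration
#'
#' Reads and validates the packaged model configuration (survival
#' parameters, full cost book, adverse-event incidences and costs,
#' utilities, regimen, scenario definitions and willingness-to-pay
#' settings).
#'
#' @return A validated configuration (class `psmcea_config`).
#' @export
default_config <- function() {
  path <- system.file("extdata", "default_config.yaml", package = "psmcea")
  validate_config(yaml::read_yaml(path))
}

#' Read a configuration file
#'
#' @param path YAML (or JSON) configuration file.
#' @return A validated configuration.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_config(raw)
}

# ---- path access ----------------------------------------------------------

#' Get / set a configuration value by dotted path
#'
#' Paths address nested fields, e.g. `"costbook.drugs.hanlikang.price"`;
#' purely numeric components index list positions (e.g. `"scenarios.3"`).
#'
#' @param config A configuration list.
#' @param path Dotted path string.
#' @param value Replacement value (for `config_set`).
#' @return The value at `path`, or the modified configuration.
#' @export
config_get <- function(config, path) {
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    p2 <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    config <- config[[p2]]
    if (is.null(config)) return(NULL)
  }
  config
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  parts <- lapply(parts, function(p) if (grepl("^[0-9]+$", p)) as.integer(p) else p)
  rec <- function(x, i) {
    if (i > length(parts)) return(value)
    key <- parts[[i]]
    x[[key]] <- rec(x[[key]], i + 1)
    x
  }
  rec(config, 1)
}

# ---- validation -----------------------------------------------------------

#' Validate a model configuration
#'
#' Cross-checks every block the model needs and reports *all* failing
#' paths at once.
#'
#' @param raw Parsed configuration (nested list).
#' @return The configuration with class `psmcea_config`.
#' @export
validate_config <- function(raw) {
  errs <- character(0)
  bad <- function(path, msg) errs <<- c(errs, sprintf("%s: %s", path, msg))
  need <- function(path) {
    v <- config_get(raw, path)
    if (is.null(v)) bad(path, "missing")
    v
  }
  num_ok <- function(path, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    v <- need(path)
    if (!is.null(v)) {
      if (!is.numeric(v)) bad(path, "not numeric")
      else if (any(v < lo) || any(v > hi) || (strict_lo && any(v <= lo)))
        bad(path, sprintf("outside [%s, %s]", lo, hi))
    }
    v
  }

  num_ok("settings.cycle_length_days", 0, Inf, strict_lo = TRUE)
  num_ok("settings.horizon_years", 0, Inf, strict_lo = TRUE)
  num_ok("settings.discount_rate", 0, 1)
  num_ok("settings.days_per_year", 0, Inf, strict_lo = TRUE)

  for (arm in c("hchop", "rchop")) for (ep in c("os", "pfs")) {
    base <- sprintf("survival.%s.%s", arm, ep)
    fam <- need(paste0(base, ".family"))
    if (!is.null(fam)) {
      if (!fam %in% surv_families()) bad(paste0(base, ".family"), "unknown family")
      else for (p in .family_param_names(fam)) {
        v <- need(sprintf("%s.%s", base, p))
        if (!is.null(v) && p %in% c("sdlog", "scale", "shape") && fam != "gompertz" &&
            is.numeric(v) && v <= 0) bad(sprintf("%s.%s", base, p), "must be > 0")
      }
    }
  }

  num_ok("costbook.bsa_m2", 0, Inf, strict_lo = TRUE)
  num_ok("costbook.exchange_rate_cny_per_usd", 0, Inf, strict_lo = TRUE)
  drugs <- need("costbook.drugs")
  if (is.list(drugs)) for (d in names(drugs)) {
    num_ok(sprintf("costbook.drugs.%s.price", d), 0)
    num_ok(sprintf("costbook.drugs.%s.unit_mg", d), 0, Inf, strict_lo = TRUE)
  }
  for (blk in c("administration", "labs", "ae_costs")) {
    b <- need(paste0("costbook.", blk))
    if (is.list(b)) for (k in names(b)) num_ok(sprintf("costbook.%s.%s", blk, k), 0)
  }
  num_ok("costbook.terminal", 0)

  ae_cost_names <- names(config_get(raw, "costbook.ae_costs"))
  for (arm in c("hchop", "rchop")) {
    risks <- need(paste0("ae_risks.", arm))
    if (is.list(risks)) {
      for (k in names(risks)) num_ok(sprintf("ae_risks.%s.%s", arm, k), 0, 1)
      extra <- setdiff(names(risks), ae_cost_names)
      if (length(extra)) bad(paste0("ae_risks.", arm),
                             paste("no matching ae_costs entry for:", paste(extra, collapse = ", ")))
    }
  }

  u_pfs <- num_ok("utilities.pfs.value", 0, 1)
  u_pd <- num_ok("utilities.pd.value", 0, 1)
  if (is.numeric(u_pfs) && is.numeric(u_pd) && length(u_pfs) == 1 &&
      length(u_pd) == 1 && u_pd > u_pfs) bad("utilities.pd.value", "exceeds utilities.pfs.value")
  du <- need("utilities.ae_disutility.value")
  if (is.numeric(du) && du > 0) bad("utilities.ae_disutility.value", "must be <= 0")

  need("regimen.n_cycles"); need("regimen.chop")
  for (arm in c("hchop", "rchop")) {
    ab <- need(sprintf("regimen.antibody.%s", arm))
    if (is.list(ab) && !is.null(drugs) && !ab$drug %in% names(drugs)) {
      bad(sprintf("regimen.antibody.%s.drug", arm), "not in costbook.drugs")
    }
  }

  scen <- need("scenarios")
  if (is.list(scen)) {
    ids <- vapply(scen, function(s) as.integer(s$id), integer(1))
    if (anyDuplicated(ids)) bad("scenarios", "duplicate scenario ids")
    for (i in seq_along(scen)) {
      num_ok(sprintf("scenarios.%d.postprogression_cost", i), 0)
      num_ok(sprintf("scenarios.%d.pd_cycle_cost", i), 0)
    }
  }
  num_ok("wtp.gdp_per_capita", 0, Inf, strict_lo = TRUE)

  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  class(raw) <- c("psmcea_config", "list")
  raw
}

# ---- derived objects ------------------------------------------------------

#' Build model settings from a configuration
#'
#' @param config A validated configuration.
#' @return A [model_settings()].
#' @export
settings_from_config <- function(config) {
  s <- config$settings
  model_settings(s$cycle_length_days, s$horizon_years, s$discount_rate, s$days_per_year)
}

#' Build a survival model from a configuration block
#'
#' @param config A validated configuration.
#' @param arm `"hchop"` or `"rchop"`.
#' @param endpoint `"os"` or `"pfs"`.
#' @return A [parametric_survival()].
#' @export
survival_from_config <- function(config, arm, endpoint) {
  blk <- config$survival[[arm]][[endpoint]]
  fam <- blk$family
  params <- unlist(blk[.family_param_names(fam)])
  parametric_survival(fam, params)
}

#' Cost book view of a configuration
#'
#' @param config A validated configuration.
#' @return List with `drugs`, `administration`, `labs`, `ae_costs`,
#'   `terminal`, `bsa`, `exchange_rate`.
#' @export
cost_book <- function(config) {
  cb <- config$costbook
  list(drugs = cb$drugs, administration = cb$administration, labs = cb$labs,
       ae_costs = cb$ae_costs, terminal = cb$terminal,
       bsa = cb$bsa_m2, exchange_rate = cb$exchange_rate_cny_per_usd)
}

#' Regimen component list for an arm
#'
#' @param config A validated configuration.
#' @param arm `"hchop"` or `"rchop"`.
#' @return List of regimen components (antibody first, then CHOP).
#' @export
regimen_for_arm <- function(config, arm) {
  c(list(config$regimen$antibody[[arm]]), config$regimen$chop)
}

#' Utility set from a configuration
#'
#' @param config A validated configuration.
#' @return A [utility_set()].
#' @export
utilities_from_config <- function(config) {
  u <- config$utilities
  utility_set(u$pfs$value, u$pd$value, u$ae_disutility$value,
              enforce_order = FALSE)  # ordering checked by validate_config
}

#' Scenario specification from a configuration
#'
#' @param config A validated configuration.
#' @param id Scenario id (1-5).
#' @return A [scenario_spec()].
#' @export
scenario_from_config <- function(config, id) {
  for (s in config$scenarios) {
    if (as.integer(s$id) == as.integer(id)) {
      return(scenario_spec(s$id, s$label, s$postprogression_cost, s$pd_cycle_cost))
    }
  }
  stop(sprintf("unknown scenario id %s", id))
}

#' Compute both arms' occupancy traces
#'
#' @param config A validated configuration.
#' @return Named list of [state_occupancy()] traces (`hchop`, `rchop`).
#' @export
compute_traces <- function(config) {
  settings <- settings_from_config(config)
  lapply(setNames(c("hchop", "rchop"), c("hchop", "rchop")), function(arm) {
    state_occupancy(survival_from_config(config, arm, "os"),
                    survival_from_config(config, arm, "pfs"), settings)
  })
}

#' Build a model evaluation closure
#'
#' Returns a function mapping a named list of configuration overrides
#' (dotted paths, see [config_set()]) to a [cea_compare()] result for the
#' given scenario. Occupancy traces are cached and only recomputed when an
#' override touches the survival parameters or the cycle/horizon settings,
#' which makes the closure cheap enough for many-iteration probabilistic
#' sensitivity analysis.
#'
#' @param config A validated configuration.
#' @param scenario_id Scenario id (1-5).
#' @param wtp Willingness-to-pay used for the NMB column of the result.
#' @return `function(overrides = list()) -> cea_result`.
#' @export
build_evaluator <- function(config, scenario_id, wtp = NULL) {
  base <- config
  base_traces <- compute_traces(base)
  if (is.null(wtp)) wtp <- wtp_from_gdp(config$wtp$gdp_per_capita, 3)
  structural <- c("survival", "settings.cycle_length_days",
                  "settings.horizon_years", "settings.days_per_year")
  function(overrides = list()) {
    cfg <- base
    for (nm in names(overrides)) cfg <- config_set(cfg, nm, overrides[[nm]])
    needs_trace <- any(vapply(names(overrides), function(nm)
      any(startsWith(nm, structural)), logical(1)))
    traces <- if (needs_trace) compute_traces(cfg) else base_traces
    settings <- settings_from_config(cfg)
    book <- cost_book(cfg)
    utilities <- utilities_from_config(cfg)
    scenario <- scenario_from_config(cfg, scenario_id)
    res <- lapply(c(hchop = "hchop", rchop = "rchop"), function(arm) {
      arm_totals(traces[[arm]], book, regimen_for_arm(cfg, arm),
                 unlist(cfg$ae_risks[[arm]]), scenario, utilities, settings)
    })
    out <- cea_compare(res$hchop$breakdown[["total"]], res$hchop$qalys,
                       res$rchop$breakdown[["total"]], res$rchop$qalys, wtp)
    out$breakdowns <- list(hchop = res$hchop$breakdown, rchop = res$rchop$breakdown)
    out
  }
}
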