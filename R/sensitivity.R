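# Deterministic (one-way, tornado) and probabilistic (Monte Carlo, CEAC)
# sensitivity analysis.

#' Sensitivity-analysis parameter specification
#'
#' @param name Parameter label.
#' @param base Base-case value.
#' @param lower,upper Bounds; default plus/minus 20% of base. Read as a
#'   95% interval when building sampling distributions.
#' @param family Sampling family: `"gamma"` (costs), `"beta"`
#'   (probabilities and utilities; negative bases are sampled on their
#'   magnitude and negated), `"beta-scaled"` (beta rescaled to
#'   `[0, support_upper]`, used for the discount rate), or `"fixed"`.
#' @param target Dotted configuration path the parameter feeds
#'   (see [config_set()]).
#' @param dsa_only Exclude from probabilistic analysis (used for survival
#'   parameters, which have no published uncertainty bounds).
#' @param support_upper Upper end of the support for `"beta-scaled"`.
#' @return Object of class `param_spec`.
#' @export
param_spec <- function(name, base, lower = NULL, upper = NULL,
                       family = c("gamma", "beta", "beta-scaled", "fixed"),
                       target = name, dsa_only = FALSE, support_upper = NULL) {
  family <- match.arg(family)
  if (is.null(lower)) lower <- min(0.8 * base, 1.2 * base)
  if (is.null(upper)) upper <- max(0.8 * base, 1.2 * base)
  if (family == "beta" && base >= 0 && upper > 1) upper <- 1  # probabilities truncate at 1
  if (lower > base || base > upper) {
    stop(sprintf("parameter '%s': need lower <= base <= upper", name))
  }
  structure(list(name = name, base = base, lower = lower, upper = upper,
                 family = family, target = target, dsa_only = dsa_only,
                 support_upper = support_upper), class = "param_spec")
}

#' Build a sampler for a parameter
#'
#' Method-of-moments sampling distribution with mean equal to the base
#' value and SD equal to `(upper - lower)/3.92` (bounds read as a 95%
#' interval): gamma via shape/rate, beta via alpha/beta, beta-scaled via a
#' beta on `[0, support_upper]`. Degenerate specs (zero spread or zero
#' base for gamma) collapse to the base value.
#'
#' @param spec A [param_spec()].
#' @return `function(n)` drawing `n` values.
#' @export
fit_sampling_distribution <- function(spec) {
  base <- spec$base
  sdv <- (spec$upper - spec$lower) / 3.92
  if (spec$family == "fixed" || sdv == 0) {
    return(function(n) rep(base, n))
  }
  if (spec$family == "gamma") {
    if (base <= 0) return(function(n) rep(base, n))
    shape <- (base / sdv)^2
    rate <- shape / base
    f <- function(n) rgamma(n, shape = shape, rate = rate)
    attr(f, "dist") <- list(family = "gamma", shape = shape, rate = rate)
    return(f)
  }
  if (spec$family == "beta") {
    m <- abs(base); sgn <- if (base < 0) -1 else 1
    if (sdv^2 >= m * (1 - m)) {
      stop(sprintf("infeasible beta moments for parameter '%s' (SD^2 >= m(1-m))", spec$name))
    }
    nu <- m * (1 - m) / sdv^2 - 1
    a <- m * nu; b <- (1 - m) * nu
    f <- function(n) sgn * rbeta(n, a, b)
    attr(f, "dist") <- list(family = "beta", alpha = a, beta = b)
    return(f)
  }
  # beta-scaled on [0, support_upper]
  S <- spec$support_upper
  if (is.null(S)) S <- spec$upper
  m <- base / S; sds <- sdv / S
  if (sds^2 >= m * (1 - m)) {
    stop(sprintf("infeasible beta moments for parameter '%s' (SD^2 >= m(1-m))", spec$name))
  }
  nu <- m * (1 - m) / sds^2 - 1
  a <- m * nu; b <- (1 - m) * nu
  f <- function(n) S * rbeta(n, a, b)
  attr(f, "dist") <- list(family = "beta-scaled", alpha = a, beta = b, scale = S)
  f
}

# support predicate for resampling checks
.in_support <- function(spec, x) {
  switch(spec$family,
    gamma = x >= 0,
    beta = if (spec$base < 0) x <= 0 & x >= -1 else x >= 0 & x <= 1,
    `beta-scaled` = x >= 0 & x <= (if (is.null(spec$support_upper)) spec$upper else spec$support_upper),
    fixed = rep(TRUE, length(x))
  )
}

#' Build the full parameter set from a configuration
#'
#' Assembles one [param_spec()] per varied model input: all unit prices
#' (gamma, plus/minus 20%), adverse-event incidences (beta, plus/minus 20%
#' truncated at 1), utilities and the adverse-event disutility (beta, with
#' the configured bounds), the discount rate (beta scaled to its 0-0.08
#' range), the scenario post-progression costs (gamma), and the survival
#' parameters (plus/minus 20%, one-way analysis only).
#'
#' @param config A validated configuration.
#' @param scenario_id Scenario whose pathway costs are included.
#' @return List of `param_spec` objects.
#' @export
build_param_specs <- function(config, scenario_id = 1) {
  specs <- list()
  add <- function(s) specs[[length(specs) + 1]] <<- s

  for (arm in c("hchop", "rchop")) for (ep in c("os", "pfs")) {
    blk <- config$survival[[arm]][[ep]]
    for (p in .family_param_names(blk$family)) {
      add(param_spec(sprintf("%s_%s_%s", arm, ep, p), blk[[p]],
                     family = "fixed", dsa_only = TRUE,
                     target = sprintf("survival.%s.%s.%s", arm, ep, p)))
    }
  }
  for (d in names(config$costbook$drugs)) {
    add(param_spec(paste0("price_", d), config$costbook$drugs[[d]]$price,
                   family = "gamma", target = sprintf("costbook.drugs.%s.price", d)))
  }
  for (blk in c("administration", "labs", "ae_costs")) {
    for (k in names(config$costbook[[blk]])) {
      add(param_spec(sprintf("%s_%s", blk, k), config$costbook[[blk]][[k]],
                     family = "gamma", target = sprintf("costbook.%s.%s", blk, k)))
    }
  }
  add(param_spec("terminal_cost", config$costbook$terminal,
                 family = "gamma", target = "costbook.terminal"))
  for (arm in c("hchop", "rchop")) {
    for (k in names(config$ae_risks[[arm]])) {
      add(param_spec(sprintf("risk_%s_%s", arm, k), config$ae_risks[[arm]][[k]],
                     family = "beta", target = sprintf("ae_risks.%s.%s", arm, k)))
    }
  }
  u <- config$utilities
  add(param_spec("utility_pfs", u$pfs$value, u$pfs$lower, min(u$pfs$upper, 1),
                 family = "beta", target = "utilities.pfs.value"))
  add(param_spec("utility_pd", u$pd$value, u$pd$lower, min(u$pd$upper, 1),
                 family = "beta", target = "utilities.pd.value"))
  add(param_spec("ae_disutility", u$ae_disutility$value,
                 u$ae_disutility$lower, u$ae_disutility$upper,
                 family = "beta", target = "utilities.ae_disutility.value"))
  db <- config$discount_bounds
  add(param_spec("discount_rate", config$settings$discount_rate, db$lower, db$upper,
                 family = "beta-scaled", support_upper = db$upper,
                 target = "settings.discount_rate"))
  idx <- which(vapply(config$scenarios, function(s) as.integer(s$id), integer(1)) ==
                 as.integer(scenario_id))
  if (length(idx) != 1) stop(sprintf("unknown scenario id %s", scenario_id))
  sc <- config$scenarios[[idx]]
  if (sc$postprogression_cost > 0) {
    add(param_spec("postprogression_cost", sc$postprogression_cost, family = "gamma",
                   target = sprintf("scenarios.%d.postprogression_cost", idx)))
  }
  if (sc$pd_cycle_cost > 0) {
    add(param_spec("pd_cycle_cost", sc$pd_cycle_cost, family = "gamma",
                   target = sprintf("scenarios.%d.pd_cycle_cost", idx)))
  }
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Evaluates the model at each parameter's lower and upper bound with all
#' other parameters at base, and ranks parameters by the absolute ICER
#' range they induce. The bound values are the signed cost-effectiveness
#' ratios (incremental cost over incremental QALYs, negative when a bound
#' makes the intervention cost-saving) so the tornado remains defined
#' through dominance; bound evaluations that error or land on zero
#' incremental effect are recorded as failed and ranked last.
#'
#' @param model Evaluation closure from [build_evaluator()].
#' @param specs List of [param_spec()]s.
#' @return `data.frame` of class `tornado` (name, icer_low, icer_high,
#'   range, failed), sorted by descending range, with the base-case ICER
#'   as attribute `"base_icer"`.
#' @export
one_way_dsa <- function(model, specs) {
  base <- model()
  eval_icer <- function(target, value) {
    res <- tryCatch(model(setNames(list(value), target)), error = function(e) NULL)
    if (is.null(res) || res$delta_qaly == 0) NA_real_
    else res$delta_cost / res$delta_qaly
  }
  rows <- lapply(specs, function(s) {
    lo <- eval_icer(s$target, s$lower)
    hi <- eval_icer(s$target, s$upper)
    data.frame(name = s$name, icer_low = lo, icer_high = hi,
               range = abs(hi - lo), failed = is.na(lo) || is.na(hi))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$failed, -out$range), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters simultaneously from their sampling distributions
#' (see [fit_sampling_distribution()]) and records the incremental cost
#' and QALYs of every iteration. Parameters marked `dsa_only` are held at
#' base. Reproducible given `seed`; draws falling outside their support
#' are resampled (bounded retries).
#'
#' @param model Evaluation closure from [build_evaluator()].
#' @param specs List of [param_spec()]s.
#' @param n_iter Number of Monte Carlo iterations (>= 1).
#' @param seed RNG seed.
#' @param max_retries Resampling attempts per parameter.
#' @return `data.frame` of class `psa_draws` (iteration, delta_cost,
#'   delta_qaly) with the sampled parameter matrix as attribute
#'   `"samples"` and the seed as attribute `"seed"`.
#' @export
run_psa <- function(model, specs, n_iter = 10000, seed = 1, max_retries = 100) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  specs <- Filter(function(s) !isTRUE(s$dsa_only), specs)
  set.seed(seed)
  samples <- matrix(NA_real_, nrow = n_iter, ncol = length(specs),
                    dimnames = list(NULL, vapply(specs, `[[`, character(1), "name")))
  for (j in seq_along(specs)) {
    sampler <- fit_sampling_distribution(specs[[j]])
    x <- sampler(n_iter)
    tries <- 0
    repeat {
      bad <- !.in_support(specs[[j]], x)
      if (!any(bad)) break
      tries <- tries + 1
      if (tries > max_retries) {
        stop(sprintf("parameter '%s': draws persistently outside support", specs[[j]]$name))
      }
      x[bad] <- sampler(sum(bad))
    }
    samples[, j] <- x
  }
  targets <- vapply(specs, `[[`, character(1), "target")
  dc <- de <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    overrides <- setNames(as.list(samples[i, ]), targets)
    res <- model(overrides)
    dc[i] <- res$delta_cost
    de[i] <- res$delta_qaly
  }
  out <- data.frame(iteration = seq_len(n_iter), delta_cost = dc, delta_qaly = de)
  attr(out, "samples") <- samples
  attr(out, "seed") <- seed
  class(out) <- c("psa_draws", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of Monte Carlo draws
#' with strictly positive incremental net monetary benefit
#' (`delta_qaly * wtp - delta_cost > 0`); exact ties count as not
#' cost-effective.
#'
#' @param draws A [run_psa()] result.
#' @param wtp_grid Non-empty vector of WTP values (USD/QALY).
#' @return `data.frame(wtp, probability)`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (length(wtp_grid) < 1) stop("wtp_grid must be non-empty")
  if (nrow(draws) < 1) stop("need at least one draw")
  prob <- vapply(wtp_grid, function(w)
    mean(draws$delta_qaly * w - draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Write tornado / PSA scatter / CEAC tables
#'
#' @param x Tornado `data.frame`, `psa_draws`, or CEAC `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(x, path) {
  out <- as.data.frame(x)
  out$rank <- seq_len(nrow(out))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado
#' @export
write_psa_scatter <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tornado
#' @export
write_ceac <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
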