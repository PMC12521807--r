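# Synthetic-data generation: pseudo individual patient data under known
# truth, digitiser-like Kaplan-Meier coordinates, and complete fixture
# configurations, so every pipeline stage is testable without downloads.

#' Simulation specification
#'
#' @param family Survival family of the truth distribution (see
#'   [surv_families()]).
#' @param params Named parameter vector of the truth (years).
#' @param n Cohort size (>= 1).
#' @param admin_time Administrative censoring time in years (`Inf` for
#'   none).
#' @param cens_frac Expected fraction of subjects lost to random
#'   censoring, in \[0, 1). Random censoring must be independent of the
#'   event time for Kaplan-Meier and likelihood methods to remain
#'   unbiased, so a `2 * cens_frac` random subset of subjects receives a
#'   censoring time drawn independently from the truth distribution
#'   (which precedes the subject's own event time with probability 1/2).
#' @param seed RNG seed.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(family = "lognormal",
                     params = c(meanlog = 3.284, sdlog = 1.938),
                     n = 200, admin_time = Inf, cens_frac = 0, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (cens_frac < 0 || cens_frac > 0.5) stop("cens_frac must lie in [0, 0.5]")
  model <- parametric_survival(family, params)  # validates family/params
  structure(list(family = model$family, params = model$params, n = as.integer(n),
                 admin_time = admin_time, cens_frac = cens_frac, seed = seed),
            class = "sim_spec")
}

.r_event_times <- function(family, params, n) {
  p <- params
  switch(family,
    lognormal   = rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    weibull     = rweibull(n, p[["shape"]], p[["scale"]]),
    loglogistic = flexsurv::rllogis(n, shape = p[["shape"]], scale = p[["scale"]]),
    gompertz    = flexsurv::rgompertz(n, shape = p[["shape"]], rate = p[["rate"]]),
    gamma       = rgamma(n, p[["shape"]], p[["rate"]]),
    exponential = rexp(n, p[["rate"]])
  )
}

#' Simulate right-censored individual patient data
#'
#' Event times are drawn from the truth distribution; random censoring
#' (independent of the event times, see [sim_spec()]) removes an expected
#' `cens_frac` of subjects, and administrative censoring truncates
#' everything at `admin_time`.
#'
#' @param spec A [sim_spec()].
#' @return IPD `data.frame(time, event)` with `n` rows; reproducible by
#'   seed.
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  t_event <- .r_event_times(spec$family, spec$params, spec$n)
  time <- t_event
  event <- rep(1, spec$n)
  if (spec$cens_frac > 0) {
    sel <- runif(spec$n) < 2 * spec$cens_frac
    c_time <- .r_event_times(spec$family, spec$params, spec$n)
    cens <- sel & c_time < t_event
    time[cens] <- c_time[cens]
    event[cens] <- 0
  }
  admin <- time > spec$admin_time
  time[admin] <- spec$admin_time
  event[admin] <- 0
  ipd_records(time, event)
}

#' Digitise a Kaplan-Meier curve
#'
#' Emulates graph-digitiser output: samples the Kaplan-Meier step function
#' of the records at `n_points` survival-quantile-spaced times (denser
#' where the curve drops), optionally perturbs the read-off survival
#' values with truncated Gaussian jitter, and restores monotonicity by
#' isotonic (running-minimum) clipping. As in published figures, the
#' curve is read only over the plotted follow-up window: by default it is
#' truncated where fewer than `min_at_risk` subjects remain at risk (the
#' usual convention for terminating a plotted Kaplan-Meier curve, whose
#' tail is otherwise dominated by a handful of subjects).
#'
#' @param records IPD `data.frame(time, event)`.
#' @param n_points Number of digitised coordinates (>= 2).
#' @param jitter_sd SD of the Gaussian read-off error on the probability
#'   scale (0 = exact).
#' @param seed Optional RNG seed for the jitter.
#' @param t_max Right edge of the plotted window; default is the last
#'   time with at least `min_at_risk` subjects at risk.
#' @param min_at_risk At-risk count used to derive the default `t_max`
#'   (default 10).
#' @return A [digitized_curve()] with `total_n = nrow(records)`.
#' @export
digitize_km <- function(records, n_points = 40, jitter_sd = 0, seed = NULL,
                        t_max = NULL, min_at_risk = 10) {
  if (n_points < 2) stop("n_points must be >= 2")
  km <- km_estimate(records)
  if (is.null(t_max)) {
    ord <- sort(records$time, decreasing = TRUE)
    t_max <- if (length(ord) >= min_at_risk) ord[min_at_risk] else max(ord)
  }
  s_min <- min(km$surv[km$time <= t_max], 1)
  levels <- seq(1, s_min, length.out = n_points)
  tm <- vapply(levels, function(l) {
    i <- which(km$surv <= l + 1e-12)
    if (length(i)) min(km$time[i[1]], t_max) else 0
  }, numeric(1))
  tm[1] <- 0
  keep <- !duplicated(tm)
  tm <- tm[keep]
  sv <- km_surv_at(km, tm)
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sv <- pmin(1, pmax(0, sv + rnorm(length(sv), 0, jitter_sd)))
    sv <- cummin(sv)     # isotonic clipping
    sv[tm == 0] <- 1
  }
  digitized_curve(tm, sv, total_n = km$n)
}

#' Build a complete fixture configuration
#'
#' Returns the bundled default configuration (all base-case inputs) with
#' the requested post-progression scenario selected. The scenario pathway
#' cost magnitudes are placeholders (see the configuration file).
#'
#' @param scenario_id Scenario id, 1-5.
#' @return A validated configuration with `scenario_id` set.
#' @export
make_fixture <- function(scenario_id = 1) {
  if (!scenario_id %in% 1:5) stop("scenario_id must be 1..5")
  cfg <- default_config()
  cfg$scenario_id <- as.integer(scenario_id)
  cfg
}
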