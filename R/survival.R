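# Survival stage: digitised-curve reconstruction, Kaplan-Meier estimation,
# right-censored parametric fitting and information-criterion model selection.

# canonical family names -> flexsurv distribution names
.SURV_FAMILIES <- c(
  lognormal   = "lnorm",
  weibull     = "weibull",
  loglogistic = "llogis",
  gompertz    = "gompertz",
  gamma       = "gamma",
  exponential = "exp"
)

#' Supported parametric survival families
#'
#' @return Character vector of family names accepted by [fit_parametric()]
#'   and [parametric_survival()].
#' @export
surv_families <- function() names(.SURV_FAMILIES)

#' Construct a parametric survival model
#'
#' A declared (or fitted) survival distribution used to evaluate S(t) for
#' extrapolation. Time is measured in years. For the log-normal family the
#' parameters are `meanlog` (location of log event time) and `sdlog`
#' (scale of log event time, > 0).
#'
#' @param family One of [surv_families()].
#' @param params Named numeric vector of family parameters on the natural
#'   scale (e.g. `c(meanlog = 3.284, sdlog = 1.938)`).
#' @param loglik,n_obs Optional maximised log-likelihood and number of
#'   subjects; when both are given AIC and BIC are populated
#'   (`aic = 2k - 2*loglik`, `bic = k*log(n_obs) - 2*loglik` with `k` the
#'   number of parameters and `n_obs` the number of subjects).
#' @return An object of class `parametric_survival`.
#' @export
parametric_survival <- function(family, params, loglik = NA_real_, n_obs = NA_integer_) {
  family <- match.arg(family, names(.SURV_FAMILIES))
  params <- unlist(params)
  expected <- .family_param_names(family)
  if (is.null(names(params)) && length(params) == length(expected)) {
    names(params) <- expected
  }
  if (!setequal(names(params), expected)) {
    stop(sprintf("family '%s' expects parameters {%s}, got {%s}",
                 family, paste(expected, collapse = ", "),
                 paste(names(params), collapse = ", ")))
  }
  params <- params[expected]
  if (family == "lognormal" && params[["sdlog"]] <= 0) stop("sdlog must be > 0")
  if (family %in% c("weibull", "loglogistic", "gamma") &&
      any(params <= 0)) stop(sprintf("'%s' parameters must be > 0", family))
  if (family == "exponential" && params[["rate"]] <= 0) stop("rate must be > 0")
  if (family == "gompertz" && params[["rate"]] <= 0) stop("gompertz rate must be > 0")
  k <- length(params)
  structure(list(
    family = family, params = params, loglik = loglik, n_params = k,
    n_obs = n_obs,
    aic = if (is.na(loglik)) NA_real_ else 2 * k - 2 * loglik,
    bic = if (is.na(loglik) || is.na(n_obs)) NA_real_ else k * log(n_obs) - 2 * loglik
  ), class = "parametric_survival")
}

.family_param_names <- function(family) {
  switch(family,
    lognormal   = c("meanlog", "sdlog"),
    weibull     = c("shape", "scale"),
    loglogistic = c("shape", "scale"),
    gompertz    = c("shape", "rate"),
    gamma       = c("shape", "rate"),
    exponential = "rate"
  )
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("Parametric survival model: %s\n", x$family))
  cat("  ", paste(sprintf("%s = %.6g", names(x$params), x$params), collapse = ", "), "\n")
  if (!is.na(x$loglik)) {
    cat(sprintf("  loglik = %.4f (n = %s), AIC = %.4f, BIC = %.4f\n",
                x$loglik, x$n_obs, x$aic, x$bic))
  }
  invisible(x)
}

#' Evaluate a survival function
#'
#' Computes S(t), the probability of being event-free at time `t` (years),
#' for a fitted or declared parametric model. For the log-normal family
#' `S(t) = 1 - pnorm((log(t) - meanlog)/sdlog)`.
#'
#' @param model A [parametric_survival()] object.
#' @param t Non-negative time(s) in years.
#' @return Numeric vector of survival probabilities, `S(0) = 1`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(t < 0)) stop("t must be >= 0")
  p <- model$params
  s <- switch(model$family,
    lognormal   = plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    weibull     = pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[["shape"]], scale = p[["scale"]],
                                    lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p[["shape"]], rate = p[["rate"]],
                                      lower.tail = FALSE),
    gamma       = pgamma(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    exponential = pexp(t, p[["rate"]], lower.tail = FALSE)
  )
  s[t == 0] <- 1
  s
}

#' Individual patient data records
#'
#' @param time Non-negative follow-up durations (years).
#' @param event Binary indicator, 1 = event observed, 0 = right-censored.
#' @return A `data.frame` with columns `time` and `event`.
#' @export
ipd_records <- function(time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(event)) stop("time and event must have equal length")
  if (any(time < 0)) stop("time must be >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  data.frame(time = time, event = event)
}

#' Construct a digitised Kaplan-Meier curve
#'
#' Holds (time, survival) coordinates read off a published survival figure
#' together with the cohort size, the substrate for [reconstruct_ipd()].
#'
#' @param time,survival Coordinate vectors; survival must be non-increasing
#'   and in \[0, 1\]. A leading (0, 1) anchor is added if absent.
#' @param total_n Cohort size (>= 1).
#' @param at_risk Optional `data.frame(time, n_risk)` with published
#'   numbers at risk (currently informational).
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(time, survival, total_n, at_risk = NULL) {
  time <- as.numeric(time); survival <- as.numeric(survival)
  if (length(time) != length(survival) || length(time) < 1) {
    stop("time and survival must be non-empty vectors of equal length")
  }
  o <- order(time)
  time <- time[o]; survival <- survival[o]
  if (any(survival < 0 | survival > 1)) stop("survival values must lie in [0, 1]")
  if (any(diff(survival) > 1e-9)) {
    stop("survival values must be non-increasing in time")
  }
  survival <- cummin(survival)  # iron out sub-tolerance digitiser wobble
  if (time[1] > 0 || survival[1] < 1) {
    time <- c(0, time); survival <- c(1, survival)
  }
  if (total_n < 1) stop("total_n must be >= 1")
  structure(list(points = data.frame(time = time, survival = survival),
                 total_n = as.integer(total_n), at_risk = at_risk),
            class = "digitized_curve")
}

#' Reconstruct pseudo individual patient data from a digitised curve
#'
#' Inverts a digitised Kaplan-Meier curve into `total_n` (time, event)
#' records whose Kaplan-Meier estimate tracks the input coordinates. Since
#' published curves rarely ship numbers-at-risk tables, the non-event mass
#' `total_n * S(t_last)` is assumed censored at a constant rate spread
#' uniformly over follow-up; within each digitised interval censorings are
#' placed in the first half and events are spread log-uniformly up to the
#' coordinate (survival decays smoothly in log event time, so this tracks
#' the within-interval path far better than lumping all events on the
#' coordinate), and the event count at each coordinate is chosen to
#' re-anchor the reconstructed Kaplan-Meier to the digitised value
#' (preventing rounding drift).
#'
#' @param curve A [digitized_curve()].
#' @return IPD `data.frame(time, event)` with exactly `total_n` rows.
#' @export
reconstruct_ipd <- function(curve) {
  stopifnot(inherits(curve, "digitized_curve"))
  n <- curve$total_n
  if (n < 2) stop("total_n must be >= 2 for reconstruction")
  pts <- curve$points
  m <- nrow(pts)
  if (m < 2) {
    warning("digitised curve has no drops: returning all-censored records at time 0")
    return(ipd_records(rep(0, n), rep(0, n)))
  }
  tms <- pts$time; S <- pts$survival
  t_last <- tms[m]
  cens_total <- n * S[m]          # expected never-event mass
  out_t <- numeric(0); out_e <- numeric(0)
  risk <- n; km <- 1; carry <- 0
  for (i in 2:m) {
    dt <- tms[i] - tms[i - 1]
    # censorings in (t[i-1], t[i]) at constant rate, carry-rounded
    c_exp <- if (t_last > 0) cens_total * dt / t_last + carry else 0
    c_i <- min(floor(c_exp + 0.5), risk)
    carry <- c_exp - c_i
    risk_after_cens <- risk - c_i
    d_i <- 0L
    tt <- numeric(0)
    if (risk_after_cens > 0 && km > 0) {
      d_i <- round(risk_after_cens * (1 - S[i] / km))
      d_i <- max(0L, min(d_i, risk_after_cens))
      if (d_i > 0) {
        km <- km * (1 - d_i / risk_after_cens)
        # log-uniform spread finishing exactly on the digitised coordinate
        # (a single event sits on it, preserving exact-curve inversion)
        u <- seq_len(d_i) / d_i
        tt <- if (tms[i - 1] > 0) {
          exp(log(tms[i - 1]) + (log(tms[i]) - log(tms[i - 1])) * u)
        } else {
          tms[i - 1] + dt * u
        }
      }
    }
    if (c_i > 0) {
      # censorings precede the interval's first event, as assumed by the
      # event-count arithmetic above
      c_end <- if (d_i > 0) tt[1] else tms[i]
      out_t <- c(out_t, tms[i - 1] + (c_end - tms[i - 1]) * (seq_len(c_i) - 0.5) / c_i)
      out_e <- c(out_e, rep(0, c_i))
    }
    if (d_i > 0) {
      out_t <- c(out_t, tt)
      out_e <- c(out_e, rep(1, d_i))
    }
    risk <- risk_after_cens - d_i
  }
  if (risk > 0) {  # survivors administratively censored at last coordinate
    out_t <- c(out_t, rep(t_last, risk))
    out_e <- c(out_e, rep(0, risk))
  }
  ipd_records(out_t, out_e)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function; at tied times events
#' are processed before censorings (the standard convention). Computed via
#' [survival::survfit()].
#'
#' @param records IPD `data.frame(time, event)`.
#' @return Object of class `km_estimate` with components `time`, `surv`,
#'   `n_event`, `n_censor`, `n`.
#' @export
km_estimate <- function(records) {
  if (is.null(records) || nrow(records) < 1) stop("at least one record required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(list(time = fit$time, surv = fit$surv,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = nrow(records)),
            class = "km_estimate")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km A [km_estimate()].
#' @param t Times at which to evaluate (years).
#' @return `S(t)` as a right-continuous step function starting at 1.
#' @export
km_surv_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  stats::stepfun(km$time, c(1, km$surv), right = FALSE)(t)
}

#' Fit a right-censored parametric survival model
#'
#' Maximum-likelihood fit (density contribution for events, survival
#' contribution for censored subjects) via [flexsurv::flexsurvreg()].
#'
#' @param records IPD `data.frame(time, event)`; at least 2 records with
#'   at least one event.
#' @param family One of [surv_families()].
#' @return A [parametric_survival()] with `loglik`, `aic`, `bic` populated;
#'   `n_obs` is the number of subjects.
#' @export
fit_parametric <- function(records, family) {
  family <- match.arg(family, names(.SURV_FAMILIES))
  if (nrow(records) < 2) stop("need at least 2 records")
  if (sum(records$event) < 1) {
    stop("no events in data: parametric likelihood is undetermined")
  }
  dat <- records
  dat$time <- pmax(dat$time, 1e-9)  # log-time families need t > 0
  args <- list(survival::Surv(time, event) ~ 1, data = dat,
               dist = .SURV_FAMILIES[[family]],
               control = list(reltol = 1e-10, maxit = 500))
  if (family == "gompertz") {
    # moment-style start: near-exponential shape with the crude event rate
    args$inits <- c(1e-3, sum(dat$event) / sum(dat$time))
  }
  fit <- tryCatch(
    do.call(flexsurv::flexsurvreg, args),
    error = function(e) stop(sprintf("fit for family '%s' failed to converge: %s",
                                     family, conditionMessage(e)), call. = FALSE)
  )
  est <- fit$res[, "est"]
  names(est) <- rownames(fit$res)
  names(est)[names(est) == "mu"] <- "meanlog"     # lnorm naming guard
  names(est)[names(est) == "sigma"] <- "sdlog"
  parametric_survival(family, est, loglik = fit$loglik, n_obs = nrow(records))
}

#' Fit all six candidate families
#'
#' @param records IPD data frame.
#' @param families Families to screen (default all six).
#' @return Named list of `parametric_survival` fits; families that fail to
#'   converge are dropped with a warning.
#' @export
fit_all_families <- function(records, families = surv_families()) {
  fits <- list()
  for (f in families) {
    r <- tryCatch(fit_parametric(records, f), error = function(e) e)
    if (inherits(r, "error")) {
      warning(sprintf("dropping family '%s': %s", f, conditionMessage(r)))
    } else {
      fits[[f]] <- r
    }
  }
  fits
}

#' Select a survival model by information criteria
#'
#' Picks the candidate with the lowest AIC; ties are broken by lowest BIC,
#' then by fewer parameters. BIC uses the number of subjects, not events.
#'
#' @param candidates List of fitted [parametric_survival()] objects on the
#'   same data.
#' @return The winning model, with a ranking `data.frame` attached as
#'   attribute `"ranking"` (family, loglik, n_params, aic, bic, rank).
#' @export
select_model <- function(candidates) {
  if (length(candidates) < 1) stop("need at least one candidate")
  n_obs <- vapply(candidates, function(x) as.integer(x$n_obs), integer(1))
  if (length(unique(n_obs)) != 1) {
    stop("candidates were fitted on different numbers of observations")
  }
  aic <- vapply(candidates, function(x) x$aic, numeric(1))
  bic <- vapply(candidates, function(x) x$bic, numeric(1))
  k <- vapply(candidates, function(x) x$n_params, numeric(1))
  if (any(is.na(aic))) stop("all candidates must carry a log-likelihood")
  o <- order(aic, bic, k)
  ranking <- data.frame(
    family = vapply(candidates, function(x) x$family, character(1)),
    params = vapply(candidates, function(x)
      paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = "; "),
      character(1)),
    loglik = vapply(candidates, function(x) x$loglik, numeric(1)),
    n_params = k, n_obs = n_obs, aic = aic, bic = bic,
    row.names = NULL
  )[o, ]
  ranking$rank <- seq_len(nrow(ranking))
  best <- candidates[[o[1]]]
  attr(best, "ranking") <- ranking
  best
}
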