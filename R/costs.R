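# Costing and QALY accrual: drug acquisition with vial wastage,
# administration, monitoring schedule, adverse events, post-progression
# scenario pathways and end-of-life care.

#' Health-state utility set
#'
#' @param u_pfs Utility while progression-free (base 0.83).
#' @param u_pd Utility in progressive disease (base 0.63).
#' @param ae_disutility One-off utility decrement for treatment-emergent
#'   adverse events (base -0.42, applied in cycle 1; see [arm_totals()]).
#' @param enforce_order Require `u_pd <= u_pfs`? The base case always
#'   satisfies this; probabilistic draws sample the two utilities
#'   independently, so their joint ordering is not constrained there.
#' @return Object of class `utility_set`.
#' @export
utility_set <- function(u_pfs = 0.83, u_pd = 0.63, ae_disutility = -0.42,
                        enforce_order = TRUE) {
  if (u_pfs < 0 || u_pfs > 1 || u_pd < 0 || u_pd > 1) stop("utilities must lie in [0, 1]")
  if (enforce_order && u_pd > u_pfs) stop("u_pd must not exceed u_pfs")
  if (ae_disutility > 0) stop("ae_disutility must be <= 0")
  structure(list(u_pfs = u_pfs, u_pd = u_pd, u_dead = 0,
                 ae_disutility = ae_disutility), class = "utility_set")
}

#' Vials needed to deliver a dose
#'
#' Whole vials are purchased and surplus discarded, so the count is the
#' ceiling of dose over vial size; a zero dose needs zero vials.
#'
#' @param dose_mg Dose to deliver (mg), >= 0.
#' @param vial_mg Vial (or tablet) strength (mg), > 0.
#' @return Integer vial count.
#' @export
vials_required <- function(dose_mg, vial_mg) {
  if (any(dose_mg < 0)) stop("dose_mg must be >= 0")
  if (any(vial_mg <= 0)) stop("vial_mg must be > 0")
  as.integer(ceiling(round(dose_mg / vial_mg, 9)))
}

# dose in mg for one administration of a regimen component
.component_dose <- function(comp, bsa) {
  if (!is.null(comp$dose_per_m2)) {
    d <- comp$dose_per_m2 * bsa
    if (!is.null(comp$cap_mg)) d <- min(d, comp$cap_mg)
    d
  } else if (!is.null(comp$mg_per_day)) {
    comp$mg_per_day  # per-day dose; days handled by caller
  } else {
    stop(sprintf("regimen component '%s' has no dose rule", comp$drug))
  }
}

#' Drug acquisition cost of one treatment cycle
#'
#' Sums, over the scheduled components of a regimen, the whole-vial
#' purchase cost of each body-surface-area (or capped, or fixed daily)
#' dose. Daily oral components are priced per tablet per day of
#' administration (e.g. prednisone 100 mg/day = 20 x 5 mg tablets, 5 days).
#'
#' @param regimen List of regimen components; each has `drug`, a dose rule
#'   (`dose_per_m2` with optional `cap_mg`, or `mg_per_day` + `days`).
#' @param book A cost book (see [validate_config()]), providing `bsa` and
#'   `drugs[[name]] = list(price, unit_mg)`.
#' @return Acquisition cost (USD) per cycle.
#' @export
cycle_drug_cost <- function(regimen, book) {
  total <- 0
  for (comp in regimen) {
    spec <- book$drugs[[comp$drug]]
    if (is.null(spec) || is.null(spec$price)) {
      stop(sprintf("no price for drug '%s' in cost book", comp$drug))
    }
    if (!is.null(comp$mg_per_day)) {
      units <- vials_required(comp$mg_per_day, spec$unit_mg) * comp$days
    } else {
      units <- vials_required(.component_dose(comp, book$bsa), spec$unit_mg)
    }
    total <- total + units * spec$price
  }
  total
}

#' Expected adverse-event management cost
#'
#' Expected per-patient cost of the listed adverse events, each costed
#' once at its incidence (events are assumed to occur during the initial
#' treatment cycle; discounting at the cycle-1 midpoint is applied by
#' [arm_totals()]).
#'
#' @param incidence Named numeric vector of per-arm AE incidences in
#'   \[0, 1\].
#' @param unit_cost Named numeric vector of per-episode costs (USD),
#'   matched by name to `incidence`.
#' @return Expected (undiscounted) cost in USD.
#' @export
ae_expected_cost <- function(incidence, unit_cost) {
  if (any(incidence < 0 | incidence > 1)) stop("incidence must lie in [0, 1]")
  if (any(unit_cost < 0)) stop("unit costs must be >= 0")
  nm <- names(incidence)
  if (!is.null(nm) && !is.null(names(unit_cost))) {
    missing <- setdiff(nm, names(unit_cost))
    if (length(missing)) stop("no AE cost for: ", paste(missing, collapse = ", "))
    unit_cost <- unit_cost[nm]
  }
  sum(incidence * unit_cost)
}

# lab/imaging schedule (per DESIGN of the monitoring cadence):
# every treatment cycle: hematology, serum chemistry, hepatic/renal +
# electrolytes, urinalysis, ECG; cycle 1 only: immunoglobulin, coagulation,
# echocardiography; CT every second cycle while progression-free.
.lab_every_cycle <- c("hematology", "serum_chemistry", "hepatic_renal", "urinalysis", "ecg")
.lab_first_cycle <- c("immunoglobulin", "coagulation", "echocardiography")

#' Monitoring (laboratory and imaging) cost
#'
#' Applies the laboratory panel at every treatment cycle, the one-off
#' baseline panel at cycle 1, and contrast-enhanced CT at every second
#' treatment cycle, each weighted by the start-of-cycle progression-free
#' occupancy and discounted at the cycle start.
#'
#' @param trace An [state_occupancy()] trace.
#' @param book Cost book with a `labs` price list.
#' @param settings A [model_settings()].
#' @param n_treatment_cycles Number of treatment cycles (default 6).
#' @return Discounted monitoring cost (USD).
#' @export
monitoring_cost <- function(trace, book, settings = attr(trace, "settings"),
                            n_treatment_cycles = 6) {
  labs <- book$labs
  per_cycle <- sum(unlist(labs[.lab_every_cycle]))
  first_only <- sum(unlist(labs[.lab_first_cycle]))
  kk <- seq_len(min(n_treatment_cycles, nrow(trace)))
  w <- trace$pfs_start[kk] * discount_factor(trace$t_start[kk], settings$discount_rate)
  cost <- sum(per_cycle * w) + first_only * w[1]
  ct_cycles <- kk[kk %% 2 == 0]
  cost + sum(labs$ct * w[match(ct_cycles, kk)])
}

#' Post-progression treatment pathway
#'
#' One of the five modelled salvage pathways; the magnitudes are analyst
#' inputs (the trial publication does not print them).
#'
#' @param id Scenario id, 1-5.
#' @param label Human-readable pathway label.
#' @param postprogression_cost One-off cost per incident progressor (USD).
#' @param pd_cycle_cost Recurring cost per cycle spent progressed (USD).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, label, postprogression_cost = 0, pd_cycle_cost = 0) {
  if (!id %in% 1:5) stop("scenario id must be 1..5")
  if (postprogression_cost < 0 || pd_cycle_cost < 0) stop("scenario costs must be >= 0")
  structure(list(id = as.integer(id), label = label,
                 postprogression_cost = postprogression_cost,
                 pd_cycle_cost = pd_cycle_cost), class = "scenario_spec")
}

#' Probability of experiencing at least one adverse event
#'
#' Under independence of the listed events.
#'
#' @param incidence Numeric vector of AE incidences.
#' @return `1 - prod(1 - incidence)`.
#' @export
p_any_ae <- function(incidence) 1 - prod(1 - incidence)

#' Discounted cost breakdown and QALYs for one arm
#'
#' Assembles the six cost components — drug acquisition and administration
#' over the six treatment cycles (weighted by start-of-cycle PFS occupancy,
#' discounted at cycle start), monitoring, adverse-event management
#' (cycle-1 midpoint), post-progression pathway costs (one-off per incident
#' progressor at the cycle midpoint plus any recurring per-cycle PD cost),
#' and end-of-life care (per incident death at the cycle midpoint) — and
#' the QALY total: half-cycle corrected utility accrual minus a one-off
#' cycle-1 adverse-event disutility `|ae_disutility| * P(any AE) * cycle
#' length in years`.
#'
#' @param trace An [state_occupancy()] trace for the arm.
#' @param book Cost book (see [validate_config()]).
#' @param regimen Regimen component list for the arm (see
#'   [cycle_drug_cost()]).
#' @param ae_risks Named incidence vector for the arm.
#' @param scenario A [scenario_spec()].
#' @param utilities A [utility_set()].
#' @param settings A [model_settings()].
#' @return List with `breakdown` (named component costs plus `total`, USD)
#'   and `qalys`.
#' @export
arm_totals <- function(trace, book, regimen, ae_risks, scenario, utilities,
                       settings = attr(trace, "settings")) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(utilities, "utility_set"))
  r <- settings$discount_rate
  n_treat <- min(6, nrow(trace))
  kk <- seq_len(n_treat)
  w_treat <- trace$pfs_start[kk] * discount_factor(trace$t_start[kk], r)
  mid <- .trace_mid(trace); len <- .trace_len(trace)
  df_mid <- discount_factor(mid, r)

  acquisition <- cycle_drug_cost(regimen, book) * sum(w_treat)
  administration <- sum(unlist(book$administration)) * sum(w_treat)
  monitoring <- monitoring_cost(trace, book, settings, n_treat)
  ae <- ae_expected_cost(ae_risks, unlist(book$ae_costs)) * df_mid[1]
  pd_mean <- (trace$pd_start + trace$pd_end) / 2
  post_progression <-
    scenario$postprogression_cost * sum(trace$new_pd * df_mid) +
    scenario$pd_cycle_cost * sum(pd_mean * (len / settings$cycle_years) * df_mid)
  terminal <- book$terminal * sum(trace$new_dead * df_mid)

  breakdown <- c(acquisition = acquisition, administration = administration,
                 monitoring = monitoring, ae = ae,
                 post_progression = post_progression, terminal = terminal)
  breakdown <- c(breakdown, total = sum(breakdown))

  qalys <- accrue(trace, c(utilities$u_pfs, utilities$u_pd, 0), settings) -
    abs(utilities$ae_disutility) * p_any_ae(ae_risks) *
      settings$cycle_years * df_mid[1]
  list(breakdown = breakdown, qalys = qalys)
}

#' Write per-arm cost breakdowns to CSV
#'
#' @param breakdowns Named list (by arm) of breakdown vectors from
#'   [arm_totals()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_breakdown <- function(breakdowns, path) {
  rows <- do.call(rbind, lapply(names(breakdowns), function(arm) {
    b <- breakdowns[[arm]]
    data.frame(arm = arm, component = names(b), cost_usd = as.numeric(b))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
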