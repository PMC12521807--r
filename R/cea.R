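# Incremental cost-effectiveness: ICERs with dominance handling, net
# monetary benefit, willingness-to-pay thresholds, currency conversion,
# and the published base-case results table used for consistency checks.

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental effectiveness (QALYs).
#' @return List with `value` (USD/QALY, `NA` when flagged) and `flag`:
#'   `"icer"` for an ordinary ratio, `"dominant"` (cheaper and more
#'   effective), `"dominated"` (costlier and less effective), or
#'   `"undefined"` (zero incremental effect).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    list(value = NA_real_, flag = "undefined")
  } else if (delta_cost < 0 && delta_qaly > 0) {
    list(value = NA_real_, flag = "dominant")
  } else if (delta_cost > 0 && delta_qaly < 0) {
    list(value = NA_real_, flag = "dominated")
  } else {
    list(value = delta_cost / delta_qaly, flag = "icer")
  }
}

#' Net monetary benefit
#'
#' @param cost Total cost (USD).
#' @param qaly Total QALYs.
#' @param wtp Willingness-to-pay threshold (USD/QALY), >= 0.
#' @return `qaly * wtp - cost`.
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  qaly * wtp - cost
}

#' Willingness-to-pay threshold from GDP per capita
#'
#' @param gdp GDP per capita (USD), > 0.
#' @param multiplier Threshold multiple (1, 2 or 3 in common practice).
#' @return `gdp * multiplier`, rounded to 2 decimals for reporting.
#' @export
wtp_from_gdp <- function(gdp, multiplier) {
  if (any(gdp <= 0)) stop("gdp must be > 0")
  if (any(multiplier < 1)) stop("multiplier must be >= 1")
  round(gdp * multiplier, 2)
}

#' Convert USD to CNY
#'
#' @param usd Amount in USD.
#' @param rate Exchange rate (CNY per USD), > 0.
#' @return Amount in CNY, rounded to 2 decimals.
#' @export
convert_currency <- function(usd, rate = 7.2338) {
  if (any(rate <= 0)) stop("rate must be > 0")
  round(usd * rate, 2)
}

#' Compare two strategies
#'
#' @param cost_a,qaly_a Totals for the intervention arm.
#' @param cost_b,qaly_b Totals for the comparator arm.
#' @param wtp Willingness-to-pay threshold for the NMB column (USD/QALY).
#' @return Object of class `cea_result`: arm totals, incremental cost and
#'   QALYs, ICER value/flag, and incremental NMB at `wtp`.
#' @export
cea_compare <- function(cost_a, qaly_a, cost_b, qaly_b, wtp = 37075.95) {
  delta_cost <- cost_a - cost_b
  delta_qaly <- qaly_a - qaly_b
  ic <- icer(delta_cost, delta_qaly)
  structure(list(cost_a = cost_a, cost_b = cost_b,
                 qaly_a = qaly_a, qaly_b = qaly_b,
                 delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icer = ic$value, icer_flag = ic$flag,
                 wtp = wtp,
                 inmb = nmb(delta_cost, delta_qaly, wtp)),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Incremental cost: %.2f USD, incremental QALYs: %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (x$icer_flag == "icer") {
    cat(sprintf("ICER: %.2f USD/QALY\n", x$icer))
  } else {
    cat(sprintf("ICER: %s\n", x$icer_flag))
  }
  cat(sprintf("Incremental NMB at WTP %.2f: %.2f USD\n", x$wtp, x$inmb))
  invisible(x)
}

#' Published base-case results (reference data)
#'
#' The peer-reviewed base-case cost-effectiveness results for H-CHOP vs
#' R-CHOP across the five post-progression scenarios, as printed
#' (total costs and QALYs per arm, ICER per scenario). Bundled as reference
#' data for exact-arithmetic reproduction and internal-consistency checks;
#' these numbers are inputs, not outputs, of this package.
#'
#' @return `data.frame` with columns `scenario`, `label`, `arm`,
#'   `total_cost_usd`, `qalys`, `icer_usd_per_qaly` (ICER carried on the
#'   intervention row).
#' @export
published_results <- function() {
  data.frame(
    scenario = rep(1:5, each = 2),
    label = rep(c("Transplant-eligible: DHAP + ASCT",
                  "Transplant-eligible: novel agent + DHAP + ASCT",
                  "Not transplant-eligible: DHAP alone",
                  "Not transplant-eligible: novel agents (R2+BTK or Pola-BR)",
                  "Primary refractory/early relapse: CAR-T"), each = 2),
    arm = rep(c("hchop", "rchop"), times = 5),
    total_cost_usd = c(94467.21, 72498.21,
                       98753.03, 75580.80,
                       31438.75, 27164.63,
                       52977.72, 42656.66,
                       783525.17, 568107.00),
    qalys = rep(c(7.11, 6.50), times = 5),
    icer_usd_per_qaly = as.numeric(rbind(
      c(36386.92, 38379.79, 7079.15, 17094.61, 356793.77), NA))
  )
}

#' Published economic constants (reference data)
#'
#' @return List with the printed `gdp_per_capita` (USD, 2023 China) and
#'   `exchange_rate` (CNY per USD, April 2024).
#' @export
published_constants <- function() {
  list(gdp_per_capita = 12358.65, exchange_rate = 7.2338)
}

#' Check scenario-invariance of incremental QALYs in a results table
#'
#' Scenarios differ only in post-progression costs, so the incremental
#' QALY implied by each scenario (incremental cost divided by ICER) must
#' be scenario-invariant. Applies to any Table-2-shaped results table
#' (including [published_results()]).
#'
#' @param results `data.frame` shaped like [published_results()].
#' @return List with `implied_delta_qaly` per scenario (`NA` where the
#'   ICER is flagged rather than numeric), `delta_qaly` per scenario from
#'   the QALY columns, their `spread`s (max - min over available values),
#'   and `consistent` (every available spread below `tol`).
#' @param tol Allowed spread in QALYs (default 1e-3, printed-rounding
#'   scale).
#' @export
check_results_consistency <- function(results, tol = 1e-3) {
  sc <- sort(unique(results$scenario))
  one <- function(s, f) {
    sub <- results[results$scenario == s, ]
    f(sub)
  }
  implied <- vapply(sc, one, numeric(1), f = function(sub) {
    dc <- sub$total_cost_usd[sub$arm == "hchop"] - sub$total_cost_usd[sub$arm == "rchop"]
    dc / sub$icer_usd_per_qaly[sub$arm == "hchop"]
  })
  dq <- vapply(sc, one, numeric(1), f = function(sub) {
    sub$qalys[sub$arm == "hchop"] - sub$qalys[sub$arm == "rchop"]
  })
  names(implied) <- names(dq) <- paste0("scenario", sc)
  rng <- function(x) if (all(is.na(x))) NA_real_ else diff(range(x, na.rm = TRUE))
  spreads <- c(implied = rng(implied), delta_qaly = rng(dq))
  list(implied_delta_qaly = implied, delta_qaly = dq, spread = spreads,
       consistent = all(spreads <= tol, na.rm = TRUE))
}

#' Write a Table-2-style results table
#'
#' @param results Results `data.frame` (see [published_results()] for the
#'   shape); CNY-converted columns are appended using `rate`.
#' @param path Output CSV path.
#' @param rate Exchange rate, CNY per USD.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, rate = 7.2338) {
  results$total_cost_cny <- convert_currency(results$total_cost_usd, rate)
  results$icer_cny_per_qaly <- ifelse(is.na(results$icer_usd_per_qaly), NA,
                                      convert_currency(results$icer_usd_per_qaly, rate))
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
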