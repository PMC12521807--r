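cfg <- default_config()
book <- cost_book(cfg)

test_that("vial counts are ceilings of dose over vial size", {
  expect_equal(vials_required(375 * 1.73, 100), 7L)   # rituximab/biosimilar
  expect_equal(vials_required(750 * 1.73, 1000), 2L)  # cyclophosphamide
  expect_equal(vials_required(min(1.4 * 1.73, 2), 1), 2L)  # capped vincristine
  expect_equal(vials_required(0, 100), 0L)
  expect_equal(vials_required(100, 100), 1L)  # exact fit buys exactly one
  expect_error(vials_required(-1, 100), ">= 0")
  expect_error(vials_required(10, 0), "> 0")
})

test_that("per-cycle drug acquisition follows vial-wastage arithmetic", {
  hanlikang <- list(list(drug = "hanlikang", dose_per_m2 = 375))
  expect_equal(cycle_drug_cost(hanlikang, book), 7 * 193.09)
  expect_equal(cycle_drug_cost(list(), book), 0)
  prednisone <- list(list(drug = "prednisone", mg_per_day = 100, days = 5))
  expect_equal(cycle_drug_cost(prednisone, book), 20 * 5 * 1.61)
  # full H-CHOP cycle: antibody + CHOP backbone
  full <- regimen_for_arm(cfg, "hchop")
  expect_equal(cycle_drug_cost(full, book),
               7 * 193.09 + 2 * 26.61 + 9 * 10.88 + 2 * 38.29 + 20 * 5 * 1.61)
  expect_error(cycle_drug_cost(list(list(drug = "nivolumab", dose_per_m2 = 3)), book),
               "nivolumab")
})

test_that("expected adverse-event cost is the incidence-cost dot product", {
  expect_equal(ae_expected_cost(c(x = 0.5), c(x = 100)), 50)
  expect_equal(ae_expected_cost(setNames(rep(0, 3), letters[1:3]),
                                setNames(c(10, 20, 30), letters[1:3])), 0)
  inc <- unlist(cfg$ae_risks$hchop)
  costs <- unlist(cfg$costbook$ae_costs)
  expect_equal(length(inc), 17)
  expect_equal(ae_expected_cost(inc, costs), sum(inc * costs[names(inc)]))
  expect_error(ae_expected_cost(c(x = 1.5), c(x = 1)), "\\[0, 1\\]")
  expect_error(ae_expected_cost(c(y = 0.5), c(x = 1)), "no AE cost")
})

test_that("monitoring cost follows the treatment-phase schedule", {
  s0 <- model_settings(discount_rate = 0)
  tr_full <- state_occupancy(const_surv(), const_surv(), s0)
  # CT component: every second of six treatment cycles at full occupancy
  book_noct <- book
  book_noct$labs$ct <- 0
  ct_component <- monitoring_cost(tr_full, book, s0) - monitoring_cost(tr_full, book_noct, s0)
  expect_equal(ct_component, 3 * 308.81)
  # no progression-free occupancy -> no monitoring
  tr0 <- tr_full
  tr0$pfs_start <- tr0$pfs_end <- rep(0, nrow(tr0))
  expect_equal(monitoring_cost(tr0, book, s0), 0)
  # linearity in prices
  book2 <- book
  book2$labs <- lapply(book$labs, function(x) 2 * x)
  expect_equal(monitoring_cost(tr_full, book2, s0), 2 * monitoring_cost(tr_full, book, s0))
})

test_that("arm totals vanish when all prices and utilities are zero", {
  tr <- state_occupancy(hchop_os(), hchop_pfs(), model_settings())
  zero_book <- book
  zero_book$drugs <- lapply(book$drugs, function(d) list(price = 0, unit_mg = d$unit_mg))
  zero_book$administration <- lapply(book$administration, function(x) 0)
  zero_book$labs <- lapply(book$labs, function(x) 0)
  zero_book$ae_costs <- lapply(book$ae_costs, function(x) 0)
  zero_book$terminal <- 0
  res <- arm_totals(tr, zero_book, regimen_for_arm(cfg, "hchop"),
                    unlist(cfg$ae_risks$hchop),
                    scenario_spec(1, "zero", 0, 0),
                    utility_set(0, 0, 0))
  expect_equal(unname(res$breakdown[["total"]]), 0)
  expect_equal(res$qalys, 0)
})

test_that("undiscounted terminal cost telescopes to cumulative mortality", {
  s0 <- model_settings(discount_rate = 0)
  tr <- state_occupancy(hchop_os(), hchop_pfs(), s0)
  res <- arm_totals(tr, book, regimen_for_arm(cfg, "hchop"),
                    unlist(cfg$ae_risks$hchop), scenario_spec(3, "s", 0, 0),
                    utilities_from_config(cfg), s0)
  expect_equal(unname(res$breakdown[["terminal"]]),
               1036.80 * tr$dead_end[nrow(tr)], tolerance = 1e-12)
})

test_that("breakdown components sum to the total", {
  tr <- state_occupancy(hchop_os(), hchop_pfs(), model_settings())
  res <- arm_totals(tr, book, regimen_for_arm(cfg, "hchop"),
                    unlist(cfg$ae_risks$hchop),
                    scenario_from_config(cfg, 1), utilities_from_config(cfg))
  b <- res$breakdown
  expect_equal(unname(b[["total"]]),
               sum(b[setdiff(names(b), "total")]), tolerance = 1e-9)
})

test_that("arm totals agree with an independent spreadsheet-style recomputation", {
  settings <- model_settings()
  tr <- state_occupancy(hchop_os(), hchop_pfs(), settings)
  res <- arm_totals(tr, book, regimen_for_arm(cfg, "hchop"),
                    unlist(cfg$ae_risks$hchop), scenario_spec(3, "zero-pp", 0, 0),
                    utilities_from_config(cfg), settings)

  # -- independent recomputation from first principles --
  cyc <- 21 / 365.25
  b <- seq(0, 10, by = cyc); if (b[length(b)] < 10) b <- c(b, 10)
  S_os <- lnorm_surv(b, 3.284, 1.938)
  S_pfs <- lnorm_surv(b, 2.998, 1.884)
  pfs <- pmin(S_pfs, S_os); dead <- 1 - S_os; pd <- S_os - pfs
  disc <- function(t) 1.05^(-t)
  mid <- (b[-length(b)] + b[-1]) / 2
  len <- diff(b)

  drug <- 7 * 193.09 + 2 * 26.61 + 9 * 10.88 + 2 * 38.29 + 20 * 5 * 1.61
  admin <- 19.35 + 67.58 + 5.26
  w_treat <- pfs[1:6] * disc(b[1:6])
  labs_per_cycle <- 3.46 + 23.50 + 18.07 + 4.15 + 3.73
  first_only <- 8.72 + 9.20 + 39.12
  monitoring <- labs_per_cycle * sum(w_treat) + first_only * w_treat[1] +
    308.81 * sum(pfs[c(2, 4, 6)] * disc(b[c(2, 4, 6)]))
  inc <- c(0.855, 0.790, 0.385, 0.170, 0.230, 0.245, 0.160, 0.175, 0.155,
           0.110, 0.095, 0.140, 0.135, 0.095, 0.080, 0.025, 0.025)
  ae_cost <- c(118.70, 3881.64, 63.60, 334.78, 273.00, 1372.98, 273.00, 150.00,
               65.52, 344.93, 1991.14, 493.90, 71.67, 1338.40, 290.65, 3881.64,
               6641.76)
  ae <- sum(inc * ae_cost) * disc(mid[1])
  terminal <- 1036.80 * sum(diff(dead) * disc(mid))
  expected_total <- (drug + admin) * sum(w_treat) + monitoring + ae + terminal

  u_curve <- 0.83 * pfs + 0.63 * pd
  expected_qalys <- sum((u_curve[-length(u_curve)] + u_curve[-1]) / 2 * len * disc(mid)) -
    0.42 * (1 - prod(1 - inc)) * cyc * disc(mid[1])

  expect_equal(unname(res$breakdown[["total"]]), expected_total, tolerance = 1e-9)
  expect_equal(res$qalys, expected_qalys, tolerance = 1e-9)
})

test_that("cost components are monotone in unit prices", {
  ev <- build_evaluator(cfg, 1)
  base <- ev()$breakdowns$hchop
  up <- ev(list("costbook.drugs.hanlikang.price" = 193.09 * 1.2))$breakdowns$hchop
  dn <- ev(list("costbook.drugs.hanlikang.price" = 193.09 * 0.8))$breakdowns$hchop
  expect_gt(up[["acquisition"]], base[["acquisition"]])
  expect_lt(dn[["acquisition"]], base[["acquisition"]])
  up2 <- ev(list("costbook.terminal" = 1036.80 * 1.2))$breakdowns$hchop
  expect_gt(up2[["terminal"]], base[["terminal"]])
})

test_that("computing in CNY equals the USD result times the exchange rate", {
  rate <- 7.2338
  cny_cfg <- cfg
  cny_cfg$costbook$drugs <- lapply(cfg$costbook$drugs, function(d)
    list(price = d$price * rate, unit_mg = d$unit_mg))
  for (blk in c("administration", "labs", "ae_costs")) {
    cny_cfg$costbook[[blk]] <- lapply(cfg$costbook[[blk]], function(x) x * rate)
  }
  cny_cfg$costbook$terminal <- cfg$costbook$terminal * rate
  cny_cfg$scenarios <- lapply(cfg$scenarios, function(s) {
    s$postprogression_cost <- s$postprogression_cost * rate
    s$pd_cycle_cost <- s$pd_cycle_cost * rate
    s
  })
  usd <- build_evaluator(cfg, 1)()
  cny <- build_evaluator(validate_config(unclass(cny_cfg)), 1)()
  expect_equal(cny$cost_a, usd$cost_a * rate, tolerance = 1e-6)
  expect_equal(cny$cost_b, usd$cost_b * rate, tolerance = 1e-6)
})

test_that("removing discounting never decreases any cost component", {
  tr <- state_occupancy(hchop_os(), hchop_pfs(), model_settings())
  s0 <- model_settings(discount_rate = 0)
  tr0 <- state_occupancy(hchop_os(), hchop_pfs(), s0)
  args <- list(book, regimen_for_arm(cfg, "hchop"), unlist(cfg$ae_risks$hchop),
               scenario_from_config(cfg, 1), utilities_from_config(cfg))
  disc <- do.call(arm_totals, c(list(tr), args))$breakdown
  undisc <- do.call(arm_totals, c(list(tr0), args, list(s0)))$breakdown
  expect_true(all(undisc >= disc - 1e-12))
})
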