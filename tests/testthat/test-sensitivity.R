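cfg <- default_config()

test_that("parameter specs default to plus/minus 20% bounds", {
  s <- param_spec("x", 100, family = "gamma")
  expect_equal(c(s$lower, s$upper), c(80, 120))
  neg <- param_spec("d", -0.42, family = "beta")
  expect_equal(c(neg$lower, neg$upper), c(-0.504, -0.336))
  expect_error(param_spec("bad", 1, lower = 2, upper = 3), "lower <= base")
  # probability bounds above 1 are truncated
  p <- param_spec("risk", 0.855, family = "beta")
  expect_equal(p$upper, 1)
})

test_that("method-of-moments samplers hit the stated closed forms", {
  # symmetric beta: mean 0.5, SD 0.1 -> alpha = beta = 12
  s <- param_spec("u", 0.5, lower = 0.5 - 1.96 * 0.1, upper = 0.5 + 1.96 * 0.1,
                  family = "beta")
  d <- attr(fit_sampling_distribution(s), "dist")
  expect_equal(d$alpha, 12, tolerance = 1e-9)
  expect_equal(d$beta, 12, tolerance = 1e-9)
  # gamma from the biosimilar price bounds
  g <- param_spec("price", 193.09, 154.47, 231.71, family = "gamma")
  dg <- attr(fit_sampling_distribution(g), "dist")
  sd_expected <- (231.71 - 154.47) / 3.92
  expect_equal(sd_expected, 19.704, tolerance = 1e-3)
  expect_equal(dg$shape, (193.09 / sd_expected)^2, tolerance = 1e-9)
  expect_equal(dg$shape, 96.0, tolerance = 0.1 / 96)
  expect_equal(dg$rate, dg$shape / 193.09, tolerance = 1e-9)
  # infeasible beta moments are rejected by name
  expect_error(
    fit_sampling_distribution(param_spec("wild", 0.5, -1.5, 2.5, family = "beta")),
    "wild")
})

test_that("samplers are mean-unbiased and respect their supports", {
  set.seed(31)
  for (s in list(param_spec("c", 1036.80, family = "gamma"),
                 param_spec("u", 0.83, 0.66, 1.00, family = "beta"),
                 param_spec("d", -0.42, -0.50, -0.34, family = "beta"),
                 param_spec("r", 0.05, 0, 0.08, family = "beta-scaled",
                            support_upper = 0.08))) {
    x <- fit_sampling_distribution(s)(20000)
    expect_lt(abs(mean(x) - s$base), 0.01 * max(abs(s$base), 0.01))
    if (s$family == "gamma") expect_true(all(x >= 0))
    if (s$family == "beta" && s$base > 0) expect_true(all(x >= 0 & x <= 1))
    if (s$family == "beta" && s$base < 0) expect_true(all(x <= 0))
    if (s$family == "beta-scaled") expect_true(all(x >= 0 & x <= 0.08))
  }
})

test_that("configuration-derived specs cover Table-1 blocks with stated bounds", {
  specs <- build_param_specs(cfg, 1)
  expect_true("price_hanlikang" %in% names(specs))
  expect_equal(specs$price_hanlikang$lower, 193.09 * 0.8)
  # the discount rate is varied over 0-0.08, not plus/minus 20%
  expect_equal(c(specs$discount_rate$lower, specs$discount_rate$upper), c(0, 0.08))
  expect_equal(specs$discount_rate$family, "beta-scaled")
  # survival parameters are one-way only
  expect_true(specs$hchop_os_meanlog$dsa_only)
  # 17 AE risks per arm, truncated at 1
  risk_specs <- specs[startsWith(names(specs), "risk_hchop_")]
  expect_length(risk_specs, 17)
  expect_true(all(vapply(risk_specs, function(s) s$upper <= 1, logical(1))))
})

test_that("one-way DSA ranks by ICER range and keeps inert parameters last", {
  ev <- build_evaluator(cfg, 1)
  specs <- build_param_specs(cfg, 1)
  pick <- specs[c("price_hanlikang", "price_mabthera", "price_acetaminophen",
                  "utility_pfs", "hchop_os_meanlog")]
  tor <- one_way_dsa(ev, pick)
  expect_s3_class(tor, "tornado")
  expect_true(all(diff(tor$range[!tor$failed]) <= 1e-12))
  # premedication price feeds no costed component: zero range, ranked last
  inert <- tor[tor$name == "price_acetaminophen", ]
  expect_equal(inert$range, 0)
  expect_gt(which(tor$name == "price_acetaminophen"),
            which(tor$name == "price_hanlikang"))
  expect_false(is.null(attr(tor, "base_icer")))
})

test_that("a single-arm drug price shifts the ICER by its discounted quantity", {
  ev <- build_evaluator(cfg, 1)
  spec <- build_param_specs(cfg, 1)["price_hanlikang"]
  tor <- one_way_dsa(ev, spec)
  base <- ev()
  tr <- compute_traces(cfg)$hchop
  w_treat <- sum(tr$pfs_start[1:6] *
                   discount_factor(tr$t_start[1:6], cfg$settings$discount_rate))
  expected <- 7 * (spec[[1]]$upper - spec[[1]]$lower) * w_treat / base$delta_qaly
  expect_equal(tor$icer_high - tor$icer_low, expected, tolerance = 1e-6)
})

test_that("tornado ordering is invariant to input permutation", {
  ev <- build_evaluator(cfg, 1)
  specs <- build_param_specs(cfg, 1)
  pick <- specs[c("price_hanlikang", "price_mabthera", "utility_pfs", "terminal_cost")]
  t1 <- one_way_dsa(ev, pick)
  t2 <- one_way_dsa(ev, rev(pick))
  expect_equal(t1$name, t2$name)
  expect_equal(t1$range, t2$range)
})

test_that("PSA with fixed parameters reproduces the base case exactly", {
  ev <- build_evaluator(cfg, 1)
  base <- ev()
  specs <- list(param_spec("a", 193.09, family = "fixed",
                           target = "costbook.drugs.hanlikang.price"),
                param_spec("b", 0.83, family = "fixed",
                           target = "utilities.pfs.value"))
  draws <- run_psa(ev, specs, n_iter = 1, seed = 99)
  expect_equal(draws$delta_cost, base$delta_cost)
  expect_equal(draws$delta_qaly, base$delta_qaly)
})

test_that("PSA draws are reproducible for a given seed", {
  ev <- build_evaluator(cfg, 1)
  specs <- build_param_specs(cfg, 1)
  d1 <- run_psa(ev, specs, n_iter = 25, seed = 123)
  d2 <- run_psa(ev, specs, n_iter = 25, seed = 123)
  expect_identical(d1$delta_cost, d2$delta_cost)
  expect_identical(attr(d1, "samples"), attr(d2, "samples"))
  d3 <- run_psa(ev, specs, n_iter = 25, seed = 124)
  expect_false(identical(d1$delta_cost, d3$delta_cost))
})

test_that("PSA incremental QALYs are centred on the base case", {
  ev <- build_evaluator(cfg, 1)
  specs <- build_param_specs(cfg, 1)
  draws <- run_psa(ev, specs, n_iter = 400, seed = 7)
  base <- ev()
  mc_err <- 3 * sd(draws$delta_qaly) / sqrt(nrow(draws))
  expect_lt(abs(mean(draws$delta_qaly) - base$delta_qaly), mc_err)
})

test_that("CEAC follows its defining enumeration", {
  draws <- structure(data.frame(iteration = 1:2, delta_cost = c(10, 30),
                                delta_qaly = c(1, 1)),
                     class = c("psa_draws", "data.frame"))
  expect_equal(ceac(draws, 20)$probability, 0.5)
  # at wtp = 0 the probability is the fraction of cost-saving draws
  expect_equal(ceac(draws, 0)$probability, 0)
  dom <- structure(data.frame(iteration = 1:3, delta_cost = c(-1, -2, -3),
                              delta_qaly = c(1, 2, 0.5)),
                   class = c("psa_draws", "data.frame"))
  expect_equal(ceac(dom, c(0, 1e4, 1e5))$probability, c(1, 1, 1))
  # exact ties count as not cost-effective
  tie <- structure(data.frame(iteration = 1L, delta_cost = 20, delta_qaly = 1),
                   class = c("psa_draws", "data.frame"))
  expect_equal(ceac(tie, 20)$probability, 0)
  expect_error(ceac(draws, numeric(0)), "non-empty")
})

test_that("CEAC is non-decreasing in WTP when all draws gain QALYs", {
  set.seed(17)
  draws <- structure(data.frame(iteration = 1:200,
                                delta_cost = rnorm(200, 5000, 4000),
                                delta_qaly = runif(200, 0.05, 1)),
                     class = c("psa_draws", "data.frame"))
  p <- ceac(draws, seq(0, 1e5, by = 5000))$probability
  expect_true(all(diff(p) >= 0))
})
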