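test_that("parameter sampling honours distributions and the seed", {
  specs <- default_parameter_table()
  fixed <- specs
  fixed$distribution <- "fixed"
  expect_equal(unname(sample_parameters(fixed, 1)),
               fixed$base)
  d1 <- sample_parameters(specs, 77)
  d2 <- sample_parameters(specs, 77)
  expect_identical(d1, d2)
  expect_false(identical(d1, sample_parameters(specs, 78)))
  # infeasible beta moments are named
  bad <- tibble::tibble(name = "p_thing", component = "effects",
                        field = "p_adverse_diabetes", base = 0.5,
                        low = 0, high = 4, distribution = "beta")
  expect_error(sample_parameters(bad, 1), "p_thing")
})

test_that("lognormal RR draws centre on the published point estimate", {
  specs <- default_parameter_table()
  rr <- specs[specs$name == "rr_nonfatal_ihd", ]
  set.seed(123)
  draws <- stats::rlnorm(10000, log(rr$base),
                         (log(rr$high) - log(rr$low)) / 3.92)
  expect_equal(stats::median(draws), 0.67, tolerance = 0.01 / 0.67)
  # package sampler draws from the same law
  one <- vapply(1:2000, function(s)
    sample_parameters(rr, s)[["rr_nonfatal_ihd"]], numeric(1))
  expect_equal(stats::median(one), 0.67, tolerance = 0.02)
})

test_that("beta and gamma draws recover base-case means", {
  specs <- default_parameter_table()
  for (nm in c("statin_annual", "unemployment", "u_chronic_ihd")) {
    row <- specs[specs$name == nm, ]
    sdv <- (row$high - row$low) / 3.92
    draws <- vapply(1:4000, function(s) sample_parameters(row, s)[[nm]],
                    numeric(1))
    se <- sdv / sqrt(length(draws))
    expect_lt(abs(mean(draws) - row$base), 3 * se + 1e-9)
  }
})

test_that("one-way sensitivity has zero swing for inert parameters", {
  tab <- toy_transition_table()
  pair_eval <- make_pair_evaluator(0.15, NA, "soft", tab)
  inert <- tibble::tibble(name = "u_myopathy", component = "utilities",
                          field = "myopathy", base = 0.56, low = 0.56,
                          high = 0.56, distribution = "fixed")
  res <- one_way_sensitivity(pair_eval, inert)
  expect_equal(res$swing, 0)
})

test_that("statin price and discount rate move the ICER as expected", {
  tab <- toy_transition_table()
  # adverse events off so the treated arm is unambiguously more effective
  base <- model_params(effects = treatment_effects(p_adverse_diabetes = 0,
                                                   p_adverse_myopathy = 0))
  pair_eval <- make_pair_evaluator(0.15, NA, "soft", tab, base = base)
  base_out <- pair_eval(NULL)
  base_icer <- icer(base_out[1, ], base_out[2, ])
  res <- one_way_sensitivity(pair_eval, "statin_annual")
  expect_lt(res$icer_low, base_icer)
  expect_gt(res$icer_high, base_icer)
  # discount 0 -> 0.08: PV cost of the no-treatment arm falls monotonically
  costs <- vapply(c(0, 0.04, 0.08), function(r) {
    out <- pair_eval(c(discount_rate = r))
    out$cost[2]
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
})

test_that("PSA is reproducible with substream prefix discipline", {
  tab <- toy_transition_table()
  evg <- make_grid_evaluator(c(0.15, 0.18), "soft", tab)
  p1 <- run_psa(evg, n = 4, seed = 9)
  p2 <- run_psa(evg, n = 8, seed = 9)
  expect_equal(p1$draws, p2$draws[1:4, ])
  expect_equal(p1$outcomes, p2$outcomes[1:4])
  # all-fixed manifest reproduces the base case exactly
  fixed <- default_parameter_table()
  fixed$distribution <- "fixed"
  pf <- run_psa(evg, specs = fixed, n = 1, seed = 1)
  expect_equal(as.data.frame(pf$outcomes[[1]]),
               as.data.frame(evg(NULL)))
})

test_that("acceptability probabilities are proper and limit cases hold", {
  tab <- toy_transition_table()
  evg <- make_grid_evaluator(c(0.12, 0.15, 0.18), "soft", tab)
  psa <- run_psa(evg, n = 12, seed = 3)
  grid <- c(0, 5000, 10274, 30823)
  ac <- acceptability_curve(psa, grid)
  sums <- tapply(ac$probability, ac$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # WTP = 0: the cheapest strategy per iteration wins
  cheapest_wins <- mean(vapply(psa$outcomes, function(o) {
    which.min(o$cost) == which.max(0 * o$qalys - o$cost)
  }, logical(1)))
  expect_equal(cheapest_wins, 1)
  expect_error(acceptability_curve(psa, numeric(0)), "Empty WTP")
  # single strategy: probability one everywhere
  single <- structure(list(outcomes = list(tibble::tibble(
    label = "only", cost = 1, qalys = 1))), class = "psa_result")
  ac1 <- acceptability_curve(single, c(0, 100))
  expect_true(all(ac1$probability == 1))
})
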