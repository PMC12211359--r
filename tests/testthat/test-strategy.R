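test_that("threshold stratification is census-weighted and monotone", {
  out <- stratify_by_threshold(c(0.05, 0.10, 0.20), 0.18)
  expect_equal(out$eligible_fraction, 1 / 3)
  expect_equal(stratify_by_threshold(c(0.05, 0.2), 0)$eligible_fraction, 1)
  expect_equal(stratify_by_threshold(c(0.05, 0.2), 0.5)$eligible_fraction, 0)
  expect_error(stratify_by_threshold(numeric(0), 0.1), "Empty cohort")
  # ties count as eligible
  expect_equal(stratify_by_threshold(c(0.18), 0.18)$eligible_fraction, 1)
  # census weighting: weighted mean of cell fractions
  cw <- default_census_weights()
  set.seed(31)
  n <- 4000
  age <- stats::runif(n, 30, 75)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  risks <- stats::runif(n, 0, 0.4)
  res <- stratify_by_threshold(risks, 0.15, cw, sex = sex, age = age)
  manual <- sum(res$by_cell$eligible_fraction * res$by_cell$weight)
  expect_equal(res$eligible_fraction, manual)
  # monotone in threshold
  ths <- seq(0.05, 0.35, by = 0.05)
  fr <- vapply(ths, function(t)
    stratify_by_threshold(risks, t, cw, sex = sex, age = age)$eligible_fraction,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("null treatment leaves every strategy identical to no treatment", {
  tab <- toy_transition_table()
  eff <- null_effects()
  costs <- cost_set(statin_annual = 0, registration_annual = 0,
                    exam_per_visit = 0)
  utils_ <- utility_set(on_statin = 1)
  nt <- evaluate_strategy(strategy("soft", NA), tab, eff, costs, utils_,
                          comparability_override = tab)
  for (th in c(0.12, 0.18)) {
    st <- evaluate_strategy(strategy("soft", th), tab, eff, costs, utils_)
    expect_equal(st$cost, nt$cost, tolerance = 1e-9)
    expect_equal(st$qalys, nt$qalys, tolerance = 1e-9)
    expect_equal(st$ascvd_pct, nt$ascvd_pct, tolerance = 1e-9)
  }
})

test_that("treatment with protective relative risks reduces lifetime events", {
  tab <- toy_transition_table()
  treated <- evaluate_strategy(strategy("soft", 0.15), tab)
  nt <- evaluate_strategy(strategy("soft", NA), tab,
                          comparability_override = tab)
  expect_lt(treated$ascvd_pct, nt$ascvd_pct)
  # with adverse events switched off, prevention must gain QALYs
  eff_safe <- treatment_effects(p_adverse_diabetes = 0,
                                p_adverse_myopathy = 0)
  treated_safe <- evaluate_strategy(strategy("soft", 0.15), tab, eff_safe)
  expect_gt(treated_safe$qalys, nt$qalys)
})

test_that("free harmless treatment never reduces QALYs at lower thresholds", {
  # a table whose eligible and non-eligible strata share the same risks,
  # so lowering the threshold only extends treatment coverage
  tab <- toy_transition_table()
  flat <- tibble::as_tibble(tab)
  overall <- flat[flat$risk_group == "overall", ]
  for (grp in c("eligible", "non_eligible")) {
    g <- overall
    g$risk_group <- grp
    sel <- flat$risk_group == grp
    flat$value[sel] <- g$value[match(
      paste(flat$sex[sel], flat$age_group[sel], flat$from_state[sel],
            flat$to_state[sel]),
      paste(g$sex, g$age_group, g$from_state, g$to_state))]
  }
  flat_tab <- transition_table(flat)
  costs <- cost_set(statin_annual = 0, registration_annual = 0,
                    exam_per_visit = 0)
  utils_ <- utility_set(on_statin = 1)
  eff <- treatment_effects(p_adverse_diabetes = 0, p_adverse_myopathy = 0,
                           p_discontinue_other = 0)
  elig <- attr(tab, "eligibility")
  qal <- vapply(c(1, 2), function(mult) {
    e2 <- elig
    e2$eligible_fraction <- pmin(e2$eligible_fraction * mult, 1)
    evaluate_strategy(strategy("soft", 0.15), flat_tab, eff, costs, utils_,
                      eligibility = e2)$qalys
  }, numeric(1))
  expect_gte(qal[2], qal[1])
})

test_that("full discontinuation reproduces untreated dynamics at statin cost 0", {
  tab <- toy_transition_table()
  eff <- treatment_effects(p_discontinue_other = 1, p_adverse_diabetes = 0,
                           p_adverse_myopathy = 0)
  st <- evaluate_strategy(strategy("soft", 0.15), tab, eff)
  nt_strat <- evaluate_strategy(strategy("soft", 0.15), tab, null_effects(),
                                cost_set(statin_annual = 0,
                                         registration_annual = 0,
                                         exam_per_visit = 0),
                                utility_set(on_statin = 1))
  expect_equal(st$qalys, nt_strat$qalys, tolerance = 1e-9)
  expect_equal(st$cost, nt_strat$cost, tolerance = 1e-9)
})

test_that("grid evaluation orders strategies and enforces unique thresholds", {
  tab <- toy_transition_table()
  grid <- evaluate_threshold_grid(c(0.12, 0.18, 0.15), "soft", tab)
  expect_equal(nrow(grid), 4)
  expect_true(is.na(grid$threshold[1]))
  expect_equal(grid$threshold[-1], c(0.18, 0.15, 0.12))
  expect_true(all(diff(grid$eligible_pct[-1]) >= 0))
  expect_error(evaluate_threshold_grid(c(0.1, 0.1), "soft", tab),
               "Duplicate")
  expect_error(evaluate_threshold_grid(numeric(0), "soft", tab), "Empty")
})

test_that("missing strata are reported by name", {
  tab <- toy_transition_table()
  sub <- transition_table(tab[tab$risk_group != "eligible" |
                                tab$age_group != "50-54", ])
  attr(sub, "eligibility") <- attr(tab, "eligibility")
  expect_error(evaluate_strategy(strategy("soft", 0.15), sub),
               "50-54")
})
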