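test_that("generated cohorts hit the calibration anchors", {
  fix <- synthetic_fixture()
  cohort <- fix$cohort
  expect_equal(stats::median(cohort$risk_soft), 0.098, tolerance = 0.005 / 0.098)
  expect_equal(stats::median(cohort$risk_hard), 0.052, tolerance = 0.005 / 0.052)
  expect_true(all(cohort$risk_hard <= cohort$risk_soft))
  expect_true(all(cohort$risk_soft >= 0 & cohort$risk_soft < 1))
  expect_true(all(cohort$age >= 30 & cohort$age <= 75))
  expect_equal(sort(unique(cohort$sex)), c("female", "male"))
  expect_length(unique(cohort$region), 10)
  # determinism and edge sizes
  expect_identical(generate_cohort(500, seed = 3), generate_cohort(500, seed = 3))
  expect_equal(nrow(suppressWarnings(generate_cohort(1, seed = 1))), 1)
  expect_error(cohort_calibration(median_soft = 0.05, median_hard = 0.09),
               "below soft")
})

test_that("simulated follow-up reproduces the cohort event fractions", {
  fix <- synthetic_fixture()
  n <- nrow(fix$cohort)
  soft_frac <- sum(fix$events$event_type != "fatal_non_ASCVD") / n
  hard_frac <- sum(fix$events$event_type %in%
                     c("acute_MI", "IS", "fatal_ASCVD")) / n
  expect_equal(soft_frac, 0.169, tolerance = 0.005 / 0.169)
  expect_equal(hard_frac, 0.114, tolerance = 0.005 / 0.114)
  expect_lt(hard_frac, soft_frac)
  expect_true(all(fix$events$time >= 0 & fix$events$time <= 12))
  expect_error(simulate_followup(fix$cohort, years = 0), "positive")
  # zero hazards produce no ASCVD events
  quiet <- fix$cohort[1:200, ]
  quiet$h_soft <- 0; quiet$h_hard <- 0; quiet$h_death <- 0
  ev0 <- simulate_followup(quiet, years = 12, seed = 5)
  expect_equal(nrow(ev0), 0)
})

test_that("regional recalibration rescales means and preserves order", {
  set.seed(61)
  risks <- stats::rbeta(2000, 2, 18)
  region <- sample(c("r1", "r2"), 2000, replace = TRUE)
  mean_r1 <- mean(risks[region == "r1"])
  # identity when observed equals the mean predicted
  same <- recalibrate_risk(risks, region,
                           c(r1 = mean_r1,
                             r2 = mean(risks[region == "r2"])))
  expect_equal(same, risks, tolerance = 1e-9)
  # doubling the observed risk doubles the regional mean
  dbl <- recalibrate_risk(risks, region,
                          c(r1 = 2 * mean_r1,
                            r2 = mean(risks[region == "r2"])))
  expect_equal(mean(dbl[region == "r1"]), 2 * mean_r1, tolerance = 1e-6)
  expect_equal(stats::cor(dbl[region == "r1"], risks[region == "r1"],
                          method = "spearman"), 1)
  expect_error(recalibrate_risk(risks, region, c(r1 = 0, r2 = 0.5)),
               "strictly in")
})

test_that("estimated tables recover the generating 10-year probabilities", {
  # single-stratum binomial oracle: one age-sex cell, known p10, no
  # competing mortality
  n <- 100000
  cohort <- generate_cohort(n, seed = 300)
  cohort$age <- rep(42, n)
  cohort$sex <- "female"
  p10_true <- 0.10
  cohort$h_soft <- rep(-log(1 - p10_true) / 10, n)
  cohort$h_hard <- cohort$h_soft / 2
  cohort$h_death <- 0
  ev <- simulate_followup(cohort, years = 12, seed = 301)
  tab <- suppressWarnings(estimate_transition_table(ev, cohort))
  got <- tab[tab$sex == "female" & tab$age_group == "40-44" &
               tab$from_state == "disease_free" &
               tab$to_state != "fatal_non_ASCVD", ]
  p10_hat <- sum(got$value)
  se <- sqrt(p10_true * (1 - p10_true) / n)
  expect_lt(abs(p10_hat - p10_true), 3 * se)
})

test_that("eligible strata carry higher event probabilities than non-eligible", {
  fix <- synthetic_fixture()
  tab <- suppressWarnings(estimate_transition_table(
    fix$events, fix$cohort, threshold = 0.18, model = "soft"))
  df <- tab[tab$from_state == "disease_free" &
              tab$to_state != "fatal_non_ASCVD" & !is.na(tab$value), ]
  agg <- stats::aggregate(value ~ sex + age_group + risk_group, data = df,
                          FUN = sum)
  wide <- merge(agg[agg$risk_group == "eligible", ],
                agg[agg$risk_group == "non_eligible", ],
                by = c("sex", "age_group"))
  # drop sparse cells (few eligible individuals at young ages)
  expect_true(mean(wide$value.x >= wide$value.y) > 0.85)
  old <- wide[wide$age_group %in% c("55-59", "60-64", "65-69", "70-75"), ]
  expect_true(all(old$value.x > old$value.y))
})

test_that("identical seeds give identical tables; uniform weights equal unweighted", {
  fix <- synthetic_fixture()
  t1 <- suppressWarnings(estimate_transition_table(
    fix$events, fix$cohort, threshold = 0.15, model = "soft"))
  t2 <- suppressWarnings(estimate_transition_table(
    fix$events, fix$cohort, threshold = 0.15, model = "soft"))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # census weighting of post-event rows: uniform weights = simple mean
  uw <- default_census_weights()
  uw$weight <- 1 / nrow(uw)
  tu <- suppressWarnings(estimate_transition_table(
    fix$events, fix$cohort, census_weights = uw))
  overall <- tu[tu$risk_group == "overall" & tu$from_state == "disease_free" &
                  tu$to_state == "nonfatal_IS" & !is.na(tu$value), ]
  manual <- mean(annualize_probability(overall$value))
  post <- tu[tu$from_state == "nonfatal_acute_MI" &
               tu$to_state == "nonfatal_IS", ]
  expect_equal(post$value, manual * 1.5, tolerance = 1e-12)
})

test_that("end-to-end parameter recovery: pipeline reproduces generator truth", {
  # generate -> simulate -> estimate -> run the Markov engine untreated;
  # its 10-year disease-free ASCVD incidence must match the generator
  fix <- synthetic_fixture()
  cohort <- fix$cohort
  tab <- suppressWarnings(estimate_transition_table(fix$events, cohort))
  # pick a well-populated cell
  idx <- cohort$sex == "male" & age_to_band(cohort$age) == "50-54"
  truth <- mean(cohort$h_soft[idx] /
                  (cohort$h_soft[idx] + cohort$h_death[idx]) *
                  (1 - exp(-10 * (cohort$h_soft[idx] + cohort$h_death[idx]))))
  m <- build_transition_matrix(tab, "male", "50-54", "overall")
  init <- stats::setNames(numeric(9), health_states())
  init["disease_free_untreated"] <- 1
  tr <- run_cohort(m, init, 10, start_age = 52)
  got <- lifetime_ascvd_fraction(tr)
  se <- sqrt(truth * (1 - truth) / sum(idx))
  expect_lt(abs(got - truth), 3 * se)
})
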