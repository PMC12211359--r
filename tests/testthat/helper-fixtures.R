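# Shared fixtures, built in code at test time.

# A small deterministic transition table covering both sexes and all age
# bands, with eligible risk roughly three times non-eligible risk and
# mortality rising with age.
toy_transition_table <- function() {
  rows <- list()
  bands <- age_bands()
  for (sx in c("female", "male")) {
    for (k in seq_along(bands)) {
      base <- 0.004 + 0.004 * k + 0.002 * (sx == "male")
      for (grp in c("eligible", "non_eligible", "overall")) {
        mult <- switch(grp, eligible = 3, non_eligible = 0.6, overall = 1)
        p10 <- c(nonfatal_acute_MI = 0.08, nonfatal_other_IHD = 0.35,
                 nonfatal_IS = 0.25, fatal_ASCVD = 0.12) * base * 10 * mult
        p10["fatal_non_ASCVD"] <- min(0.008 * k * 10, 0.6)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, age_group = bands[k], risk_group = grp,
          from_state = "disease_free", to_state = names(p10),
          horizon = "p10", value = pmin(unname(p10), 0.9))
      }
    }
  }
  post <- tibble::tibble(
    sex = "all", age_group = "all", risk_group = "overall",
    from_state = rep(nonfatal_event_states(), each = 4),
    to_state = c("nonfatal_other_IHD", "nonfatal_IS", "fatal_ASCVD",
                 "fatal_non_ASCVD",
                 "nonfatal_acute_MI", "nonfatal_IS", "fatal_ASCVD",
                 "fatal_non_ASCVD",
                 "nonfatal_acute_MI", "nonfatal_other_IHD", "fatal_ASCVD",
                 "fatal_non_ASCVD"),
    horizon = "p1",
    # post-event states must be more lethal than disease-free at any age
    value = rep(c(0.010, 0.008, 0.060, 0.080), 3))
  tab <- transition_table(do.call(rbind, c(rows, list(post))))
  elig <- default_census_weights()
  elig$eligible_fraction <- 0.15 + 0.06 * (match(elig$age_group,
                                                 bands) - 1)
  attr(tab, "eligibility") <- elig[, c("sex", "age_group",
                                       "eligible_fraction")]
  tab
}

# memoized mid-size synthetic cohort + follow-up shared across test files
synthetic_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(30000, seed = 2024)
      events <- simulate_followup(cohort, seed = 2025)
      cache <<- list(cohort = cohort, events = events)
    }
    cache
  }
})

null_effects <- function() {
  treatment_effects(rr_nonfatal_ihd = 1, rr_nonfatal_is = 1,
                    rr_fatal_ascvd = 1, p_adverse_diabetes = 0,
                    p_adverse_myopathy = 0, p_discontinue_other = 0)
}

# random valid stochastic matrix over the package states
random_stochastic_matrix <- function(states = health_states()) {
  n <- length(states)
  m <- matrix(stats::rexp(n * n), n, n, dimnames = list(states, states))
  for (s in intersect(absorbing_states(), states)) {
    m[s, ] <- 0
    m[s, s] <- 1
  }
  m / rowSums(m)
}
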