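#' Cost parameters (2019 US$)
#'
#' Direct and indirect (human-capital) cost inputs, societal perspective.
#' Defaults are base-case values: annual statin therapy, annual registration
#' fee and per-visit risk-assessment examination; hospitalization costs and
#' lengths of stay per event; annual chronic-stage treatment costs; national
#' average annual salary and unemployment rate. RMB amounts were converted at
#' 6.9 RMB per US$.
#'
#' @param ... Named overrides of any default field.
#' @return A `cost_set` (named list).
#' @export
#' @examples
#' cost_set(statin_annual = 112.07)
cost_set <- function(...) {
  base <- list(
    statin_annual = 61.43,
    registration_annual = 52.17,
    exam_per_visit = 4.35,
    hosp_acute_mi = 4401.23,
    hosp_other_ihd = 2037.71,
    hosp_is = 1421.91,
    hosp_diabetes = 1149.70,
    hosp_myopathy = 1793.36,
    chronic_ihd = 427.04,
    chronic_is = 242.38,
    chronic_diabetes = 835.87,
    days_acute_mi = 8.05,
    days_other_ihd = 7.79,
    days_is = 10.01,
    days_diabetes = 9.39,
    days_myopathy = 9.21,
    salary_annual = 13116.09,
    unemployment = 0.052,
    retirement_age = 60,
    caregivers = 1,
    wage_day_denominator = 365
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    stop("Unknown cost field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(over)] <- over
  vals <- unlist(base)
  if (any(vals < 0)) stop("Costs must be non-negative.", call. = FALSE)
  if (any(base[c("days_acute_mi", "days_other_ihd", "days_is",
                 "days_diabetes", "days_myopathy")] >= 365)) {
    stop("Hospitalization durations must be below 365 days.", call. = FALSE)
  }
  structure(base, class = "cost_set")
}

#' Utility weights
#'
#' Health-state utility weights: 1 for untreated disease-free, 0.999 on
#' statin therapy (small pill-taking disutility), 0.5 during the acute stage
#' of an ASCVD event (the hospitalization), chronic-stage weights per
#' condition, 0.56 during a myopathy episode, 0 for death.
#'
#' @param ... Named overrides of any default field.
#' @return A `utility_set` (named list).
#' @export
utility_set <- function(...) {
  base <- list(
    disease_free = 1.0,
    on_statin = 0.999,
    acute_event = 0.50,
    chronic_ihd = 0.87,
    chronic_is = 0.90,
    diabetes = 0.84,
    myopathy = 0.56,
    death = 0.0
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    stop("Unknown utility field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(over)] <- over
  vals <- unlist(base)
  if (any(vals < 0 | vals > 1)) {
    stop("Utilities must lie in [0, 1].", call. = FALSE)
  }
  structure(base, class = "utility_set")
}

# chronic-stage annual direct cost per state
state_chronic_cost <- function(costs) {
  c(disease_free_untreated = 0,
    disease_free_on_statin = costs$statin_annual + costs$registration_annual +
      costs$exam_per_visit,
    nonfatal_acute_MI = costs$chronic_ihd,
    nonfatal_other_IHD = costs$chronic_ihd,
    nonfatal_IS = costs$chronic_is,
    adverse_diabetes = costs$chronic_diabetes,
    adverse_myopathy_recovered = 0,
    fatal_ASCVD = 0,
    fatal_non_ASCVD = 0)
}

# chronic-stage utility per state
state_chronic_utility <- function(utilities) {
  c(disease_free_untreated = utilities$disease_free,
    disease_free_on_statin = utilities$on_statin,
    nonfatal_acute_MI = utilities$chronic_ihd,
    nonfatal_other_IHD = utilities$chronic_ihd,
    nonfatal_IS = utilities$chronic_is,
    adverse_diabetes = utilities$diabetes,
    adverse_myopathy_recovered = utilities$disease_free,
    fatal_ASCVD = utilities$death,
    fatal_non_ASCVD = utilities$death)
}

#' Annual direct cost of a state
#'
#' Event-entry cycles accrue the admission cost plus the chronic-stage cost
#' pro-rated over the out-of-hospital remainder of the year; chronic cycles
#' accrue the annual chronic cost; statin-treated disease-free years accrue
#' drug, registration and examination costs; untreated disease-free years
#' accrue nothing.
#'
#' @param state One of [health_states()].
#' @param stage `"chronic"` (default) or `"entry"` (the event-entry cycle).
#' @param on_statin Ignored except for disease-free states, where the
#'   on-statin state already encodes it; kept for call-site clarity.
#' @param costs A [cost_set()].
#' @return USD per year.
#' @export
#' @examples
#' annual_direct_cost("disease_free_on_statin")      # 117.95
#' annual_direct_cost("nonfatal_IS")                 # 242.38
annual_direct_cost <- function(state, stage = c("chronic", "entry"),
                               on_statin = NULL, costs = cost_set()) {
  stage <- match.arg(stage)
  if (!state %in% health_states()) {
    stop("Unknown state: ", state, call. = FALSE)
  }
  chronic <- state_chronic_cost(costs)[state]
  if (stage == "chronic") return(unname(chronic))
  hosp <- switch(state,
    nonfatal_acute_MI = c(costs$hosp_acute_mi, costs$days_acute_mi),
    nonfatal_other_IHD = c(costs$hosp_other_ihd, costs$days_other_ihd),
    nonfatal_IS = c(costs$hosp_is, costs$days_is),
    adverse_diabetes = c(costs$hosp_diabetes, costs$days_diabetes),
    adverse_myopathy_recovered = c(costs$hosp_myopathy, costs$days_myopathy),
    c(0, 0))
  unname(hosp[1] + (1 - hosp[2] / 365) * chronic)
}

#' Indirect cost of one hospitalization (human capital approach)
#'
#' Lost production time is valued at the average daily wage for the patient
#' plus one caregiver, scaled by the employment rate:
#' (salary / denominator) x days x (1 + caregivers) x (1 - unemployment).
#'
#' @param days Length of stay in days (>= 0).
#' @param salary_annual Average annual salary, USD.
#' @param unemployment Unemployment rate in `[0, 1]`.
#' @param caregivers Number of caregiving family members (default 1).
#' @param denominator Days per year used for the daily wage (default 365
#'   calendar days: all lost time is assumed productive).
#' @return USD.
#' @export
#' @examples
#' indirect_hospitalization_cost(8.05, 13116.09, 0.052)
indirect_hospitalization_cost <- function(days, salary_annual = 13116.09,
                                          unemployment = 0.052,
                                          caregivers = 1,
                                          denominator = 365) {
  if (any(days < 0)) stop("`days` must be non-negative.", call. = FALSE)
  (salary_annual / denominator) * days * (1 + caregivers) * (1 - unemployment)
}

#' Productivity loss from premature death
#'
#' Human-capital value of working years lost: the discounted sum of the
#' employment-adjusted annual salary from the year of death up to (not
#' including) retirement age. Zero at or beyond retirement age.
#'
#' @param age_at_death Age in years (>= 0).
#' @param salary_annual Average annual salary, USD.
#' @param unemployment Unemployment rate in `[0, 1]`.
#' @param retirement_age Retirement age in years (default 60).
#' @param spec A [discount_spec()].
#' @return USD (present value at the year of death).
#' @export
#' @examples
#' premature_death_productivity_loss(55, spec = discount_spec(0.05))
premature_death_productivity_loss <- function(age_at_death,
                                              salary_annual = 13116.09,
                                              unemployment = 0.052,
                                              retirement_age = 60,
                                              spec = discount_spec()) {
  years <- max(0, ceiling(retirement_age - age_at_death))
  if (years == 0) return(0)
  present_value(rep(salary_annual * (1 - unemployment), years), spec)
}

#' Utility weight accrued over one cycle
#'
#' Event-entry cycles mix the acute-stage utility over the hospitalization
#' days with the chronic-stage utility over the remainder of the year:
#' (days/365) x u_acute + (1 - days/365) x u_chronic. Chronic cycles return
#' the chronic weight; disease-free cycles 1 (or 0.999 on statin); death 0.
#' The myopathy episode uses its own stay utility (0.56) against a
#' disease-free remainder.
#'
#' @param state One of [health_states()].
#' @param stage `"chronic"` or `"entry"`.
#' @param on_statin Unused for non-disease-free states.
#' @param hosp_days Length of stay for the entry cycle; defaults to the
#'   event's value in [cost_set()].
#' @param utilities A [utility_set()].
#' @param costs A [cost_set()] (source of default stay durations).
#' @return QALY weight for the cycle, in `[0, 1]`.
#' @export
#' @examples
#' annual_utility("nonfatal_IS", "entry")   # 0.8890
annual_utility <- function(state, stage = c("chronic", "entry"),
                           on_statin = NULL, hosp_days = NULL,
                           utilities = utility_set(), costs = cost_set()) {
  stage <- match.arg(stage)
  if (!state %in% health_states()) {
    stop("Unknown state: ", state, call. = FALSE)
  }
  chronic <- state_chronic_utility(utilities)[state]
  if (stage == "chronic") return(unname(chronic))
  days <- if (!is.null(hosp_days)) hosp_days else switch(state,
    nonfatal_acute_MI = costs$days_acute_mi,
    nonfatal_other_IHD = costs$days_other_ihd,
    nonfatal_IS = costs$days_is,
    adverse_diabetes = costs$days_diabetes,
    adverse_myopathy_recovered = costs$days_myopathy,
    0)
  acute <- switch(state,
    nonfatal_acute_MI = utilities$acute_event,
    nonfatal_other_IHD = utilities$acute_event,
    nonfatal_IS = utilities$acute_event,
    adverse_diabetes = utilities$diabetes,
    adverse_myopathy_recovered = utilities$myopathy,
    chronic)
  frac <- min(days / 365, 1)
  unname(frac * acute + (1 - frac) * chronic)
}
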