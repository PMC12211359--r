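#' Statin treatment effects and adherence parameters
#'
#' Relative risks of statin therapy on non-fatal IHD events (acute MI and
#' other IHD), non-fatal ischemic stroke, and fatal ASCVD events, from
#' randomized-trial meta-analysis; annual probabilities of treatment-ending
#' adverse events (new-onset diabetes, definite myopathy); and the
#' probability of discontinuation for other reasons, applied once in the
#' first treated cycle by default (`discontinue_mode = "annual"` switches to
#' a per-cycle probability).
#'
#' @param ... Named overrides of any default field.
#' @return A `treatment_effects` (named list).
#' @export
#' @examples
#' treatment_effects(rr_nonfatal_ihd = 1, rr_nonfatal_is = 1, rr_fatal_ascvd = 1)
treatment_effects <- function(...) {
  base <- list(
    rr_nonfatal_ihd = 0.67,
    rr_nonfatal_is = 0.69,
    rr_fatal_ascvd = 0.83,
    p_adverse_diabetes = 0.0030,
    p_adverse_myopathy = 0.0024,
    p_discontinue_other = 0.1186,
    discontinue_mode = "one_time"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    stop("Unknown treatment-effect field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  base[names(over)] <- over
  rr <- unlist(base[c("rr_nonfatal_ihd", "rr_nonfatal_is", "rr_fatal_ascvd")])
  if (any(rr <= 0)) stop("Relative risks must be positive.", call. = FALSE)
  pr <- unlist(base[c("p_adverse_diabetes", "p_adverse_myopathy",
                      "p_discontinue_other")])
  if (any(pr < 0 | pr > 1)) {
    stop("Adverse-event and discontinuation probabilities must lie in [0, 1].",
         call. = FALSE)
  }
  structure(base, class = "treatment_effects")
}

#' A threshold screening strategy
#'
#' @param model `"soft"` or `"hard"` ASCVD outcome model.
#' @param threshold 10-year risk threshold as a fraction (e.g. 0.18), or `NA`
#'   for the no-treatment comparator.
#' @return A `strategy` (named list).
#' @export
strategy <- function(model = c("soft", "hard"), threshold = NA_real_) {
  model <- match.arg(model)
  structure(list(model = model, threshold = threshold), class = "strategy")
}

#' Stylized census weights (sex by 5-year age band)
#'
#' Population weights approximating the 2019 Chinese national age structure
#' for ages 30-75, split evenly by sex. Used to weight sub-cohort outcomes
#' and eligible fractions to the national population.
#'
#' @return Tibble with columns `sex`, `age_group`, `weight` (summing to 1).
#' @export
default_census_weights <- function() {
  band_w <- c(`30-34` = 0.112, `35-39` = 0.108, `40-44` = 0.118,
              `45-49` = 0.128, `50-54` = 0.132, `55-59` = 0.108,
              `60-64` = 0.102, `65-69` = 0.082, `70-75` = 0.110)
  tibble::tibble(
    sex = rep(c("female", "male"), each = length(band_w)),
    age_group = rep(names(band_w), 2),
    weight = rep(unname(band_w) / 2, 2))
}

#' Stratify a cohort by a risk threshold
#'
#' Individuals with predicted 10-year risk at or above the threshold are
#' eligible for statin initiation (ties treated as eligible). The reported
#' eligible fraction is the census-weighted mean of cell-level (sex by age
#' band) eligible fractions; without cell information it is the simple mean.
#'
#' @param risks Numeric vector of 10-year risks in `[0, 1]`.
#' @param threshold Risk threshold as a fraction.
#' @param census_weights Optional tibble from [default_census_weights()].
#' @param sex,age Optional per-individual sex labels and ages (needed for
#'   census weighting).
#' @return List with `eligible` (logical vector), `eligible_fraction`
#'   (weighted scalar) and `by_cell` (tibble of cell-level fractions, or
#'   `NULL`).
#' @export
stratify_by_threshold <- function(risks, threshold, census_weights = NULL,
                                  sex = NULL, age = NULL) {
  if (length(risks) == 0) stop("Empty cohort.", call. = FALSE)
  if (any(risks < 0 | risks > 1)) {
    stop("Risks must lie in [0, 1].", call. = FALSE)
  }
  eligible <- risks >= threshold
  if (is.null(census_weights) || is.null(sex) || is.null(age)) {
    return(list(eligible = eligible, eligible_fraction = mean(eligible),
                by_cell = NULL))
  }
  band <- age_to_band(age)
  cell <- stats::aggregate(eligible,
                           by = list(sex = sex, age_group = band), FUN = mean)
  names(cell)[3] <- "eligible_fraction"
  merged <- merge(cell, as.data.frame(census_weights),
                  by = c("sex", "age_group"))
  merged$weight <- merged$weight / sum(merged$weight)
  list(eligible = eligible,
       eligible_fraction = sum(merged$eligible_fraction * merged$weight),
       by_cell = tibble::as_tibble(
         merged[c("sex", "age_group", "eligible_fraction", "weight")]))
}

band_midpoint <- function(band) {
  lo <- as.numeric(sub("-.*", "", band))
  hi <- as.numeric(sub(".*-", "", band))
  (lo + hi) / 2
}

# Present-value cost and QALYs for one sub-cohort trace, with event-entry
# (acute-stage) adjustments and premature-death productivity loss charged at
# the fatal-ASCVD entry cycle.
accrue_outcomes <- function(trace, costs, utilities, spec,
                            death_productivity = TRUE) {
  states <- trace$states
  h <- nrow(trace$occupancy) - 1
  ccost <- state_chronic_cost(costs)[states]
  cutil <- state_chronic_utility(utilities)[states]
  event_states <- c("nonfatal_acute_MI", "nonfatal_other_IHD", "nonfatal_IS",
                    "adverse_diabetes", "adverse_myopathy_recovered")
  entry_cost <- stats::setNames(numeric(length(states)), states)
  entry_util <- stats::setNames(numeric(length(states)), states)
  for (s in intersect(event_states, states)) {
    days <- switch(s,
      nonfatal_acute_MI = costs$days_acute_mi,
      nonfatal_other_IHD = costs$days_other_ihd,
      nonfatal_IS = costs$days_is,
      adverse_diabetes = costs$days_diabetes,
      adverse_myopathy_recovered = costs$days_myopathy)
    entry_cost[s] <- annual_direct_cost(s, "entry", costs = costs) -
      annual_direct_cost(s, "chronic", costs = costs) +
      indirect_hospitalization_cost(days, costs$salary_annual,
                                    costs$unemployment, costs$caregivers,
                                    costs$wage_day_denominator)
    entry_util[s] <- annual_utility(s, "entry", utilities = utilities,
                                    costs = costs) -
      annual_utility(s, "chronic", utilities = utilities, costs = costs)
  }
  occ <- trace$occupancy[seq_len(h), , drop = FALSE]
  inflow <- trace$inflow[seq_len(h), , drop = FALSE]
  cost_stream <- as.numeric(occ %*% ccost) + as.numeric(inflow %*% entry_cost)
  util_stream <- as.numeric(occ %*% cutil) + as.numeric(inflow %*% entry_util)
  if (death_productivity && "fatal_ASCVD" %in% states) {
    ages <- trace$start_age + seq_len(h) - 1
    pdl <- vapply(ages, premature_death_productivity_loss,
                  numeric(1), salary_annual = costs$salary_annual,
                  unemployment = costs$unemployment,
                  retirement_age = costs$retirement_age, spec = spec)
    cost_stream <- cost_stream + inflow[, "fatal_ASCVD"] * pdl
  }
  c(cost = present_value(cost_stream, spec),
    qalys = present_value(util_stream, spec),
    ascvd = lifetime_ascvd_fraction(trace))
}

# Run one sub-cohort for a census cell: builds band-indexed matrices lazily
# and propagates until age `max_age`.
run_cell <- function(table, sex, start_age, risk_group, init,
                     treatment_modifiers = NULL, costs, utilities, spec,
                     max_age = 100, cache = NULL) {
  horizon <- max(1L, ceiling(max_age - start_age))
  key_prefix <- paste(sex, risk_group,
                      if (is.null(treatment_modifiers)) "plain" else "treated")
  local_cache <- if (is.null(cache)) new.env(parent = emptyenv()) else cache
  matrix_fun <- function(cycle) {
    band <- age_to_band(start_age + cycle - 1)
    key <- paste(key_prefix, band)
    if (is.null(local_cache[[key]])) {
      local_cache[[key]] <- build_transition_matrix(
        table, sex, band, risk_group,
        treatment_modifiers = treatment_modifiers)
    }
    local_cache[[key]]
  }
  trace <- run_cohort(matrix_fun, init, horizon, start_age = start_age)
  accrue_outcomes(trace, costs, utilities, spec)
}

#' Evaluate one threshold strategy
#'
#' Population-level expected outcome of a screening policy: per census cell
#' (sex by age band), the eligible stratum is simulated on statin therapy
#' (with discontinuation moving individuals to untreated disease-free) and
#' the non-eligible stratum untreated; cell results are mixed by the cell's
#' eligible fraction and aggregated with census weights. The no-treatment
#' comparator runs the whole population untreated on the `overall` rows,
#' unless `comparability_override` supplies the stratified table of the
#' highest threshold (used so that the top-threshold strategy and no
#' treatment share transition inputs).
#'
#' @param strat A [strategy()].
#' @param table A [transition_table()] with `eligible`/`non_eligible` rows
#'   estimated at this strategy's threshold (or `overall` rows for no
#'   treatment).
#' @param effects A [treatment_effects()].
#' @param costs,utilities [cost_set()] / [utility_set()].
#' @param discount A [discount_spec()].
#' @param census_weights Tibble from [default_census_weights()].
#' @param eligibility Tibble with columns `sex`, `age_group`,
#'   `eligible_fraction`; defaults to `attr(table, "eligibility")`.
#' @param comparability_override Optional transition table (with
#'   eligibility attribute) used for the no-treatment comparator.
#' @param max_age Simulation stops when the cohort reaches this age.
#' @return One-row tibble: `model`, `threshold`, `eligible_pct`,
#'   `ascvd_pct`, `cost`, `qalys` (class `strategy_outcome`).
#' @export
evaluate_strategy <- function(strat, table, effects = treatment_effects(),
                              costs = cost_set(), utilities = utility_set(),
                              discount = discount_spec(),
                              census_weights = default_census_weights(),
                              eligibility = NULL,
                              comparability_override = NULL,
                              max_age = 100) {
  no_treatment <- is.na(strat$threshold)
  if (no_treatment && !is.null(comparability_override)) {
    table <- comparability_override
  }
  if (is.null(eligibility)) eligibility <- attr(table, "eligibility")
  cells <- as.data.frame(census_weights)
  cells$weight <- cells$weight / sum(cells$weight)

  cache <- new.env(parent = emptyenv())
  init0 <- stats::setNames(numeric(length(health_states())), health_states())

  cell_results <- matrix(0, nrow(cells), 4,
                         dimnames = list(NULL, c("cost", "qalys", "ascvd",
                                                 "eligible")))
  for (i in seq_len(nrow(cells))) {
    sex <- cells$sex[i]
    band <- cells$age_group[i]
    start_age <- band_midpoint(band)
    stratified <- no_treatment && !is.null(comparability_override) ||
      !no_treatment
    if (!stratified) {
      init <- init0
      init["disease_free_untreated"] <- 1
      res <- run_cell(table, sex, start_age, "overall", init,
                      NULL, costs, utilities, discount, max_age, cache)
      cell_results[i, ] <- c(res, 0)
      next
    }
    ef <- cell_eligible_fraction(eligibility, sex, band)
    # eligible stratum
    if (ef > 0) {
      if (no_treatment) {
        init <- init0
        init["disease_free_untreated"] <- 1
        elig_res <- run_cell(table, sex, start_age, "eligible", init,
                             NULL, costs, utilities, discount, max_age, cache)
      } else {
        init <- init0
        p_disc <- if (identical(effects$discontinue_mode, "one_time"))
          effects$p_discontinue_other else 0
        init["disease_free_on_statin"] <- 1 - p_disc
        init["disease_free_untreated"] <- p_disc
        elig_res <- run_cell(table, sex, start_age, "eligible", init,
                             effects, costs, utilities, discount, max_age,
                             cache)
      }
    } else {
      elig_res <- c(cost = 0, qalys = 0, ascvd = 0)
    }
    # non-eligible stratum, never treated
    if (ef < 1) {
      init <- init0
      init["disease_free_untreated"] <- 1
      non_res <- run_cell(table, sex, start_age, "non_eligible", init,
                          NULL, costs, utilities, discount, max_age, cache)
    } else {
      non_res <- c(cost = 0, qalys = 0, ascvd = 0)
    }
    mixed <- ef * elig_res + (1 - ef) * non_res
    cell_results[i, ] <- c(mixed, if (no_treatment) 0 else ef)
  }

  w <- cells$weight
  out <- tibble::tibble(
    model = strat$model,
    threshold = strat$threshold,
    eligible_pct = 100 * sum(w * cell_results[, "eligible"]),
    ascvd_pct = 100 * sum(w * cell_results[, "ascvd"]),
    cost = sum(w * cell_results[, "cost"]),
    qalys = sum(w * cell_results[, "qalys"]))
  class(out) <- c("strategy_outcome", class(out))
  out
}

cell_eligible_fraction <- function(eligibility, sex, band) {
  if (is.null(eligibility)) {
    stop("No eligibility information: supply `eligibility` or a table with ",
         "an 'eligibility' attribute.", call. = FALSE)
  }
  if (is.numeric(eligibility) && length(eligibility) == 1) return(eligibility)
  row <- eligibility$sex == sex & eligibility$age_group == band
  if (!any(row)) {
    stop(sprintf("Missing eligibility for stratum (%s, %s).", sex, band),
         call. = FALSE)
  }
  eligibility$eligible_fraction[which(row)[1]]
}

#' Evaluate a grid of threshold strategies
#'
#' Runs [evaluate_strategy()] for every threshold plus the no-treatment
#' comparator and returns one row per strategy, the comparator first and
#' thresholds in descending order. The no-treatment comparator shares the
#' highest threshold's transition inputs (comparability rule).
#'
#' @param thresholds Numeric vector of risk thresholds (fractions), no
#'   duplicates.
#' @param model `"soft"` or `"hard"`.
#' @param tables Either a single [transition_table()] used for every
#'   threshold, or a function `function(threshold)` returning the table (with
#'   eligibility attribute) for each threshold.
#' @inheritParams evaluate_strategy
#' @return Tibble of strategy outcomes, comparator first.
#' @export
evaluate_threshold_grid <- function(thresholds, model, tables,
                                    effects = treatment_effects(),
                                    costs = cost_set(),
                                    utilities = utility_set(),
                                    discount = discount_spec(),
                                    census_weights = default_census_weights(),
                                    max_age = 100) {
  if (length(thresholds) == 0) stop("Empty threshold grid.", call. = FALSE)
  if (anyDuplicated(thresholds)) {
    stop("Duplicate thresholds in grid.", call. = FALSE)
  }
  get_table <- if (is.function(tables)) tables else function(th) tables
  thresholds <- sort(thresholds, decreasing = TRUE)
  top_table <- get_table(max(thresholds))
  rows <- vector("list", length(thresholds) + 1)
  rows[[1]] <- evaluate_strategy(
    strategy(model, NA_real_), top_table, effects, costs, utilities,
    discount, census_weights, comparability_override = top_table,
    max_age = max_age)
  for (k in seq_along(thresholds)) {
    th <- thresholds[k]
    rows[[k + 1]] <- evaluate_strategy(
      strategy(model, th), get_table(th), effects, costs, utilities,
      discount, census_weights, max_age = max_age)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("strategy_outcome", class(tibble::tibble()))
  out
}
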