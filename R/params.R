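#' Model parameter manifest
#'
#' One row per uncertain model input: base-case value, lower/upper bounds
#' and the probabilistic-sensitivity-analysis distribution family. Bounds
#' derive from 95% confidence intervals where published, from +/-15% of the
#' base case, or from urban/rural values (hospitalization costs and stays).
#' Relative risks are log-normal; proportions and utilities beta; costs,
#' durations and salary gamma; inputs without a published range are fixed.
#' `component`/`field` map each row onto [cost_set()], [utility_set()],
#' [treatment_effects()] or the discount rate.
#'
#' @return Tibble with columns `name`, `component`, `field`, `base`, `low`,
#'   `high`, `distribution`.
#' @export
default_parameter_table <- function() {
  r <- function(name, component, field, base, low, high, distribution) {
    tibble::tibble(name = name, component = component, field = field,
                   base = base, low = low, high = high,
                   distribution = distribution)
  }
  do.call(rbind, list(
    r("rr_nonfatal_ihd", "effects", "rr_nonfatal_ihd",
      0.67, 0.59, 0.76, "lognormal"),
    r("rr_nonfatal_is", "effects", "rr_nonfatal_is",
      0.69, 0.58, 0.83, "lognormal"),
    r("rr_fatal_ascvd", "effects", "rr_fatal_ascvd",
      0.83, 0.72, 0.96, "lognormal"),
    r("p_adverse_diabetes", "effects", "p_adverse_diabetes",
      0.0030, 0.0026, 0.0035, "beta"),
    r("p_adverse_myopathy", "effects", "p_adverse_myopathy",
      0.0024, 0.0020, 0.0028, "beta"),
    r("p_discontinue_other", "effects", "p_discontinue_other",
      0.1186, 0.1008, 0.1364, "beta"),
    r("statin_annual", "costs", "statin_annual",
      61.43, 40.20, 112.07, "gamma"),
    r("exam_per_visit", "costs", "exam_per_visit",
      4.35, 2.90, 7.25, "gamma"),
    r("registration_annual", "costs", "registration_annual",
      52.17, 34.78, 86.96, "gamma"),
    r("hosp_diabetes", "costs", "hosp_diabetes",
      1149.70, 977.25, 1322.14, "gamma"),
    r("chronic_diabetes", "costs", "chronic_diabetes",
      835.87, 710.49, 961.25, "gamma"),
    r("hosp_myopathy", "costs", "hosp_myopathy",
      1793.36, 1524.35, 2062.36, "gamma"),
    r("hosp_acute_mi", "costs", "hosp_acute_mi",
      4401.23, 2697.80, 4738.36, "gamma"),
    r("hosp_other_ihd", "costs", "hosp_other_ihd",
      2037.71, 1093.93, 2372.42, "gamma"),
    r("hosp_is", "costs", "hosp_is",
      1421.91, 944.87, 1830.20, "gamma"),
    r("chronic_ihd", "costs", "chronic_ihd",
      427.04, 362.99, 491.10, "gamma"),
    r("chronic_is", "costs", "chronic_is",
      242.38, 206.01, 278.74, "gamma"),
    r("days_acute_mi", "costs", "days_acute_mi",
      8.05, 7.59, 8.30, "gamma"),
    r("days_other_ihd", "costs", "days_other_ihd",
      7.79, 7.73, 7.85, "gamma"),
    r("days_is", "costs", "days_is",
      10.01, 9.50, 10.73, "gamma"),
    r("days_diabetes", "costs", "days_diabetes",
      9.39, 8.83, 9.88, "gamma"),
    r("days_myopathy", "costs", "days_myopathy",
      9.21, 9.03, 9.37, "gamma"),
    r("salary_annual", "costs", "salary_annual",
      13116.09, 11148.68, 15083.51, "gamma"),
    r("unemployment", "costs", "unemployment",
      0.052, 0.044, 0.060, "beta"),
    r("u_on_statin", "utilities", "on_statin",
      0.999, 0.998, 1.000, "beta"),
    r("u_acute_event", "utilities", "acute_event",
      0.50, 0.20, 0.80, "fixed"),
    r("u_chronic_ihd", "utilities", "chronic_ihd",
      0.87, 0.75, 0.90, "beta"),
    r("u_chronic_is", "utilities", "chronic_is",
      0.90, 0.90, 0.90, "fixed"),
    r("u_diabetes", "utilities", "diabetes",
      0.84, 0.79, 0.94, "beta"),
    r("u_myopathy", "utilities", "myopathy",
      0.56, 0.56, 0.56, "fixed"),
    r("discount_rate", "other", "discount",
      0.05, 0.00, 0.08, "fixed")
  ))
}

#' Bundle of all model parameters at their base-case values
#'
#' @param costs,utilities,effects Component objects.
#' @param discount Annual discount rate.
#' @return Named list of class `model_params`.
#' @export
model_params <- function(costs = cost_set(), utilities = utility_set(),
                         effects = treatment_effects(), discount = 0.05) {
  structure(list(costs = costs, utilities = utilities, effects = effects,
                 discount = discount), class = "model_params")
}

#' Apply named parameter values onto a `model_params` bundle
#'
#' @param draw Named numeric vector whose names appear in
#'   [default_parameter_table()].
#' @param base A [model_params()] to modify.
#' @param table Parameter manifest providing the name -> component/field map.
#' @return Modified `model_params`.
#' @export
apply_parameters <- function(draw, base = model_params(),
                             table = default_parameter_table()) {
  unknown <- setdiff(names(draw), table$name)
  if (length(unknown) > 0) {
    stop("Unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- base
  for (nm in names(draw)) {
    row <- table[table$name == nm, , drop = FALSE]
    if (row$component == "other") {
      params$discount <- as.numeric(draw[[nm]])
    } else {
      params[[row$component]][[row$field]] <- as.numeric(draw[[nm]])
    }
  }
  params
}
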