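#' Build a parameter-driven grid evaluator
#'
#' Returns a closure mapping a named parameter draw (see
#' [sample_parameters()]) to the strategy-grid outcomes under those
#' parameters, for use with [run_psa()], [one_way_sensitivity()] and
#' [tornado()].
#'
#' @inheritParams evaluate_threshold_grid
#' @param base Base-case [model_params()] that draws override.
#' @return `function(draw)` returning the [evaluate_threshold_grid()]
#'   tibble.
#' @export
make_grid_evaluator <- function(thresholds, model, tables,
                                census_weights = default_census_weights(),
                                max_age = 100, base = model_params()) {
  force(thresholds); force(model); force(tables)
  force(census_weights); force(max_age); force(base)
  function(draw = NULL) {
    params <- if (is.null(draw) || length(draw) == 0) base else
      apply_parameters(draw, base)
    evaluate_threshold_grid(
      thresholds, model, tables,
      effects = params$effects, costs = params$costs,
      utilities = params$utilities,
      discount = discount_spec(params$discount),
      census_weights = census_weights, max_age = max_age)
  }
}

#' Build a parameter-driven two-strategy evaluator
#'
#' Closure for one-way sensitivity analysis: evaluates exactly two
#' strategies (a threshold or `NA` for no treatment each) under a parameter
#' draw.
#'
#' @inheritParams evaluate_threshold_grid
#' @param threshold_a,threshold_b The two strategies' thresholds (fraction,
#'   or `NA` for the no-treatment comparator).
#' @param base Base-case [model_params()].
#' @return `function(draw)` returning a two-row outcome tibble.
#' @export
make_pair_evaluator <- function(threshold_a, threshold_b, model, tables,
                                census_weights = default_census_weights(),
                                max_age = 100, base = model_params()) {
  force(threshold_a); force(threshold_b); force(model); force(tables)
  force(census_weights); force(max_age); force(base)
  get_table <- if (is.function(tables)) tables else function(th) tables
  top <- max(c(threshold_a, threshold_b), na.rm = TRUE)
  function(draw = NULL) {
    params <- if (is.null(draw) || length(draw) == 0) base else
      apply_parameters(draw, base)
    eval_one <- function(th) {
      evaluate_strategy(
        strategy(model, th), get_table(if (is.na(th)) top else th),
        effects = params$effects, costs = params$costs,
        utilities = params$utilities,
        discount = discount_spec(params$discount),
        census_weights = census_weights,
        comparability_override = if (is.na(th)) get_table(top) else NULL,
        max_age = max_age)
    }
    rbind(eval_one(threshold_a), eval_one(threshold_b))
  }
}
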