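#' Convert a 10-year cumulative probability to an annual probability
#'
#' Uses the constant-rate conversion r = 1 - exp(ln(1 - p)/10): the 10-year
#' cumulative probability p is mapped to the annual probability r of the
#' exponential process that accumulates to p over ten years.
#'
#' @param p10 Numeric vector of 10-year cumulative probabilities in `[0, 1)`.
#' @return Annual probabilities in `[0, 1)`.
#' @export
#' @examples
#' annualize_probability(0.10)
annualize_probability <- function(p10) {
  stopifnot(is.numeric(p10))
  if (any(p10 < 0 | p10 >= 1)) {
    stop("`p10` must lie in [0, 1): ln(1 - p) is undefined at p = 1.",
         call. = FALSE)
  }
  1 - exp(log(1 - p10) / 10)
}

#' Compound an annual probability over several years
#'
#' Inverse of [annualize_probability()] (for `years = 10`): returns the
#' cumulative probability 1 - (1 - p1)^years.
#'
#' @param p1 Annual probability in `[0, 1]`.
#' @param years Non-negative number of years.
#' @return Cumulative probability.
#' @export
#' @examples
#' compound_probability(annualize_probability(0.10), 10)
compound_probability <- function(p1, years) {
  stopifnot(is.numeric(p1), is.numeric(years))
  if (any(p1 < 0 | p1 > 1)) stop("`p1` must lie in [0, 1].", call. = FALSE)
  if (any(years < 0)) stop("`years` must be non-negative.", call. = FALSE)
  1 - (1 - p1)^years
}

#' Discounting specification
#'
#' Annual discount rate applied to both costs and QALYs, with cycle 0
#' undiscounted (divisor (1 + rate)^t, t = 0 at model entry). Base case 5%
#' per year; sensitivity range 0 to 8%.
#'
#' @param rate Per-year discount rate, >= 0.
#' @return An object of class `discount_spec`.
#' @export
discount_spec <- function(rate = 0.05) {
  stopifnot(is.numeric(rate), length(rate) == 1)
  if (rate < 0) stop("Discount rate must be >= 0.", call. = FALSE)
  structure(list(rate = rate), class = "discount_spec")
}

#' Present value of an annual stream
#'
#' @param stream Numeric vector, one value per cycle, first element at t = 0.
#' @param spec A [discount_spec()] (or a bare rate).
#' @return Scalar present value.
#' @export
present_value <- function(stream, spec = discount_spec()) {
  rate <- if (inherits(spec, "discount_spec")) spec$rate else spec
  if (length(stream) == 0) return(0)
  sum(stream / (1 + rate)^(seq_along(stream) - 1))
}
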