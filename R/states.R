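#' Health states of the ASCVD Markov model
#'
#' The model distinguishes nine states: two disease-free states (off and on
#' statin therapy), three non-fatal ASCVD states (acute myocardial infarction,
#' other ischemic heart disease, ischemic stroke), two statin adverse-event
#' states (new-onset diabetes, recovered myopathy), and two absorbing death
#' states (fatal ASCVD, fatal non-ASCVD). Non-fatal ASCVD states carry an
#' acute stage (the hospitalization portion of the entry cycle) and a chronic
#' stage thereafter; staging is handled by the accrual functions, not by
#' extra states.
#'
#' @return Character vector of the nine state names, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("disease_free_untreated", "disease_free_on_statin",
    "nonfatal_acute_MI", "nonfatal_other_IHD", "nonfatal_IS",
    "adverse_diabetes", "adverse_myopathy_recovered",
    "fatal_ASCVD", "fatal_non_ASCVD")
}

#' @rdname health_states
#' @export
ascvd_states <- function() {
  c("nonfatal_acute_MI", "nonfatal_other_IHD", "nonfatal_IS", "fatal_ASCVD")
}

#' @rdname health_states
#' @export
absorbing_states <- function() {
  c("fatal_ASCVD", "fatal_non_ASCVD")
}

#' @rdname health_states
#' @export
nonfatal_event_states <- function() {
  c("nonfatal_acute_MI", "nonfatal_other_IHD", "nonfatal_IS")
}

# 5-year age bands used for age-sex-specific transition probabilities.
# The last band spans six years (70-75), matching the cohort's upper age.
#' Age bands of the transition tables
#'
#' @return Character vector of the nine 5-year age bands, "30-34" to "70-75".
#' @export
age_bands <- function() {
  c("30-34", "35-39", "40-44", "45-49", "50-54",
    "55-59", "60-64", "65-69", "70-75")
}

#' Map an age in years to its transition-table age band
#'
#' Ages beyond the last band are carried in the "70-75" band (the oldest
#' observed rates are extrapolated forward over the lifetime horizon).
#'
#' @param age Numeric vector of ages in years (>= 30).
#' @return Character vector of age bands.
#' @export
#' @examples
#' age_to_band(c(30, 47, 75, 93))
age_to_band <- function(age) {
  stopifnot(is.numeric(age), all(age >= 30))
  bands <- age_bands()
  idx <- pmin(floor((age - 30) / 5) + 1, length(bands))
  bands[idx]
}
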