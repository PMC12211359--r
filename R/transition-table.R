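#' Age-sex-stratum transition probability table
#'
#' The table stores, per (sex, age band, risk group), the probabilities of
#' moving between health states. Disease-free rows (`from_state =
#' "disease_free"`) are usually supplied as 10-year cumulative probabilities
#' (`horizon = "p10"`) estimated from cohort follow-up and are annualized via
#' [annualize_probability()]; post-event rows are annual (`horizon = "p1"`).
#' Rows with `sex = "all"`, `age_group = "all"` act as whole-population
#' fallbacks, used for transitions after the first ASCVD event.
#'
#' @param x A data frame with columns `sex`, `age_group`, `risk_group`,
#'   `from_state`, `to_state`, `horizon` (`"p10"` or `"p1"`), `value`.
#' @return A validated `transition_table` (a tibble subclass).
#' @export
transition_table <- function(x) {
  req <- c("sex", "age_group", "risk_group", "from_state", "to_state",
           "horizon", "value")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("Transition table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x[req])
  if (!all(x$horizon %in% c("p10", "p1"))) {
    stop("`horizon` must be 'p10' or 'p1'.", call. = FALSE)
  }
  bad_band <- setdiff(unique(x$age_group), c(age_bands(), "all"))
  if (length(bad_band) > 0) {
    stop("Unknown age bands: ", paste(bad_band, collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$risk_group %in% c("eligible", "non_eligible", "overall"))) {
    stop("`risk_group` must be eligible, non_eligible or overall.",
         call. = FALSE)
  }
  ok <- is.na(x$value) | (x$value >= 0 & x$value <= 1)
  if (!all(ok)) stop("Probabilities must lie in [0, 1].", call. = FALSE)
  # annual outgoing mass must leave room for the stay probability
  ann <- x
  ann$p1 <- ifelse(ann$horizon == "p10",
                   annualize_probability(ifelse(is.na(ann$value), 0, ann$value)),
                   ifelse(is.na(ann$value), 0, ann$value))
  sums <- stats::aggregate(
    p1 ~ sex + age_group + risk_group + from_state, data = ann, FUN = sum)
  over <- sums[sums$p1 > 1 + 1e-12, , drop = FALSE]
  if (nrow(over) > 0) {
    stop(sprintf(
      "Outgoing annual probabilities exceed 1 for stratum (%s, %s, %s, %s): sum = %.6f",
      over$sex[1], over$age_group[1], over$risk_group[1], over$from_state[1],
      over$p1[1]), call. = FALSE)
  }
  class(x) <- c("transition_table", class(x))
  x
}

#' @rdname transition_table
#' @param path File path of a UTF-8 CSV with the schema above.
#' @export
read_transition_table <- function(path) {
  transition_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname transition_table
#' @param table A `transition_table`.
#' @export
write_transition_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# Annual outgoing probabilities for one stratum/from-state, as a named vector
# over to-states. Falls back to the whole-population ("all","all","overall")
# rows when the specific stratum has none (post-first-event transitions).
lookup_annual_probs <- function(table, sex, age_group, risk_group, from_state) {
  sel <- table$from_state == from_state & table$sex == sex &
    table$age_group == age_group & table$risk_group == risk_group
  if (!any(sel)) {
    sel <- table$from_state == from_state & table$sex == "all" &
      table$age_group == "all" & table$risk_group == "overall"
  }
  if (!any(sel)) return(NULL)
  rows <- table[sel, , drop = FALSE]
  p <- ifelse(rows$horizon == "p10",
              annualize_probability(ifelse(is.na(rows$value), 0, rows$value)),
              ifelse(is.na(rows$value), 0, rows$value))
  stats::setNames(p, rows$to_state)
}

#' Apply statin treatment effects to disease-free exit probabilities
#'
#' While on statin therapy the annual probabilities of non-fatal IHD events
#' (acute MI and other IHD) are multiplied by the IHD relative risk, ischemic
#' stroke by the IS relative risk, and fatal ASCVD by the fatal-event relative
#' risk; per-cycle adverse-event exits to new-onset diabetes and myopathy are
#' added. Non-ASCVD mortality is unmodified.
#'
#' @param probs Named numeric vector of annual exit probabilities from the
#'   disease-free state (names are destination states).
#' @param effects A [treatment_effects()] object.
#' @return Named vector including the adverse-event exits.
#' @export
#' @examples
#' apply_statin_effects(c(nonfatal_IS = 0.01), treatment_effects())
apply_statin_effects <- function(probs, effects) {
  out <- probs
  for (s in c("nonfatal_acute_MI", "nonfatal_other_IHD")) {
    if (s %in% names(out)) out[s] <- out[s] * effects$rr_nonfatal_ihd
  }
  if ("nonfatal_IS" %in% names(out)) {
    out["nonfatal_IS"] <- out["nonfatal_IS"] * effects$rr_nonfatal_is
  }
  if ("fatal_ASCVD" %in% names(out)) {
    out["fatal_ASCVD"] <- out["fatal_ASCVD"] * effects$rr_fatal_ascvd
  }
  out["adverse_diabetes"] <-
    sum(out["adverse_diabetes"], effects$p_adverse_diabetes, na.rm = TRUE)
  out["adverse_myopathy_recovered"] <-
    sum(out["adverse_myopathy_recovered"], effects$p_adverse_myopathy,
        na.rm = TRUE)
  if (identical(effects$discontinue_mode, "annual")) {
    out["disease_free_untreated"] <-
      sum(out["disease_free_untreated"], effects$p_discontinue_other,
          na.rm = TRUE)
  }
  if (sum(out) > 1 + 1e-12) {
    stop("Treated exit probabilities sum to more than 1 (",
         sprintf("%.6f", sum(out)), ").", call. = FALSE)
  }
  out
}

#' Build the annual transition matrix for one stratum
#'
#' Assembles the 9x9 row-stochastic matrix over [health_states()] for a given
#' sex, age band and risk group. Disease-free rows take the stratum's
#' first-event probabilities (the on-statin row additionally scaled by
#' treatment relative risks and extended with adverse-event exits);
#' post-event rows fall back to whole-population averages; the recovered
#' myopathy state returns to untreated disease-free in one cycle; death rows
#' are absorbing. Stay probabilities are the row residuals; residuals within
#' 1e-12 below zero are clipped, larger deficits raise an error.
#'
#' @param table A [transition_table()].
#' @param sex `"male"` or `"female"` (or any label used in the table).
#' @param age_group One of [age_bands()].
#' @param risk_group `"eligible"`, `"non_eligible"` or `"overall"`.
#' @param treatment_modifiers Optional [treatment_effects()]; when supplied,
#'   the on-statin disease-free row receives treated probabilities.
#' @param diabetes_uses Stratum whose disease-free hazards apply to the
#'   chronic-diabetes state (default: the same stratum, untreated).
#' @return Matrix with `dimnames` = [health_states()], rows summing to 1.
#' @export
build_transition_matrix <- function(table, sex, age_group, risk_group,
                                    treatment_modifiers = NULL,
                                    diabetes_uses = risk_group) {
  states <- health_states()
  m <- matrix(0, length(states), length(states),
              dimnames = list(states, states))

  df_probs <- lookup_annual_probs(table, sex, age_group, risk_group,
                                  "disease_free")
  if (is.null(df_probs)) {
    stop(sprintf("No disease-free transition rows for stratum (%s, %s, %s).",
                 sex, age_group, risk_group), call. = FALSE)
  }
  set_row <- function(m, from, probs) {
    unknown <- setdiff(names(probs), states)
    if (length(unknown) > 0) {
      stop("Unknown destination state(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    probs <- probs[names(probs) != from]
    m[from, names(probs)] <- probs
    resid <- 1 - sum(probs)
    if (resid < -1e-12) {
      stop(sprintf("Row '%s' exits sum to %.6f > 1 in stratum (%s, %s, %s).",
                   from, sum(probs), sex, age_group, risk_group),
           call. = FALSE)
    }
    m[from, from] <- m[from, from] + max(resid, 0)
    m[from, ] <- m[from, ] / sum(m[from, ])
    m
  }

  m <- set_row(m, "disease_free_untreated", df_probs)
  treated <- if (is.null(treatment_modifiers)) df_probs else
    apply_statin_effects(df_probs, treatment_modifiers)
  m <- set_row(m, "disease_free_on_statin", treated)

  for (ev in nonfatal_event_states()) {
    pe <- lookup_annual_probs(table, sex, age_group, "overall", ev)
    if (is.null(pe)) pe <- numeric(0)
    m <- set_row(m, ev, pe)
  }

  diab <- lookup_annual_probs(table, sex, age_group, diabetes_uses,
                              "disease_free")
  m <- set_row(m, "adverse_diabetes", diab)
  m["adverse_myopathy_recovered", ] <- 0
  m["adverse_myopathy_recovered", "disease_free_untreated"] <- 1
  for (s in absorbing_states()) {
    m[s, ] <- 0
    m[s, s] <- 1
  }
  m
}
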