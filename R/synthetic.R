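#' Calibration anchors for the synthetic cohort
#'
#' Defaults reproduce the published summary features of the source cohort:
#' median predicted 10-year risks of 9.8% (soft outcomes) and 5.2% (hard
#' outcomes), and cumulative event fractions over 12 years of follow-up of
#' 16.9% (soft) and 11.4% (hard).
#'
#' @param median_soft,median_hard Target median 10-year risks (fractions).
#' @param frac12_soft,frac12_hard Target 12-year cumulative event fractions.
#' @param followup_years Follow-up horizon for the event-fraction anchors.
#' @param hard_split Probabilities that a hard first event is an acute MI,
#'   an ischemic stroke, or fatal ASCVD (must sum to 1). Soft-only first
#'   events are other (non-MI) IHD.
#' @return Named list of calibration targets.
#' @export
cohort_calibration <- function(median_soft = 0.098, median_hard = 0.052,
                               frac12_soft = 0.169, frac12_hard = 0.114,
                               followup_years = 12,
                               hard_split = c(acute_MI = 0.20, IS = 0.55,
                                              fatal_ASCVD = 0.25)) {
  if (median_hard >= median_soft || frac12_hard >= frac12_soft) {
    stop("Hard-outcome targets must be below soft-outcome targets.",
         call. = FALSE)
  }
  if (abs(sum(hard_split) - 1) > 1e-9) {
    stop("`hard_split` must sum to 1.", call. = FALSE)
  }
  list(median_soft = median_soft, median_hard = median_hard,
       frac12_soft = frac12_soft, frac12_hard = frac12_hard,
       followup_years = followup_years, hard_split = hard_split)
}

# background (non-ASCVD) annual mortality hazard, Gompertz in age
background_mortality <- function(age, male) {
  exp(-11.3 + 0.093 * age + 0.35 * male)
}

# expected fraction with a first event of the given cause over `years`:
# cause-specific hazard h_event competing against total hazard h_total
# (which includes h_event plus all competing first-event causes)
event_fraction <- function(h_event, h_total, years) {
  frac <- ifelse(h_total > 0,
                 h_event / h_total * (1 - exp(-years * h_total)), 0)
  mean(frac)
}

#' Generate a synthetic cohort
#'
#' Simulates individuals aged 30-75 from ten regions (five urban, five
#' rural) with sex, age, and 10-year soft/hard ASCVD risk scores. Risk is
#' log-linear in a latent score combining age, sex and individual frailty:
#' risk = median_target x exp(s x z), where z is median-centred so the
#' cohort median equals the target exactly, and the spread s is solved
#' numerically so the expected event fraction over the follow-up horizon
#' (under competing background mortality) matches the calibration anchor.
#' The risk scores are also the generative truth: each individual's latent
#' first-event hazard is the constant-rate equivalent of their 10-year risk.
#'
#' @param n Number of individuals (>= 1).
#' @param seed Integer RNG seed.
#' @param calibration A [cohort_calibration()].
#' @return Tibble of class `synthetic_cohort`: `id`, `age`, `sex`, `region`,
#'   `risk_soft`, `risk_hard`, latent hazards `h_soft`, `h_hard`, `h_death`.
#' @export
#' @examples
#' cohort <- generate_cohort(2000, seed = 1)
#' median(cohort$risk_soft)
generate_cohort <- function(n, seed = 1L,
                            calibration = cohort_calibration()) {
  stopifnot(n >= 1)
  set.seed(seed)
  cal <- calibration
  cw <- default_census_weights()
  band_w <- stats::aggregate(weight ~ age_group, data = cw, FUN = sum)
  band <- sample(band_w$age_group, n, replace = TRUE, prob = band_w$weight)
  lo <- as.numeric(sub("-.*", "", band))
  hi <- as.numeric(sub(".*-", "", band))
  age <- lo + stats::runif(n) * (hi - lo)
  male <- stats::rbinom(n, 1, 0.5)
  region <- sample(paste0(rep(c("urban_", "rural_"), each = 5), 1:5),
                   n, replace = TRUE)
  h_death <- background_mortality(age, male)

  z_raw <- 0.055 * (age - 52) + 0.25 * male + stats::rnorm(n, 0, 0.75)
  standardize <- function(z) {
    z <- z - stats::median(z)
    sdz <- stats::sd(z)
    if (n < 2 || !is.finite(sdz) || sdz == 0) return(rep(0, n))
    z / sdz
  }
  z_soft <- standardize(z_raw)
  z_hard <- standardize(z_raw + stats::rnorm(n, 0, 0.25 *
                                               max(stats::sd(z_raw), 1e-12)))

  risk_from <- function(med, s, z) pmin(med * exp(s * z), 0.95)
  # solve the spread for a 12-year event-fraction target; in degenerate
  # cohorts (tiny n, no risk variation) the target may be unreachable and
  # the nearest bound is used
  solve_spread <- function(f) {
    lo <- 0.05; hi <- 4
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
      warning("Event-fraction target unreachable for this cohort; ",
              "using nearest spread bound.", call. = FALSE)
      return(if (is.finite(flo) && abs(flo) <= abs(fhi)) lo else hi)
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  # soft spread: first soft event competes with background death only
  s_soft <- solve_spread(function(s) {
    h <- -log(1 - risk_from(cal$median_soft, s, z_soft)) / 10
    event_fraction(h, h + h_death, cal$followup_years) - cal$frac12_soft
  })
  risk_soft <- risk_from(cal$median_soft, s_soft, z_soft)
  h_soft <- -log(1 - risk_soft) / 10
  # hard spread: a hard first event competes with soft-only events too,
  # since only the first event is classified
  s_hard <- solve_spread(function(s) {
    h <- pmin(-log(1 - risk_from(cal$median_hard, s, z_hard)) / 10, h_soft)
    event_fraction(h, h_soft + h_death, cal$followup_years) -
      cal$frac12_hard
  })
  risk_hard <- pmin(risk_from(cal$median_hard, s_hard, z_hard), risk_soft)
  h_hard <- pmin(-log(1 - risk_hard) / 10, h_soft)

  out <- tibble::tibble(
    id = seq_len(n), age = age, sex = ifelse(male == 1, "male", "female"),
    region = region, risk_soft = risk_soft, risk_hard = risk_hard,
    h_soft = h_soft, h_hard = h_hard, h_death = h_death)
  attr(out, "calibration") <- cal
  class(out) <- c("synthetic_cohort", class(out))
  out
}

#' Regionally recalibrate predicted risks
#'
#' Rescales predicted 10-year risks within each region on the
#' log-cumulative-hazard scale (risk -> 1 - (1 - risk)^k) so that the
#' regional mean predicted risk equals the observed regional 10-year risk.
#' The transform is monotone, so within-region ordering is preserved.
#'
#' @param risks Predicted 10-year risks in `(0, 1)`.
#' @param region Region label per individual.
#' @param observed Named vector of observed regional 10-year risks.
#' @return Recalibrated risks.
#' @export
recalibrate_risk <- function(risks, region, observed) {
  if (any(observed <= 0 | observed >= 1)) {
    stop("Observed regional risks must lie strictly in (0, 1).",
         call. = FALSE)
  }
  out <- risks
  for (r in unique(region)) {
    idx <- region == r
    if (!r %in% names(observed)) {
      stop("No observed risk for region: ", r, call. = FALSE)
    }
    target <- observed[[r]]
    cumhaz <- -log(1 - risks[idx])
    f <- function(k) mean(1 - exp(-k * cumhaz)) - target
    k <- stats::uniroot(f, c(1e-6, 1e6), tol = 1e-12)$root
    out[idx] <- 1 - exp(-k * cumhaz)
  }
  out
}

#' Simulate first-event follow-up
#'
#' Draws exponential first-event times from each individual's latent hazards
#' under competing background mortality, censored at `years`. A first ASCVD
#' event is classified hard with probability h_hard/h_soft and allocated to
#' acute MI / IS / fatal ASCVD by the calibration split; soft-only events
#' are other (non-MI) IHD. Background deaths are recorded as fatal
#' non-ASCVD.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param years Censoring time (> 0); default from the cohort's calibration.
#' @param seed Integer RNG seed.
#' @return Tibble of events: `id`, `event_type`, `time`; attribute
#'   `censor_time`.
#' @export
simulate_followup <- function(cohort, years = NULL, seed = 1L) {
  cal <- attr(cohort, "calibration")
  if (is.null(years)) years <- if (!is.null(cal)) cal$followup_years else 12
  if (years <= 0) stop("`years` must be positive.", call. = FALSE)
  set.seed(seed)
  n <- nrow(cohort)
  h_tot <- cohort$h_soft + cohort$h_death
  t1 <- ifelse(h_tot > 0, stats::rexp(n, pmax(h_tot, 1e-300)), Inf)
  observed <- t1 <= years
  is_ascvd <- observed & (stats::runif(n) * h_tot < cohort$h_soft)
  is_hard <- is_ascvd &
    (stats::runif(n) * cohort$h_soft < cohort$h_hard)
  split <- if (!is.null(cal)) cal$hard_split else
    c(acute_MI = 0.20, IS = 0.55, fatal_ASCVD = 0.25)
  type <- rep(NA_character_, n)
  type[observed & !is_ascvd] <- "fatal_non_ASCVD"
  type[is_ascvd & !is_hard] <- "other_IHD"
  n_hard <- sum(is_hard)
  if (n_hard > 0) {
    type[is_hard] <- sample(names(split), n_hard, replace = TRUE,
                            prob = split)
  }
  out <- tibble::tibble(id = cohort$id[observed],
                        event_type = type[observed],
                        time = t1[observed])
  attr(out, "censor_time") <- years
  out
}

#' Estimate a transition table from simulated follow-up
#'
#' Computes 10-year cumulative first-event probabilities from the
#' disease-free state per (sex, age band, risk group) stratum, where risk
#' groups are defined by the given threshold on the chosen risk model;
#' censoring is treated as event-free (simple proportions). Post-first-event
#' rows are whole-population averages: census-weighted mean annual
#' disease-free event probabilities scaled by a recurrence multiplier, with
#' event-specific case-fatality additions. The returned table carries the
#' cell-level eligible fractions as an `eligibility` attribute.
#'
#' @param events [simulate_followup()] output.
#' @param cohort The matching [generate_cohort()] tibble.
#' @param census_weights Tibble from [default_census_weights()].
#' @param threshold Risk threshold (fraction); `NA` estimates only `overall`
#'   rows.
#' @param model `"soft"` or `"hard"`.
#' @param recurrence_mult Multiplier on overall event rates for post-event
#'   recurrence.
#' @param case_fatality Named additions to the annual fatal-ASCVD
#'   probability after each non-fatal event.
#' @return A [transition_table()] with attribute `eligibility`.
#' @export
estimate_transition_table <- function(events, cohort,
                                      census_weights = default_census_weights(),
                                      threshold = NA_real_,
                                      model = c("soft", "hard"),
                                      recurrence_mult = 1.5,
                                      case_fatality = c(
                                        nonfatal_acute_MI = 0.030,
                                        nonfatal_other_IHD = 0.010,
                                        nonfatal_IS = 0.025)) {
  model <- match.arg(model)
  ev_states <- c(acute_MI = "nonfatal_acute_MI",
                 other_IHD = "nonfatal_other_IHD",
                 IS = "nonfatal_IS",
                 fatal_ASCVD = "fatal_ASCVD",
                 fatal_non_ASCVD = "fatal_non_ASCVD")
  first <- events[events$time <= 10, , drop = FALSE]
  type10 <- stats::setNames(rep(NA_character_, nrow(cohort)), cohort$id)
  type10[as.character(first$id)] <- first$event_type

  band <- age_to_band(cohort$age)
  risk <- cohort[[paste0("risk_", model)]]
  eligible <- if (is.na(threshold)) rep(NA, nrow(cohort)) else
    risk >= threshold

  groups <- if (is.na(threshold)) "overall" else
    c("eligible", "non_eligible", "overall")
  rows <- list()
  for (sx in unique(cohort$sex)) {
    for (bd in age_bands()) {
      for (grp in groups) {
        idx <- cohort$sex == sx & band == bd
        if (grp == "eligible") idx <- idx & eligible
        if (grp == "non_eligible") idx <- idx & !eligible
        if (sum(idx) == 0) {
          warning(sprintf("Empty stratum (%s, %s, %s); probabilities missing.",
                          sx, bd, grp), call. = FALSE)
          p10 <- stats::setNames(rep(NA_real_, length(ev_states)),
                                 unname(ev_states))
        } else {
          tt <- type10[idx]
          p10 <- stats::setNames(
            vapply(names(ev_states), function(e)
              sum(tt == e, na.rm = TRUE) / sum(idx), numeric(1)),
            unname(ev_states))
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, age_group = bd, risk_group = grp,
          from_state = "disease_free", to_state = names(p10),
          horizon = "p10", value = unname(p10))
      }
    }
  }
  df_rows <- do.call(rbind, rows)

  # whole-population average annual rates, census-weighted across cells
  overall <- df_rows[df_rows$risk_group == "overall" &
                       !is.na(df_rows$value), , drop = FALSE]
  cw <- as.data.frame(census_weights)
  merged <- merge(overall, cw, by = c("sex", "age_group"))
  p1_overall <- vapply(unname(ev_states), function(st) {
    sub <- merged[merged$to_state == st, , drop = FALSE]
    if (nrow(sub) == 0) return(0)
    w <- sub$weight / sum(sub$weight)
    sum(w * annualize_probability(sub$value))
  }, numeric(1))

  post <- list()
  for (from in nonfatal_event_states()) {
    dest <- setdiff(unname(ev_states), from)
    p1 <- p1_overall[dest] * recurrence_mult
    p1["fatal_ASCVD"] <- p1["fatal_ASCVD"] + case_fatality[[from]]
    post[[from]] <- tibble::tibble(
      sex = "all", age_group = "all", risk_group = "overall",
      from_state = from, to_state = dest, horizon = "p1",
      value = pmin(unname(p1), 0.99))
  }
  tab <- transition_table(rbind(df_rows, do.call(rbind, post)))

  if (!is.na(threshold)) {
    strat <- stratify_by_threshold(risk, threshold, census_weights,
                                   sex = cohort$sex, age = cohort$age)
    elig_cells <- strat$by_cell
  } else {
    elig_cells <- NULL
  }
  attr(tab, "eligibility") <- elig_cells
  attr(tab, "threshold") <- threshold
  attr(tab, "model") <- model
  tab
}
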