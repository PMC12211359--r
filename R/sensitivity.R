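#' Sample one parameter set for probabilistic sensitivity analysis
#'
#' Log-normal parameters use meanlog = ln(base) and sdlog = (ln(high) -
#' ln(low))/3.92 (the 2 x 1.96 normal-range convention); beta and gamma
#' parameters are method-of-moments fits with mean = base and sd = (high -
#' low)/3.92; fixed parameters return their base value. Draws are
#' reproducible under the seed.
#'
#' @param specs Parameter manifest, as from [default_parameter_table()].
#' @param seed Integer RNG seed.
#' @return Named numeric vector, one value per manifest row.
#' @export
#' @examples
#' sample_parameters(default_parameter_table(), seed = 7)["rr_nonfatal_ihd"]
sample_parameters <- function(specs, seed = 1L) {
  set.seed(seed)
  vals <- numeric(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    base <- specs$base[i]; low <- specs$low[i]; high <- specs$high[i]
    sdv <- (high - low) / 3.92
    vals[i] <- switch(specs$distribution[i],
      fixed = base,
      lognormal = stats::rlnorm(1, meanlog = log(base),
                                sdlog = (log(high) - log(low)) / 3.92),
      gamma = {
        if (sdv <= 0) base else
          stats::rgamma(1, shape = (base / sdv)^2, rate = base / sdv^2)
      },
      beta = {
        if (sdv <= 0) {
          base
        } else {
          if (sdv^2 >= base * (1 - base)) {
            stop(sprintf(
              "Infeasible beta moments for parameter '%s' (sd too large).",
              specs$name[i]), call. = FALSE)
          }
          nu <- base * (1 - base) / sdv^2 - 1
          stats::rbeta(1, shape1 = base * nu, shape2 = (1 - base) * nu)
        }
      },
      stop("Unknown distribution: ", specs$distribution[i], call. = FALSE))
  }
  stats::setNames(vals, specs$name)
}

#' One-way (tornado) sensitivity of an ICER to a single parameter
#'
#' Re-runs a two-strategy comparison twice with one parameter at its lower
#' and upper bound, everything else at base case, and reports both ICERs and
#' the absolute swing.
#'
#' @param evaluate_pair Function taking a named parameter vector of
#'   overrides and returning a two-row data frame with `cost` and `qalys`
#'   (any order of effectiveness).
#' @param param One row of the parameter manifest, or a parameter name to
#'   look up in `table`.
#' @param table Parameter manifest.
#' @return One-row tibble: `name`, `low`, `high`, `icer_low`, `icer_high`,
#'   `swing`.
#' @export
one_way_sensitivity <- function(evaluate_pair, param,
                                table = default_parameter_table()) {
  if (is.character(param)) {
    param <- table[table$name == param, , drop = FALSE]
    if (nrow(param) == 0) stop("Unknown parameter name.", call. = FALSE)
  }
  icer_at <- function(value) {
    out <- evaluate_pair(stats::setNames(value, param$name))
    icer(out[which.max(out$qalys), ], out[which.min(out$qalys), ])
  }
  lo <- icer_at(param$low)
  hi <- icer_at(param$high)
  tibble::tibble(name = param$name, low = param$low, high = param$high,
                 icer_low = lo, icer_high = hi, swing = abs(hi - lo))
}

#' Tornado table over every manifest parameter
#'
#' @inheritParams one_way_sensitivity
#' @param names Parameters to vary (default: all with `low < high`).
#' @return Tibble sorted by decreasing swing.
#' @export
tornado <- function(evaluate_pair, table = default_parameter_table(),
                    names = NULL) {
  if (is.null(names)) names <- table$name[table$low < table$high]
  rows <- lapply(names, function(nm)
    one_way_sensitivity(evaluate_pair, nm, table))
  out <- do.call(rbind, rows)
  out[order(-out$swing), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter sets from the manifest distributions and
#' re-evaluates the full strategy grid for each. Iteration seeds are derived
#' from a single master seed (substreams per iteration index), so the first
#' `n` iterations are reproduced when `n` is increased under the same seed.
#' Iterations whose parameter draw yields an invalid model (e.g. transition
#' rows summing above 1) are re-drawn and counted.
#'
#' @param evaluate_grid Function taking a named parameter vector and
#'   returning a data frame of per-strategy outcomes with columns `cost`,
#'   `qalys` and an identifier column (`threshold` or `label`).
#' @param specs Parameter manifest.
#' @param n Number of iterations (>= 1).
#' @param seed Master RNG seed.
#' @return `psa_result`: list with `draws` (n x p matrix), `outcomes` (list
#'   of per-iteration tibbles), `n`, `seed`, `redraws`.
#' @export
run_psa <- function(evaluate_grid, specs = default_parameter_table(),
                    n = 1000, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
  draws <- matrix(NA_real_, n, nrow(specs),
                  dimnames = list(NULL, specs$name))
  outcomes <- vector("list", n)
  redraws <- 0L
  for (i in seq_len(n)) {
    s <- iter_seeds[i]
    for (attempt in 1:25) {
      draw <- sample_parameters(specs, seed = s)
      res <- tryCatch(evaluate_grid(draw), error = function(e) e)
      if (!inherits(res, "error")) break
      redraws <- redraws + 1L
      s <- (s + 999983L * attempt) %% (.Machine$integer.max - 1L) + 1L
    }
    if (inherits(res, "error")) {
      stop("PSA iteration ", i, " failed repeatedly: ",
           conditionMessage(res), call. = FALSE)
    }
    draws[i, ] <- draw
    outcomes[[i]] <- tibble::as_tibble(res)
  }
  structure(list(draws = draws, outcomes = outcomes, n = n, seed = seed,
                 redraws = redraws), class = "psa_result")
}

psa_labels <- function(outcome) {
  if ("label" %in% names(outcome)) return(as.character(outcome$label))
  if ("threshold" %in% names(outcome)) {
    lab <- ifelse(is.na(outcome$threshold), "no_treatment",
                  format(outcome$threshold, trim = TRUE))
    if ("model" %in% names(outcome)) {
      lab <- ifelse(lab == "no_treatment", lab,
                    paste(outcome$model, lab, sep = "_"))
    }
    return(lab)
  }
  as.character(seq_len(nrow(outcome)))
}

#' Cost-utility acceptability curve
#'
#' For each willingness-to-pay value, the probability (fraction of PSA
#' iterations) that each strategy has the highest net monetary benefit
#' (QALYs x WTP - cost). Probabilities sum to 1 at every WTP.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Numeric vector of WTP values (non-empty); default 0 to
#'   40,000 USD/QALY in 500-unit steps.
#' @return Tibble with columns `wtp`, `strategy`, `probability`.
#' @export
acceptability_curve <- function(psa, wtp_grid = seq(0, 40000, by = 500)) {
  if (length(wtp_grid) == 0) stop("Empty WTP grid.", call. = FALSE)
  if (length(psa$outcomes) == 0) stop("Empty PSA result.", call. = FALSE)
  labels <- psa_labels(psa$outcomes[[1]])
  wins <- matrix(0, length(wtp_grid), length(labels),
                 dimnames = list(NULL, labels))
  for (out in psa$outcomes) {
    stopifnot(identical(psa_labels(out), labels))
    nmb <- outer(wtp_grid, out$qalys) - matrix(out$cost, length(wtp_grid),
                                               nrow(out), byrow = TRUE)
    best <- max.col(nmb, ties.method = "first")
    wins[cbind(seq_along(wtp_grid), best)] <-
      wins[cbind(seq_along(wtp_grid), best)] + 1
  }
  probs <- wins / length(psa$outcomes)
  tibble::tibble(
    wtp = rep(wtp_grid, times = length(labels)),
    strategy = rep(labels, each = length(wtp_grid)),
    probability = as.vector(probs))
}

#' Plot acceptability curves
#'
#' @param curve Output of [acceptability_curve()].
#' @param wtp_marks Optional WTP anchors drawn as dashed vertical lines.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_acceptability <- function(curve, wtp_marks = c(10274, 30823)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting.", call. = FALSE)
  }
  p <- ggplot2::ggplot(curve, ggplot2::aes(
    x = .data$wtp, y = .data$probability, colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay (US$/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
  if (length(wtp_marks) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = wtp_marks, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}
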