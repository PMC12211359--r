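#' Incremental cost-effectiveness ratio
#'
#' Incremental cost per QALY gained between two strategies, signed as
#' more-effective versus less-effective.
#'
#' @param a,b Either `strategy_outcome` rows or lists/vectors with `cost` and
#'   `qalys` elements.
#' @return USD per QALY.
#' @export
#' @examples
#' icer(c(cost = 3099.32, qalys = 14.0038), c(cost = 2904.86, qalys = 13.9412))
icer <- function(a, b) {
  ca <- as.numeric(a[["cost"]]); qa <- as.numeric(a[["qalys"]])
  cb <- as.numeric(b[["cost"]]); qb <- as.numeric(b[["qalys"]])
  if (qa == qb) {
    stop("Equal QALYs: ICER undefined; classify by dominance instead.",
         call. = FALSE)
  }
  if (qa > qb) (ca - cb) / (qa - qb) else (cb - ca) / (qb - qa)
}

#' Build the cost-effectiveness frontier
#'
#' Classifies strategies by iterative dominance elimination: strategies with
#' higher cost and no more QALYs than another are strictly dominated;
#' remaining strategies are ordered by effectiveness and adjacent ICERs
#' computed; any strategy whose ICER exceeds that of the next more effective
#' strategy is removed by extended dominance, and ICERs recomputed, until the
#' ladder is strictly increasing. The least effective remaining strategy is
#' the reference.
#'
#' @param outcomes Data frame with one row per strategy and columns `cost`,
#'   `qalys`, plus any identifier columns (carried through).
#' @return The input tibble with added columns `status` (`"reference"`,
#'   `"frontier"`, `"dominated"`, `"extended_dominance"`) and `icer` (final
#'   frontier ICER versus the previous frontier strategy; `NA` otherwise),
#'   class `frontier_result`.
#' @export
build_frontier <- function(outcomes) {
  outcomes <- tibble::as_tibble(outcomes)
  n <- nrow(outcomes)
  if (n < 2) stop("Need at least two strategies.", call. = FALSE)
  cost <- outcomes$cost
  qaly <- outcomes$qalys

  status <- rep(NA_character_, n)
  # identical (cost, QALY) pairs: keep the first listed
  dup <- duplicated(paste(signif(cost, 12), signif(qaly, 12)))
  if (any(dup)) {
    warning("Identical (cost, QALY) pairs; keeping the first listed.",
            call. = FALSE)
    status[dup] <- "dominated"
  }
  # strict dominance: some other strategy costs no more and yields at least
  # as many QALYs, with at least one strict inequality
  for (i in seq_len(n)) {
    if (!is.na(status[i])) next
    for (j in seq_len(n)) {
      if (i == j || isTRUE(status[j] == "dominated")) next
      if (cost[j] <= cost[i] && qaly[j] >= qaly[i] &&
          (cost[j] < cost[i] || qaly[j] > qaly[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }
  active <- which(is.na(status))
  active <- active[order(qaly[active], cost[active])]
  # extended dominance: remove until adjacent ICERs strictly increase
  repeat {
    if (length(active) < 3) break
    icers <- diff(cost[active]) / diff(qaly[active])
    bad <- which(diff(icers) <= 0)
    if (length(bad) == 0) break
    # icers[k] is strategy active[k+1]'s ICER; non-increasing step at k
    # means active[bad[1] + 1] is extended-dominated
    drop_idx <- active[bad[1] + 1]
    status[drop_idx] <- "extended_dominance"
    active <- setdiff(active, drop_idx)
  }
  status[active[1]] <- "reference"
  if (length(active) > 1) status[active[-1]] <- "frontier"

  icer_col <- rep(NA_real_, n)
  if (length(active) > 1) {
    icer_col[active[-1]] <- diff(cost[active]) / diff(qaly[active])
  }
  outcomes$status <- status
  outcomes$icer <- icer_col
  class(outcomes) <- c("frontier_result", class(outcomes))
  outcomes
}

#' @export
print.frontier_result <- function(x, ...) {
  y <- tibble::as_tibble(x)
  y$icer <- ifelse(is.na(y$icer) & y$status == "reference", NA, y$icer)
  lab <- c(reference = "Ref", frontier = "frontier",
           dominated = "Dominated", extended_dominance = "Extended dominance")
  y$status <- lab[y$status]
  print(y, ...)
  invisible(x)
}

#' Select the optimal strategy at a willingness-to-pay
#'
#' Walks the frontier ladder and returns the most effective frontier strategy
#' whose ICER (versus the previous frontier strategy) does not exceed the
#' willingness-to-pay; the reference strategy if none qualifies.
#'
#' @param frontier A [build_frontier()] result.
#' @param wtp Willingness-to-pay, USD per QALY.
#' @return The selected row of the frontier tibble.
#' @export
select_optimal <- function(frontier, wtp) {
  if (nrow(frontier) == 0) stop("Empty frontier.", call. = FALSE)
  on_front <- frontier$status %in% c("reference", "frontier")
  cand <- frontier[on_front, , drop = FALSE]
  cand <- cand[order(cand$qalys), , drop = FALSE]
  ok <- is.na(cand$icer) | cand$icer <= wtp
  # the ladder is increasing, so the qualifying set is a prefix
  last_ok <- max(which(ok))
  cand[last_ok, , drop = FALSE]
}

#' Compare soft- and hard-model strategies at matched treated proportions
#'
#' Pairs each soft-model strategy with the hard-model strategy whose eligible
#' fraction is nearest (within `tolerance` percentage points) and classifies
#' the soft strategy as strongly dominant (cheaper with more QALYs),
#' dominated, or reports the ICER versus its hard-model comparator.
#'
#' @param soft_outcomes,hard_outcomes Strategy-outcome tibbles with columns
#'   `threshold`, `eligible_pct`, `cost`, `qalys`.
#' @param tolerance Maximum eligible-fraction gap, percentage points.
#' @return Tibble, one row per matched pair, with `verdict` in
#'   `{"strongly_dominant", "dominated", "icer"}` and the ICER where defined.
#' @export
matched_proportion_comparison <- function(soft_outcomes, hard_outcomes,
                                          tolerance = 1) {
  soft <- tibble::as_tibble(soft_outcomes)
  hard <- tibble::as_tibble(hard_outcomes)
  soft <- soft[!is.na(soft$threshold), , drop = FALSE]
  hard <- hard[!is.na(hard$threshold), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(soft))) {
    gap <- abs(hard$eligible_pct - soft$eligible_pct[i])
    j <- which.min(gap)
    if (length(j) == 0 || gap[j] > tolerance) {
      warning(sprintf(
        "No hard-model strategy within %.1f pp of soft threshold %s; skipped.",
        tolerance, format(soft$threshold[i])), call. = FALSE)
      next
    }
    dc <- soft$cost[i] - hard$cost[j]
    dq <- soft$qalys[i] - hard$qalys[j]
    verdict <- if (dc < 0 && dq > 0) {
      "strongly_dominant"
    } else if (dc > 0 && dq < 0) {
      "dominated"
    } else {
      "icer"
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      soft_threshold = soft$threshold[i],
      hard_threshold = hard$threshold[j],
      soft_eligible_pct = soft$eligible_pct[i],
      hard_eligible_pct = hard$eligible_pct[j],
      delta_cost = dc, delta_qalys = dq,
      verdict = verdict,
      icer = if (verdict == "icer" && dq != 0)
        icer(soft[i, ], hard[j, ]) else NA_real_)
  }
  do.call(rbind, rows)
}
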