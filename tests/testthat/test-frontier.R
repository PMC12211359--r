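test_that("ICERs reproduce published worked examples", {
  expect_equal(icer(c(cost = 3099.32, qalys = 14.0038),
                    c(cost = 2904.86, qalys = 13.9412)),
               3106.39, tolerance = 1e-2 / 3106.39)
  expect_equal(icer(c(cost = 3099.47, qalys = 14.0051),
                    c(cost = 3099.32, qalys = 14.0038)),
               115.38, tolerance = 1e-2 / 115.38)
  # order of arguments does not change the ratio
  expect_equal(icer(c(cost = 2904.86, qalys = 13.9412),
                    c(cost = 3099.32, qalys = 14.0038)),
               3106.39, tolerance = 1e-2 / 3106.39)
  expect_error(icer(c(cost = 1, qalys = 2), c(cost = 3, qalys = 2)),
               "Equal QALYs")
})

test_that("frontier classification matches the published soft-model table", {
  fr <- build_frontier(reference_strategy_table("soft"))
  status <- stats::setNames(fr$status, ifelse(is.na(fr$threshold), "nt",
                                              fr$threshold))
  expect_equal(unname(status["nt"]), "reference")
  expect_equal(unname(status[c("12", "11", "10")]), rep("dominated", 3))
  expect_equal(unname(status["16"]), "extended_dominance")
  expect_equal(unname(status[c("20", "19", "18", "17", "15", "14", "13")]),
               rep("frontier", 7))
  # frontier ICERs strictly increase with effectiveness
  onf <- fr[fr$status == "frontier", ]
  onf <- onf[order(onf$qalys), ]
  expect_true(all(diff(onf$icer) > 0))
})

test_that("simple dominance cases classify as expected", {
  two <- tibble::tibble(label = c("a", "b"),
                        cost = c(100, 90), qalys = c(1, 2))
  fr <- build_frontier(two)
  expect_equal(fr$status, c("dominated", "reference"))
  expect_error(build_frontier(two[1, ]), "at least two")
  expect_warning(
    build_frontier(tibble::tibble(cost = c(1, 1, 2), qalys = c(1, 1, 2))),
    "Identical")
})

test_that("optimal threshold selection matches published conclusions", {
  soft <- build_frontier(reference_strategy_table("soft"))
  hard <- build_frontier(reference_strategy_table("hard"))
  expect_equal(select_optimal(soft, 10274)$threshold, 18)
  expect_equal(select_optimal(hard, 10274)$threshold, 10)
  # at the upper WTP the 7.5% strategy is still rejected, 8% selected
  expect_equal(select_optimal(hard, 30823)$threshold, 8)
  # a WTP below the cheapest ladder step returns the reference
  expect_true(is.na(select_optimal(soft, 100)$threshold))
})

test_that("raising the WTP never selects a less effective strategy", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    out <- tibble::tibble(cost = stats::runif(n, 0, 5000),
                          qalys = stats::runif(n, 10, 15))
    fr <- build_frontier(out)
    wtps <- sort(stats::runif(6, 0, 60000))
    q <- vapply(wtps, function(w) select_optimal(fr, w)$qalys, numeric(1))
    expect_true(all(diff(q) >= 0))
  }
})

test_that("frontier membership equals the brute-force dominance oracle", {
  # oracle: a strategy is off the frontier iff some other strategy (or a
  # convex combination of two others) achieves at least its QALYs for at
  # most its cost, with one strict inequality
  oracle_on_frontier <- function(cost, qalys) {
    n <- length(cost)
    on <- rep(TRUE, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && cost[j] <= cost[i] && qalys[j] >= qalys[i] &&
            (cost[j] < cost[i] || qalys[j] > qalys[i])) {
          on[i] <- FALSE
        }
      }
      if (!on[i]) next
      for (j in seq_len(n)) {
        for (k in seq_len(n)) {
          if (j == i || k == i || qalys[j] >= qalys[k]) next
          if (qalys[j] < qalys[i] && qalys[i] < qalys[k]) {
            lam <- (qalys[i] - qalys[j]) / (qalys[k] - qalys[j])
            mix_cost <- (1 - lam) * cost[j] + lam * cost[k]
            if (mix_cost < cost[i]) on[i] <- FALSE
          }
        }
      }
    }
    on
  }
  set.seed(20)
  for (trial in 1:300) {
    n <- sample(3:12, 1)
    cost <- stats::runif(n, 0, 1000)
    qalys <- stats::runif(n, 0, 10)
    fr <- build_frontier(tibble::tibble(cost = cost, qalys = qalys))
    got <- fr$status %in% c("reference", "frontier")
    expect_equal(got, oracle_on_frontier(cost, qalys))
  }
})

test_that("matched-proportion comparison reproduces published verdicts", {
  soft <- reference_strategy_table("soft")
  hard <- reference_strategy_table("hard")
  cmp <- suppressWarnings(matched_proportion_comparison(soft, hard))
  row20 <- cmp[cmp$soft_threshold == 20, ]
  expect_equal(row20$hard_threshold, 12)
  expect_equal(row20$verdict, "strongly_dominant")
  row17 <- cmp[cmp$soft_threshold == 17, ]
  expect_equal(row17$hard_threshold, 10)
  expect_equal(row17$icer, 115.38, tolerance = 1e-2 / 115.38)
  # identical outcomes: neither dominant, no ICER
  same <- tibble::tibble(threshold = 1, eligible_pct = 10, cost = 5,
                         qalys = 2)
  out <- matched_proportion_comparison(same, same)
  expect_equal(out$verdict, "icer")
  expect_true(is.na(out$icer))
  # pairing warning when nothing is close enough
  far <- tibble::tibble(threshold = 2, eligible_pct = 50, cost = 5,
                        qalys = 2)
  expect_warning(matched_proportion_comparison(same, far), "skipped")
})
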