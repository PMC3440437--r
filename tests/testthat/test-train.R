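test_that("histograms match a hand tally on a six-window record", {
  counts <- count_matrix(cbind(c(0, 1, 2, 3, 1, 1),
                               c(3, 3, 0, 1, 2, 0)), 0.25, 2)
  labels <- state_sequence(c(1, 1, 2, 2, NA, 1), K = 2)
  bank <- build_histograms(counts, labels)
  expect_equal(bank$occupancy, c(3L, 2L))
  # channel 1 in state 1 saw counts {0, 1, 1}
  expect_equal(bank$in_state[1, 1, ], c(1L, 2L, 0L, 0L))
  expect_equal(bank$in_state[1, 2, ], c(1L, 0L, 0L, 2L))
  expect_equal(bank$in_state[2, 1, ], c(0L, 0L, 1L, 1L))
  expect_equal(bank$in_state[2, 2, ], c(1L, 1L, 0L, 0L))
  # out-of-state histograms are the complement over labeled windows
  expect_equal(bank$out_state[1, 1, ], bank$in_state[2, 1, ])
  expect_equal(bank$out_state[2, 2, ], bank$in_state[1, 2, ])
})

test_that("histogram mass is conserved per (state, channel)", {
  set.seed(21)
  fx <- random_bank(120, 5, 4)
  for (k in 1:4) for (i in 1:5) {
    expect_equal(sum(fx$bank$in_state[k, i, ]), fx$bank$occupancy[k])
    expect_equal(sum(fx$bank$out_state[k, i, ]),
                 sum(fx$bank$occupancy[-k]))
  }
  expect_error(build_histograms(
    fx$counts, state_sequence(rep(NA, 120), 4)), "unknown")
})

test_that("threshold metrics are exact on separated and symmetric cases", {
  # all in-state mass at count 5, all out-of-state mass at 0
  counts <- count_matrix(cbind(c(rep(5, 10), rep(0, 10))), 0.25, 3)
  labels <- state_sequence(rep(c(1, 2), each = 10), K = 2)
  bank <- build_histograms(counts, labels)
  m <- threshold_metrics(bank, 1, 1, 1)
  expect_equal(unname(m), c(1, 1, 1))
  # identical distributions, equal priors -> ppv = 0.5 at any threshold
  counts2 <- count_matrix(cbind(rep(c(0, 2, 4, 6), times = 2)), 0.25, 3)
  labels2 <- state_sequence(rep(c(1, 2), each = 4), K = 2)
  bank2 <- build_histograms(counts2, labels2)
  for (theta in 1:4)
    expect_equal(threshold_metrics(bank2, 1, 1, theta)[["ppv"]], 0.5)
  expect_error(threshold_metrics(bank, 1, 1, 0), "1..2\\^b")
  expect_error(threshold_metrics(bank, 1, 1, 8), "1..2\\^b")
})

test_that("threshold metrics agree with a raw-count tally oracle", {
  set.seed(22)
  for (rep in 1:10) {
    fx <- random_bank(20, 3, 2)
    for (theta in 1:7) {
      m <- threshold_metrics(fx$bank, 1, 2, theta)
      o <- oracle_threshold_metrics(fx$counts, fx$labels, 1, 2, theta)
      expect_equal(m[["sensitivity"]], o[["sensitivity"]])
      expect_equal(m[["specificity"]], o[["specificity"]])
      if (!is.nan(o[["ppv"]])) expect_equal(m[["ppv"]], o[["ppv"]])
    }
  }
})

test_that("select_threshold returns the minimal qualifying threshold", {
  counts <- count_matrix(cbind(c(rep(5, 10), rep(0, 10))), 0.25, 3)
  labels <- state_sequence(rep(c(1, 2), each = 10), K = 2)
  bank <- build_histograms(counts, labels)
  expect_equal(select_threshold(bank, 1, 1, 0.9, 0.9), 1L)
  # identical histograms cannot reach ppv 0.99
  counts2 <- count_matrix(cbind(rep(c(1, 3), times = 4)), 0.25, 3)
  labels2 <- state_sequence(rep(c(1, 2), each = 4), K = 2)
  bank2 <- build_histograms(counts2, labels2)
  expect_true(is.na(select_threshold(bank2, 1, 1, 0.1, 0.99)))
})

test_that("select_threshold equals an exhaustive scan on random banks", {
  set.seed(23)
  for (rep in 1:40) {
    fx <- random_bank(30, 2, 3)
    smin <- runif(1)
    pmin_ <- runif(1)
    k <- sample(3, 1); i <- sample(2, 1)
    got <- select_threshold(fx$bank, k, i, smin, pmin_)
    ora <- oracle_select_threshold(fx$counts, fx$labels, k, i, smin,
                                   pmin_)
    expect_equal(got, ora)
    # minimality: theta - 1 violates a constraint (or theta is 1)
    if (!is.na(got) && got > 1L) {
      m <- threshold_metrics(fx$bank, k, i, got - 1L)
      ppv_ok <- if (pmin_ == 0) TRUE else isTRUE(m[["ppv"]] >= pmin_)
      expect_false(m[["sensitivity"]] >= smin && ppv_ok)
    }
  }
})

test_that("tightening the minima never adds qualifying channels", {
  set.seed(24)
  fx <- random_bank(200, 6, 4, lambda = 2)
  grid <- seq(0, 1, 0.25)
  for (k in 1:4) {
    qual <- function(smin, pmin_)
      which(!is.na(vapply(1:6, function(i)
        select_threshold(fx$bank, k, i, smin, pmin_), integer(1))))
    for (j in seq_len(length(grid) - 1)) {
      expect_true(all(qual(grid[j + 1], 0.3) %in% qual(grid[j], 0.3)))
      expect_true(all(qual(0.3, grid[j + 1]) %in% qual(0.3, grid[j])))
    }
  }
})

test_that("degenerate minima keep exactly M channels at threshold 1", {
  set.seed(25)
  fx <- random_bank(100, 5, 3, lambda = 2)
  ts <- learn_templates(fx$bank, 0, 0, M = 2)
  for (tp in ts$templates) {
    expect_equal(length(tp$channels), 2L)
    expect_true(all(tp$thresholds == 1L))
  }
})

test_that("disjoint one-channel-per-state fields recover their channel", {
  # channel k fires 5 spikes exactly when the state is k, silent otherwise
  K <- 4
  lab <- rep(1:K, times = 25)
  counts <- matrix(0L, length(lab), K)
  for (k in 1:K) counts[lab == k, k] <- 5L
  bank <- build_histograms(count_matrix(counts, 0.25, 3),
                           state_sequence(lab, K))
  ts <- learn_templates(bank, 0.9, 0.9, M = 2)
  for (k in 1:K) {
    expect_equal(ts$templates[[k]]$channels, k)
    expect_equal(ts$templates[[k]]$thresholds, 1L)
  }
})

test_that("learned templates always respect the M and range invariants", {
  set.seed(26)
  for (rep in 1:10) {
    fx <- random_bank(60, 4, 3)
    M <- sample(1:3, 1)
    ts <- learn_templates(fx$bank, runif(1), runif(1), M = M)
    for (tp in ts$templates) {
      expect_lte(length(tp$channels), M)
      if (length(tp$thresholds))
        expect_true(all(tp$thresholds >= 1L & tp$thresholds <= 7L))
    }
  }
})

test_that("per-state overrides of the minima are honored", {
  set.seed(27)
  fx <- random_bank(100, 4, 3, lambda = 2)
  strict <- learn_templates(fx$bank, 0.95, 0.95, M = 2)
  mixed <- learn_templates(fx$bank, 0.95, 0.95, M = 2,
                           per_state = list(list(state = 2,
                                                 sensitivity_min = 0,
                                                 ppv_min = 0)))
  expect_equal(length(mixed$templates[[2]]$channels), 2L)
  expect_equal(mixed$templates[[1]]$channels,
               strict$templates[[1]]$channels)
})
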