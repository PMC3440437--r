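test_that("classification metrics match hand arithmetic", {
  # state 1: TP = 8, FN = 2, FP = 1, TN = 89 over 100 windows
  lab <- c(rep(1, 10), rep(2, 90))
  bit1 <- c(rep(1, 8), 0, 0, 1, rep(0, 89))
  y <- decoder_output(cbind(bit1, 0L), 0.25)
  m <- classification_metrics(y, state_sequence(lab, K = 2))
  expect_equal(m$tp[1], 8L)
  expect_equal(m$sensitivity[1], 0.8)
  expect_equal(m$specificity[1], 89 / 90)
  expect_equal(m$ppv[1], 8 / 9)
  # perfect decoder
  bits <- matrix(0L, 100, 2)
  bits[cbind(1:100, lab)] <- 1L
  mp <- classification_metrics(decoder_output(bits, 0.25),
                               state_sequence(lab, 2))
  expect_equal(mp$sensitivity, c(1, 1))
  expect_equal(mp$specificity, c(1, 1))
  expect_equal(mp$ppv, c(1, 1))
  # degenerate all-zero output: ppv undefined, flagged not zeroed
  m0 <- classification_metrics(decoder_output(matrix(0L, 100, 2), 0.25),
                               state_sequence(lab, 2))
  expect_equal(m0$sensitivity, c(0, 0))
  expect_equal(m0$specificity, c(1, 1))
  expect_true(all(is.nan(m0$ppv)))
})

test_that("sensitivity and specificity are prevalence-invariant, ppv is not", {
  # a fixed decoding rule observed under two different state prevalences
  mk <- function(n1, n2) {
    lab <- c(rep(1, n1), rep(2, n2))
    # the rule: fire bit 1 on 80% of state-1 and 10% of state-2 windows
    bit1 <- c(rep(c(1, 1, 1, 1, 0), n1 / 5),
              rep(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), n2 / 10))
    classification_metrics(decoder_output(cbind(bit1, 0L), 0.25),
                           state_sequence(lab, 2))
  }
  a <- mk(50, 50)
  b <- mk(10, 200)
  expect_equal(a$sensitivity[1], b$sensitivity[1])
  expect_equal(a$specificity[1], b$specificity[1])
  expect_false(isTRUE(all.equal(a$ppv[1], b$ppv[1])))
})

test_that("trajectory correlation is exact on simple sequences", {
  s1 <- state_sequence(1:10, 10, segment_length = 0.1)
  expect_equal(trajectory_correlation(s1, s1), 1)
  rev1 <- state_sequence(10:1, 10, segment_length = 0.1)
  expect_equal(trajectory_correlation(rev1, s1), -1)
  a <- state_sequence(c(1, 2, 2, 4), 4)
  b <- state_sequence(c(1, 3, 2, 4), 4)
  expect_equal(trajectory_correlation(a, b),
               cor(c(1, 2, 2, 4), c(1, 3, 2, 4)))
  expect_true(is.nan(trajectory_correlation(
    state_sequence(rep(2, 5), 4), state_sequence(1:5, 5))))
})

test_that("compression factor matches hand arithmetic and scaling laws", {
  # 32 ch x 8 bit x 10 kHz = 2,560,000 bits/s in; 32 bits / 0.1 s out
  expect_equal(compression_factor(32, 8, 1e4, 32, 0.1), 8000)
  base <- compression_factor(32, 8, 1e4, 32, 0.1)
  expect_equal(compression_factor(64, 8, 1e4, 32, 0.1), 2 * base)
  expect_equal(compression_factor(32, 8, 1e4, 64, 0.1), base / 2)
  # factor depends on K and W only through K / W
  expect_equal(compression_factor(32, 8, 1e4, 64, 0.2), base)
  expect_error(compression_factor(0, 8, 1e4, 32, 0.1), "positive")
})

test_that("operation accounting sums its per-frame categories", {
  # one template, one threshold, single-comparison logic: hand sum
  # 1 clock + 1 memory + 1 mux + 1 comparison + 1 logic + 1 shift
  # + 1 output shift = 7 per frame
  fr <- op_count_frame(1, 1, b_logic = 1)
  expect_equal(unname(fr["total"]), 7)
  expect_equal(op_count(1, 1, frame_rate = 1), 7)
  # zero templates: overhead only
  expect_equal(unname(op_count_frame(0, 2)["total"]), 2)
  # monotone in templates, thresholds and frame rate
  expect_gt(op_count(33, 2, 10), op_count(32, 2, 10))
  expect_gt(op_count(32, 3, 10), op_count(32, 2, 10))
  expect_gt(op_count(32, 2, 11), op_count(32, 2, 10))
  # pure function: exact repeatability
  expect_identical(op_count(32, 2, 10), op_count(32, 2, 10))
})

test_that("leave-one-out returns one correlation per channel", {
  sc <- default_scenario(seed = 1, n_cells = 8, K = 8, track_length = 1,
                         traversals = 4)
  res <- run_pipeline(sc, quiet = TRUE)
  loo <- leave_one_out_eval(res$fit, res$spikes_test, res$truth,
                            seed = 7)
  expect_equal(nrow(loo$per_channel), 8L)
  expect_equal(loo$mean_r, mean(loo$per_channel$r))
  expect_equal(loo$max_r, max(loo$per_channel$r))
})

test_that("substituting a channel no template uses leaves r unchanged", {
  sc <- default_scenario(seed = 1, n_cells = 8, K = 8, track_length = 1,
                         traversals = 4)
  res <- run_pipeline(sc, quiet = TRUE)
  fit <- res$fit
  # rewire the decoder to ignore channel 8 entirely
  tps <- lapply(fit$templates$templates, function(tp) {
    keep <- tp$channels != 8L
    list(state = tp$state, channels = tp$channels[keep],
         thresholds = tp$thresholds[keep])
  })
  fit$templates <- template_set(tps, K = 8, M = fit$M, n_channels = 8)
  y <- predict(fit, spikes = res$spikes_test, type = "bits")
  fit$confusion <- estimate_confusion(y, res$truth, fit$pseudocount)
  base_r <- trajectory_correlation(
    predict(fit, spikes = res$spikes_test), res$truth)
  noisy <- res$spikes_test
  noisy$spikes[[8]] <- make_noise_channel(noisy$spikes[[8]],
                                          noisy$duration, seed = 99)
  r8 <- trajectory_correlation(predict(fit, spikes = noisy), res$truth)
  expect_equal(r8, base_r)
})
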