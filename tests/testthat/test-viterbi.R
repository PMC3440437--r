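test_that("a perfect decoder yields an identity confusion matrix", {
  K <- 4
  lab <- rep(1:K, times = 5)
  bits <- matrix(0L, length(lab), K)
  bits[cbind(seq_along(lab), lab)] <- 1L
  Q <- estimate_confusion(decoder_output(bits, 0.25),
                          state_sequence(lab, K), pseudocount = 0)
  expect_equal(unclass(Q), diag(K), ignore_attr = TRUE)
})

test_that("confusion ratios match a hand tally on ten windows", {
  lab <- state_sequence(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2), K = 2)
  bits <- cbind(c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0),
                c(0, 1, 0, 0, 0, 1, 1, 1, 0, 1))
  Q <- estimate_confusion(decoder_output(bits, 0.25), lab,
                          pseudocount = 0)
  expect_equal(unclass(Q), cbind(c(0.75, 0.25), c(0.2, 0.8)),
               ignore_attr = TRUE)
})

test_that("pseudocount smoothing keeps columns stochastic and positive", {
  set.seed(41)
  for (rep in 1:10) {
    K <- sample(2:5, 1)
    lab <- state_sequence(sample(K, 30, replace = TRUE), K)
    bits <- matrix(rbinom(30 * K, 1, 0.2), 30, K)
    bits[, 1] <- 0L  # a bit that never fires
    eps <- runif(1, 0.1, 2)
    Q <- estimate_confusion(decoder_output(bits, 0.25), lab, eps)
    expect_true(all(Q > 0))
    expect_equal(unname(colSums(Q)), rep(1, K))
    expect_error(estimate_confusion(decoder_output(bits, 0.25), lab, 0),
                 "pseudocount")
  }
})

test_that("emission probabilities multiply over set bits", {
  Q <- random_confusion(3)
  expect_equal(emission_prob(c(0, 0, 0), 2, Q), 1)  # empty product
  expect_equal(emission_prob(c(0, 1, 0), 2, Q), Q[2, 2])
  expect_equal(emission_prob(c(1, 0, 1), 3, Q), Q[3, 1] * Q[3, 3])
})

test_that("the transition kernel is row-stochastic with a hand-checked row", {
  model <- transition_model(K = 3, segment_length = 0.1, kappa = 0.02,
                            window_length = 0.25)
  P <- transition_matrix(model, tau = 0.25)  # kappa * tau = 0.005 m^2
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-12)
  # row 1 is (1, e^-1, e^-4) normalized
  expect_equal(unname(P[1, ]), c(0.7214, 0.2654, 0.0132),
               tolerance = 1e-3)
  expect_error(transition_model(3, 0.1, kappa = -1, 0.25), "kappa")
  expect_error(transition_matrix(model, 0.1), "one window")
})

test_that("the kernel broadens with tau toward the uniform limit", {
  model <- transition_model(K = 5, segment_length = 0.109, kappa = 0.01,
                            window_length = 0.25)
  taus <- 0.25 * (1:40)
  Ps <- lapply(taus, transition_matrix, model = model)
  for (j in 1:5) {
    self <- vapply(Ps, function(P) P[j, j], numeric(1))
    expect_true(all(diff(self) <= 1e-14))  # mass leaves the diagonal
    far <- vapply(Ps, function(P) P[j, which.max(model$distances[j, ])],
                  numeric(1))
    expect_true(all(diff(far) >= -1e-14))  # distant states gain mass
    ent <- vapply(Ps, function(P) -sum(P[j, ] * log(P[j, ])), numeric(1))
    expect_true(all(diff(ent) >= -1e-12))  # rows spread out
  }
  Pinf <- transition_matrix(model, 1e9 * max(model$distances)^2 /
                              model$kappa)
  expect_lt(max(abs(Pinf - 1 / 5)), 1e-6)
})

test_that("viterbi matches exhaustive path enumeration on small instances", {
  set.seed(42)
  for (rep in 1:40) {
    K <- sample(2:4, 1)
    n <- sample(2:6, 1)
    Q <- random_confusion(K)
    bits <- matrix(rbinom(n * K, 1, 0.4), n, K)
    y <- decoder_output(bits, 0.25)
    model <- transition_model(K, segment_length = 0.109,
                              kappa = runif(1, 0.005, 0.05),
                              window_length = 0.25)
    got <- viterbi(y, Q, model)
    ora <- oracle_viterbi(y, Q, model)
    expect_equal(as.integer(got), unname(ora$path))
    expect_equal(path_log_score(as.integer(got), y, Q, model),
                 log(ora$score), tolerance = 1e-10)
  }
})

test_that("log-domain path scores agree with probability-domain scores", {
  set.seed(43)
  K <- 3; n <- 6
  Q <- random_confusion(K)
  y <- decoder_output(matrix(rbinom(n * K, 1, 0.4), n, K), 0.25)
  model <- transition_model(K, 0.109, 0.01, 0.25)
  path <- as.integer(viterbi(y, Q, model))
  # probability-domain rescore of the same path
  prob <- oracle_viterbi(y, Q, model)$score
  expect_equal(path_log_score(path, y, Q, model), log(prob),
               tolerance = 1e-10)
})

test_that("K = 1 returns the only possible path", {
  y <- decoder_output(matrix(1L, 5, 1), 0.25)
  Q <- structure(matrix(1, 1, 1), pseudocount = 0,
                 class = c("confusion_matrix", "matrix", "array"))
  model <- transition_model(1, 0.1, 0.01, 0.25)
  expect_equal(as.integer(viterbi(y, Q, model)), rep(1L, 5))
})

test_that("noiseless staircase output is recovered exactly", {
  K <- 6
  truth <- rep(1:K, each = 3)
  bits <- matrix(0L, length(truth), K)
  bits[cbind(seq_along(truth), truth)] <- 1L
  y <- decoder_output(bits, 0.25)
  Q <- structure(diag(K) * 0.99 + 0.01 / K, pseudocount = 0,
                 class = c("confusion_matrix", "matrix", "array"))
  Q <- structure(sweep(unclass(Q), 2, colSums(unclass(Q)), "/"),
                 pseudocount = 0,
                 class = c("confusion_matrix", "matrix", "array"))
  model <- transition_model(K, 0.109, 0.01, 0.25)
  expect_equal(as.integer(viterbi(y, Q, model)), truth)
})

test_that("silent stretches never jump beyond the kappa-tau ball", {
  set.seed(44)
  K <- 10
  bits <- matrix(0L, 12, K)
  bits[1, 2] <- 1L
  bits[12, 8] <- 1L  # ten silent windows between two informative ones
  y <- decoder_output(bits, 0.25)
  Q <- random_confusion(K)
  diag_boost <- diag(K) * 3 + 1
  Q <- structure(sweep(unclass(Q) * diag_boost, 2,
                       colSums(unclass(Q) * diag_boost), "/"),
                 pseudocount = 0,
                 class = c("confusion_matrix", "matrix", "array"))
  model <- transition_model(K, 0.109, 0.01, 0.25)
  path <- as.integer(viterbi(y, Q, model))
  steps <- abs(diff(path))
  # the one-window kernel makes jumps beyond ~3 segments negligible,
  # and tau growth across the silent stretch only broadens gradually
  expect_true(all(steps <= 3))
})
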