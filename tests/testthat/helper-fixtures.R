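# shared fixture builders and independent oracles

# random count matrix with counts drawn uniformly over the b-bit range
random_counts <- function(n_win, n_ch, counter_bits = 3L,
                          window_length = 0.25) {
  cap <- 2L^counter_bits - 1L
  count_matrix(matrix(sample(0:cap, n_win * n_ch, replace = TRUE),
                      n_win, n_ch),
               window_length, counter_bits)
}

# random reduced template set: each state owns one template with up to
# max_entries (channel, threshold) pairs; some states may be empty
random_templates <- function(K, n_ch, max_entries = 2L,
                             counter_bits = 3L, p_empty = 0.2) {
  cap <- 2L^counter_bits - 1L
  tps <- lapply(seq_len(K), function(k) {
    n <- if (stats::runif(1) < p_empty) 0L
         else sample(seq_len(max_entries), 1)
    ch <- if (n) sample(n_ch, n) else integer(0)
    list(state = k, channels = ch,
         thresholds = if (n) sample(cap, n, replace = TRUE) else integer(0))
  })
  template_set(tps, K = K, M = max_entries, n_channels = n_ch,
               counter_bits = counter_bits)
}

# labeled training record with Poisson-ish counts for histogram tests
random_bank <- function(n_win, n_ch, K, counter_bits = 3L,
                        lambda = 1.5) {
  cap <- 2L^counter_bits - 1L
  counts <- count_matrix(
    matrix(pmin(stats::rpois(n_win * n_ch, lambda), cap), n_win, n_ch),
    0.25, counter_bits)
  labels <- state_sequence(sample(K, n_win, replace = TRUE), K)
  list(counts = counts, labels = labels,
       bank = build_histograms(counts, labels))
}

# independent threshold-quality oracle: tallies straight from the raw
# counts and labels, never touching the histogram bank
oracle_threshold_metrics <- function(counts, labels, state, channel,
                                     theta) {
  lab <- as.integer(labels)
  known <- !is.na(lab)
  x <- counts[known, channel]
  in_k <- lab[known] == state
  hit <- x >= theta
  c(sensitivity = mean(hit[in_k]),
    specificity = mean(!hit[!in_k]),
    ppv = sum(hit & in_k) / sum(hit))
}

oracle_select_threshold <- function(counts, labels, state, channel,
                                    smin, pmin_, cap = 7L) {
  for (theta in seq_len(cap)) {
    m <- oracle_threshold_metrics(counts, labels, state, channel, theta)
    ppv_ok <- if (pmin_ == 0) TRUE else isTRUE(m[["ppv"]] >= pmin_)
    if (m[["sensitivity"]] >= smin && ppv_ok) return(theta)
  }
  NA_integer_
}

# tau (windows) before each transition step, straight from its definition:
# time since the last window with any set bit, at least one window
oracle_tau <- function(bits) {
  n <- nrow(bits)
  vapply(2:n, function(t) {
    tau <- 1L
    s <- t - 1L
    while (s >= 1L && sum(bits[s, ]) == 0L) {
      tau <- tau + 1L
      s <- s - 1L
    }
    tau
  }, integer(1))
}

# exhaustive maximum a posteriori path by enumerating all K^T paths;
# scores in the probability domain, uniform initial distribution
oracle_viterbi <- function(output, Q, model) {
  bits <- unclass(output)
  n <- nrow(bits)
  K <- ncol(Q)
  W <- model$window_length
  tau_w <- if (n > 1) oracle_tau(bits) else integer(0)
  P <- lapply(unique(tau_w), function(u) transition_matrix(model, u * W))
  names(P) <- unique(tau_w)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  score <- apply(paths, 1, function(x) {
    s <- (1 / K) * emission_prob(bits[1, ], x[1], Q)
    if (n > 1) for (t in 2:n)
      s <- s * P[[as.character(tau_w[t - 1])]][x[t - 1], x[t]] *
        emission_prob(bits[t, ], x[t], Q)
    s
  })
  list(path = paths[which.max(score), ], score = max(score))
}

# probability of a given path under the same model (for score comparison)
path_log_score <- function(path, output, Q, model) {
  bits <- unclass(output)
  n <- nrow(bits)
  tau_w <- if (n > 1) oracle_tau(bits) else integer(0)
  s <- -log(ncol(Q)) + log(emission_prob(bits[1, ], path[1], Q))
  if (n > 1) for (t in 2:n) {
    P <- transition_matrix(model, tau_w[t - 1] * model$window_length)
    s <- s + log(P[path[t - 1], path[t]]) +
      log(emission_prob(bits[t, ], path[t], Q))
  }
  s
}

# random column-stochastic confusion matrix
random_confusion <- function(K) {
  Q <- matrix(stats::runif(K * K, 0.05, 1), K, K)
  Q <- sweep(Q, 2, colSums(Q), "/")
  structure(Q, pseudocount = 0,
            class = c("confusion_matrix", "matrix", "array"))
}
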