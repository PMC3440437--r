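#' Decoder confusion matrix (emission model)
#'
#' Estimates Q(j, k) ~ P(true state j | decoder bit k set) from a labeled
#' training record: the raw tally raw(j, k) counts windows where bit k
#' was set while the true state was j, and each column is normalized to
#' sum to 1 after adding a Laplace pseudocount. Unknown-label windows are
#' excluded. With pseudocount 0 a column whose bit never fired cannot be
#' normalized and is an error.
#'
#' @param output a [decoder_output()] from the training period.
#' @param labels a [state_sequence()] aligned with `output`.
#' @param pseudocount Laplace smoothing constant epsilon >= 0 (default 1,
#'   guaranteeing strictly positive emissions).
#' @return an object of class `confusion_matrix`: a K x K column-
#'   stochastic matrix with attribute `pseudocount`.
#' @export
estimate_confusion <- function(output, labels, pseudocount = 1) {
  stopifnot(inherits(output, "decoder_output"),
            inherits(labels, "state_sequence"))
  if (nrow(output) != length(labels))
    stop("output and labels must cover the same windows")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  K <- attr(labels, "K")
  if (ncol(output) != K) stop("output has ", ncol(output),
                              " state bits but labels have K = ", K)
  lab <- as.integer(labels)
  known <- !is.na(lab)
  raw <- matrix(0, K, K)
  for (j in seq_len(K)) {
    rows <- known & lab == j
    if (any(rows)) raw[j, ] <- colSums(output[rows, , drop = FALSE])
  }
  colsum <- colSums(raw) + K * pseudocount
  if (any(colsum == 0))
    stop("unnormalizable column (bit never set); use pseudocount > 0")
  Q <- sweep(raw + pseudocount, 2, colsum, "/")
  structure(Q, pseudocount = pseudocount,
            class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix Q(true state | bit set):", nrow(x), "x", ncol(x),
      ", pseudocount =", attr(x, "pseudocount"), "\n")
  cat("  diagonal mass:", round(sum(diag(x)) / ncol(x), 3), "\n")
  invisible(x)
}

#' Emission probability of one decoder output row
#'
#' Treats the K output bits as conditionally independent given the true
#' state and uses Q(j, k) directly as the per-bit factor: the probability
#' of observing output row y in state j is the product of Q(j, k) over
#' the set bits k. An all-zero row has an empty product, i.e. probability
#' 1 for every state — silent windows are uninformative and the
#' trajectory there is carried by the transition prior alone.
#'
#' @param y_row length-K 0/1 vector (one decoder output row).
#' @param state true-state index j.
#' @param Q a [estimate_confusion()] result.
#' @return the emission probability.
#' @export
emission_prob <- function(y_row, state, Q) {
  on <- which(y_row == 1L)
  if (!length(on)) return(1)
  prod(Q[state, on])
}

#' Diffusion-like transition prior
#'
#' Physical model for state-to-state transitions on a track: positions
#' diffuse, so the transition probability decays as a Gaussian in the
#' physical distance between segments, with variance growing linearly in
#' tau, the time elapsed since the decoder last produced an informative
#' (nonzero) output. `transition_model()` packages the distance matrix
#' d(j, j') (by default |j - j'| * segment_length), the diffusivity-like
#' constant kappa (m^2/s, related to the mean speed of movement), and the
#' window length; `transition_matrix()` evaluates the row-stochastic
#' kernel P(j -> j') = exp(-d^2 / (2 kappa tau)) / Z_j at a given tau.
#' Longer tau broadens the kernel, permitting transitions between more
#' distant states with increased probability; as kappa*tau grows without
#' bound the rows approach the uniform distribution.
#'
#' @param K number of states.
#' @param segment_length physical segment length in meters.
#' @param kappa diffusivity-like constant in m^2/s (> 0). Default 0.01,
#'   of order (mean speed)^2 x window length for slow locomotion.
#' @param window_length decoding window length W in seconds.
#' @param distances optional explicit K x K symmetric distance matrix
#'   with zero diagonal, overriding the linear-track default.
#' @return an object of class `transition_model`.
#' @export
transition_model <- function(K, segment_length, kappa = 0.01,
                             window_length, distances = NULL) {
  if (kappa <= 0) stop("'kappa' must be > 0")
  if (is.null(distances)) {
    idx <- seq_len(K)
    distances <- abs(outer(idx, idx, "-")) * segment_length
  } else {
    distances <- as.matrix(distances)
    if (!isSymmetric(distances) || any(diag(distances) != 0))
      stop("'distances' must be symmetric with zero diagonal")
  }
  structure(list(distances = distances, kappa = kappa,
                 window_length = window_length, K = K),
            class = "transition_model")
}

#' @rdname transition_model
#' @param model a `transition_model`.
#' @param tau elapsed time in seconds since the last informative decoder
#'   output; must be at least one window (tau >= W).
#' @return `transition_matrix()` returns a K x K row-stochastic matrix.
#' @export
transition_matrix <- function(model, tau) {
  stopifnot(inherits(model, "transition_model"))
  if (!is.na(model$window_length) && tau < model$window_length)
    stop("tau must be at least one window length")
  kern <- exp(-model$distances^2 / (2 * model$kappa * tau))
  sweep(kern, 1, rowSums(kern), "/")
}

# tau (in windows) for each transition step t-1 -> t: one plus the number
# of consecutive all-zero output rows immediately before row t. Row
# indices 2..T.
.tau_windows <- function(bits) {
  n_win <- nrow(bits)
  if (n_win < 2L) return(integer(0))
  any_set <- rowSums(bits) > 0L
  tau <- integer(n_win - 1L)
  run <- 0L
  for (t in seq_len(n_win - 1L)) {
    run <- if (any_set[t]) 0L else run + 1L
    tau[t] <- 1L + run  # transition t -> t+1
  }
  tau
}

#' Viterbi smoothing of decoder output
#'
#' Converts the internal unit's binary output stream into a single
#' maximum a posteriori state trajectory, treating discretized positions
#' as the hidden states of a discrete-time Markov model with the
#' confusion-matrix emission model of [emission_prob()] and the
#' diffusion-like transition prior of [transition_matrix()]. The initial
#' state distribution is uniform. The tau clock resets to one window at
#' every window with at least one set bit and grows by one window per
#' silent window, so the transition kernel broadens across silent
#' stretches. Computed in log space with backtracking; argmax ties break
#' toward the smaller state index.
#'
#' @param output a [decoder_output()].
#' @param Q a [estimate_confusion()] result (K x K).
#' @param model a [transition_model()].
#' @return a [state_sequence()] of length T.
#' @export
viterbi <- function(output, Q, model) {
  stopifnot(inherits(output, "decoder_output"),
            inherits(model, "transition_model"))
  bits <- unclass(output)
  n_win <- nrow(bits)
  K <- ncol(bits)
  if (K != model$K || K != nrow(Q))
    stop("output, Q and model disagree on K")
  logQ <- log(unclass(Q))
  # emission log-probabilities for all (t, j): sum of logQ[j, k] over set
  # bits k; empty sum = 0 (probability 1)
  log_emis <- bits %*% t(logQ)  # T x K
  # per-step transition kernels, cached by tau expressed in windows
  tau_w <- .tau_windows(bits)
  logP <- list()
  for (u in unique(tau_w))
    logP[[as.character(u)]] <-
      log(transition_matrix(model, u * model$window_length))
  delta <- matrix(-Inf, n_win, K)
  psi <- matrix(0L, n_win, K)
  delta[1, ] <- -log(K) + log_emis[1, ]
  if (n_win > 1L) {
    for (t in 2:n_win) {
      lp <- logP[[as.character(tau_w[t - 1L])]]
      scores <- delta[t - 1L, ] + lp  # K x K: row j' -> col j
      best <- max.col(t(scores), ties.method = "first")
      delta[t, ] <- scores[cbind(best, seq_len(K))] + log_emis[t, ]
      psi[t, ] <- best
    }
  }
  path <- integer(n_win)
  path[n_win] <- which.max(delta[n_win, ])
  if (n_win > 1L)
    for (t in (n_win - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  state_sequence(path, K,
                 segment_length = model$distances[1, min(2, K)],
                 window_length = attr(output, "window_length"))
}
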