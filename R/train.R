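#' In-state / out-of-state spike-count histogram bank
#'
#' The learning substrate: for every (state k, channel i) pair, the
#' frequency histogram of windowed spike counts observed while the system
#' was in state k (`in_state`) and while it was in any other labeled
#' state (`out_state`). Count values run 0..2^b - 1 (third array index is
#' count + 1). `occupancy[k]` is the number of labeled training windows
#' spent in state k; these empirical occupancies are the class priors
#' used for positive predictive value.
#'
#' @param counts a [count_matrix()] of training data.
#' @param labels a [state_sequence()] aligned with `counts` (equal T);
#'   unknown (NA) windows are excluded from accumulation.
#' @return an object of class `histogram_bank` with arrays
#'   `in_state` and `out_state` of dim K x N x 2^b, and `occupancy`.
#' @export
build_histograms <- function(counts, labels) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(labels, "state_sequence"))
  if (nrow(counts) != length(labels))
    stop("counts and labels must cover the same windows (equal T)")
  K <- attr(labels, "K")
  N <- ncol(counts)
  b <- attr(counts, "counter_bits")
  n_vals <- 2L^b
  lab <- as.integer(labels)
  known <- !is.na(lab)
  if (!any(known)) stop("all labels unknown; nothing to accumulate")
  H <- array(0L, dim = c(K, N, n_vals))
  occupancy <- tabulate(lab[known], nbins = K)
  for (i in seq_len(N)) {
    # joint (state, count) tally for channel i over labeled windows
    tab <- table(factor(lab[known], levels = seq_len(K)),
                 factor(counts[known, i], levels = 0:(n_vals - 1L)))
    H[, i, ] <- as.integer(tab)
  }
  # out-of-state histogram: column sums over all states minus own state
  tot <- apply(H, c(2, 3), sum)  # N x n_vals
  Hbar <- array(0L, dim = c(K, N, n_vals))
  for (k in seq_len(K)) Hbar[k, , ] <- tot - H[k, , ]
  structure(list(in_state = H, out_state = Hbar, occupancy = occupancy,
                 K = K, N = N, counter_bits = b),
            class = "histogram_bank")
}

#' @export
print.histogram_bank <- function(x, ...) {
  cat("Histogram bank: K =", x$K, "states x N =", x$N, "channels, counts",
      "0..", 2L^x$counter_bits - 1L, "\n")
  cat("  occupancy: ", paste(x$occupancy, collapse = " "), "\n")
  invisible(x)
}

#' Sensitivity, specificity and PPV of a count threshold
#'
#' Evaluates how well the rule "count >= theta on channel i" discriminates
#' state k from all other states, using the training histograms:
#' sensitivity = P(count >= theta | state k), specificity =
#' P(count < theta | not k), and positive predictive value =
#' in-state mass at or above theta / total mass at or above theta —
#' the latter computed under the empirical training occupancies, which
#' makes PPV (unlike sensitivity and specificity) prevalence-dependent.
#' PPV is NaN when no training window on either side reaches theta.
#'
#' @param bank a [build_histograms()] result.
#' @param state state index k.
#' @param channel channel index i.
#' @param threshold count threshold theta in 1..2^b - 1.
#' @return named numeric vector `(sensitivity, specificity, ppv)`.
#' @export
threshold_metrics <- function(bank, state, channel, threshold) {
  stopifnot(inherits(bank, "histogram_bank"))
  cap <- 2L^bank$counter_bits - 1L
  if (threshold < 1L || threshold > cap)
    stop("threshold must lie in 1..2^b - 1")
  if (bank$occupancy[state] == 0L)
    stop("state ", state, " unobserved in training")
  h <- bank$in_state[state, channel, ]
  hbar <- bank$out_state[state, channel, ]
  n_out <- sum(hbar)
  if (n_out == 0L)
    stop("no out-of-state windows for state ", state)
  hi <- (threshold + 1L):(cap + 1L)  # array index = count + 1
  mass_in <- sum(h[hi])
  mass_out <- sum(hbar[hi])
  c(sensitivity = mass_in / bank$occupancy[state],
    specificity = 1 - mass_out / n_out,
    ppv = mass_in / (mass_in + mass_out))
}

#' Lowest threshold meeting the sensitivity and PPV minima
#'
#' Scans theta = 1, 2, ..., 2^b - 1 in ascending order and returns the
#' first value whose sensitivity is at least `sensitivity_min` and whose
#' positive predictive value is at least `ppv_min`; returns NA when no
#' threshold qualifies. With `ppv_min = 0` the PPV constraint is vacuous
#' (an undefined NaN PPV cannot disqualify a threshold).
#'
#' @param bank a [build_histograms()] result.
#' @param state,channel indices.
#' @param sensitivity_min,ppv_min global minima in \[0, 1\].
#' @return the selected threshold (integer) or NA.
#' @export
select_threshold <- function(bank, state, channel,
                             sensitivity_min, ppv_min) {
  cap <- 2L^bank$counter_bits - 1L
  for (theta in seq_len(cap)) {
    m <- threshold_metrics(bank, state, channel, theta)
    ppv_ok <- if (ppv_min == 0) TRUE else isTRUE(m[["ppv"]] >= ppv_min)
    if (m[["sensitivity"]] >= sensitivity_min && ppv_ok)
      return(as.integer(theta))
  }
  NA_integer_
}

#' Learn a reduced template set from training histograms
#'
#' For every state, runs [select_threshold()] on every channel and keeps
#' the M most informative qualifying (channel, threshold) pairs:
#' qualifying channels are ranked by PPV at the selected threshold,
#' ties broken by sensitivity, then by lower channel index. States where
#' fewer than M channels (possibly none) satisfy the minima end with
#' shorter — possibly empty — templates; empty templates are legal and
#' decode to a constant 0 bit, left to the smoother to resolve.
#'
#' The minima may be overridden per state via `per_state`, a list of
#' `list(state=, sensitivity_min=, ppv_min=)` records, supporting
#' state-by-state tuning.
#'
#' @param bank a [build_histograms()] result.
#' @param sensitivity_min global minimum sensitivity in \[0, 1\].
#' @param ppv_min global minimum positive predictive value in \[0, 1\].
#' @param M maximum (channel, threshold) pairs kept per state.
#' @param per_state optional per-state overrides (see above).
#' @return a [template_set()] with one template per state.
#' @export
learn_templates <- function(bank, sensitivity_min, ppv_min, M = 2L,
                            per_state = NULL) {
  stopifnot(inherits(bank, "histogram_bank"))
  if (sensitivity_min < 0 || sensitivity_min > 1 ||
      ppv_min < 0 || ppv_min > 1)
    stop("minima must lie in [0, 1]")
  overrides <- list()
  for (ov in per_state) overrides[[as.character(ov$state)]] <- ov
  templates <- vector("list", bank$K)
  for (k in seq_len(bank$K)) {
    ov <- overrides[[as.character(k)]]
    smin <- if (!is.null(ov$sensitivity_min)) ov$sensitivity_min
            else sensitivity_min
    pmin_ <- if (!is.null(ov$ppv_min)) ov$ppv_min else ppv_min
    cand <- data.frame(channel = integer(0), theta = integer(0),
                       ppv = numeric(0), sens = numeric(0))
    if (bank$occupancy[k] > 0L) {
      for (i in seq_len(bank$N)) {
        theta <- select_threshold(bank, k, i, smin, pmin_)
        if (!is.na(theta)) {
          m <- threshold_metrics(bank, k, i, theta)
          cand <- rbind(cand, data.frame(
            channel = i, theta = theta,
            ppv = if (is.nan(m[["ppv"]])) 0 else m[["ppv"]],
            sens = m[["sensitivity"]]))
        }
      }
    }
    if (nrow(cand)) {
      ord <- order(-cand$ppv, -cand$sens, cand$channel)
      cand <- cand[ord[seq_len(min(M, nrow(cand)))], ]
    }
    templates[[k]] <- list(state = k, channels = cand$channel,
                           thresholds = cand$theta)
  }
  template_set(templates, K = bank$K, M = M, n_channels = bank$N,
               counter_bits = bank$counter_bits)
}

#' Export a histogram bank in long CSV format
#'
#' Columns `state, channel, count, side (in|out), frequency`.
#'
#' @param bank a [build_histograms()] result.
#' @param path file path.
#' @export
write_histogram_bank <- function(bank, path) {
  stopifnot(inherits(bank, "histogram_bank"))
  n_vals <- 2L^bank$counter_bits
  grid <- expand.grid(state = seq_len(bank$K), channel = seq_len(bank$N),
                      count = 0:(n_vals - 1L))
  df <- rbind(
    cbind(grid, side = "in",
          frequency = as.vector(bank$in_state)),
    cbind(grid, side = "out",
          frequency = as.vector(bank$out_state)))
  utils::write.csv(df[order(df$side, df$state, df$channel, df$count), ],
                   path, row.names = FALSE)
  invisible(path)
}
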