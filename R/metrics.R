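#' Per-state binary classification metrics of decoder output
#'
#' For each state k, tallies TP/FN/FP/TN over windows between the decoder
#' bit Y(., k) and the indicator (label == k), and reports sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP) and positive predictive value
#' TP/(TP+FP). Sensitivity and specificity are properties of the
#' decoding function alone (prevalence-invariant); PPV depends on state
#' prevalence. A metric whose denominator is zero (for example PPV when
#' the bit never fires, or sensitivity for a never-labeled state) is
#' reported as NaN, never silently as zero. Unknown-label windows are
#' excluded.
#'
#' @param output a [decoder_output()].
#' @param labels an aligned [state_sequence()].
#' @return data frame with one row per state: `state, tp, fn, fp, tn,
#'   sensitivity, specificity, ppv`.
#' @export
classification_metrics <- function(output, labels) {
  stopifnot(inherits(output, "decoder_output"),
            inherits(labels, "state_sequence"))
  if (nrow(output) != length(labels))
    stop("output and labels must cover the same windows")
  K <- attr(labels, "K")
  lab <- as.integer(labels)
  known <- !is.na(lab)
  res <- data.frame(state = seq_len(K), tp = 0L, fn = 0L, fp = 0L,
                    tn = 0L, sensitivity = NaN, specificity = NaN,
                    ppv = NaN)
  for (k in seq_len(K)) {
    y <- output[known, k]
    truth <- lab[known] == k
    tp <- sum(y == 1L & truth); fn <- sum(y == 0L & truth)
    fp <- sum(y == 1L & !truth); tn <- sum(y == 0L & !truth)
    res[k, 2:5] <- c(tp, fn, fp, tn)
    res$sensitivity[k] <- if (tp + fn > 0L) tp / (tp + fn) else NaN
    res$specificity[k] <- if (tn + fp > 0L) tn / (tn + fp) else NaN
    res$ppv[k] <- if (tp + fp > 0L) tp / (tp + fp) else NaN
  }
  res
}

#' Pearson correlation between decoded and true trajectories
#'
#' Correlates the two state sequences window by window. When both carry
#' a known segment length the correlation is computed on segment-center
#' positions in meters; this is an affine map of the indices, so r is
#' identical either way. Windows where either sequence is unknown are
#' dropped; a constant sequence yields NaN (undefined), never a silent
#' zero.
#'
#' @param decoded,truth aligned [state_sequence()] objects.
#' @return Pearson r, or NaN when undefined.
#' @export
trajectory_correlation <- function(decoded, truth) {
  stopifnot(inherits(decoded, "state_sequence"),
            inherits(truth, "state_sequence"))
  if (length(decoded) != length(truth))
    stop("sequences must have equal length")
  if (length(truth) < 2L) stop("need at least 2 windows")
  use_pos <- !is.na(attr(decoded, "segment_length")) &&
    !is.na(attr(truth, "segment_length"))
  a <- if (use_pos) state_positions(decoded) else as.numeric(decoded)
  b <- if (use_pos) state_positions(truth) else as.numeric(truth)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(NaN)
  stats::cor(a, b)
}

#' Telemetry compression factor
#'
#' Ratio of the raw digitized input bit rate to the decoder's binary
#' output bit rate: the internal unit turns N channels sampled at f_s
#' samples/s with B bits of precision (N*B*f_s bits/s) into K bits per
#' window of length W (K/W bits/s), for a compression factor of
#' N*B*f_s*W / K.
#'
#' @param n_channels N.
#' @param bits_per_sample B.
#' @param sampling_rate f_s in samples per second.
#' @param K number of decoded states (output bits per window).
#' @param window_length W in seconds.
#' @return the dimensionless compression factor.
#' @export
compression_factor <- function(n_channels, bits_per_sample, sampling_rate,
                               K, window_length) {
  if (any(c(n_channels, bits_per_sample, sampling_rate, K,
            window_length) <= 0))
    stop("all inputs must be positive")
  (n_channels * bits_per_sample * sampling_rate) / (K / window_length)
}

#' Per-frame operation accounting of the internal decoder
#'
#' Tallies the basic operations executed in one computational frame (one
#' pass through all templates after a count vector is latched). Each of
#' the K_T * M threshold comparisons costs one memory access (threshold +
#' pointer fetch), one multiplexer selection of the pointed-to counter,
#' one comparison, `b_logic` binary-logic operations combining the result
#' into its template's conjunction, and one shift-register update holding
#' the comparison result. Fixed per-frame overhead: one clock-counter
#' operation (window timing) and one output shift-register operation
#' (latching the K-bit output word). `b_logic = 1` corresponds to plain
#' single-comparison conjunction logic; more intricate per-comparison
#' logic (e.g. sum-of-products for multimodal fields) raises it.
#'
#' @param n_templates K_T, number of stored templates.
#' @param thresholds_per_template M.
#' @param b_logic binary-logic operations per comparison (default 1).
#' @return named numeric vector of per-frame tallies by category, with a
#'   `total` element.
#' @export
op_count_frame <- function(n_templates, thresholds_per_template,
                           b_logic = 1) {
  if (n_templates < 0 || thresholds_per_template < 0 || b_logic < 0)
    stop("tallies must be >= 0")
  n_cmp <- n_templates * thresholds_per_template
  ops <- c(clock_counter = 1,
           memory_access = n_cmp,
           multiplexer = n_cmp,
           comparison = n_cmp,
           binary_logic = n_cmp * b_logic,
           shift_register_cmp = n_cmp,
           shift_register_out = 1)
  c(ops, total = sum(ops))
}

#' Total operation rate of the internal decoder
#'
#' Multiplies the per-frame total of [op_count_frame()] by the frame rate
#' 1/W: total load = (K_T * M * (4 + b_logic) + 2) / W operations per
#' second. Pure function of its arguments; exactly repeatable.
#'
#' @inheritParams op_count_frame
#' @param frame_rate frames per second (1/W).
#' @return operations per second.
#' @export
op_count <- function(n_templates, thresholds_per_template, frame_rate,
                     b_logic = 1) {
  if (frame_rate <= 0) stop("'frame_rate' must be > 0")
  frame_rate * op_count_frame(n_templates, thresholds_per_template,
                              b_logic)[["total"]]
}

#' Leave-one-out channel-noise robustness evaluation
#'
#' Replays decoding and smoothing on a test record with each channel, in
#' turn, replaced by a rate-matched random-time noise channel
#' ([make_noise_channel()]), quantifying the decoder's robustness to the
#' loss of any single input. Templates and the confusion matrix are NOT
#' relearned — the fitted decoder is applied as-is, mirroring a failure
#' occurring after deployment.
#'
#' @param object a fitted [spike_decoder()].
#' @param spikes test-period [spike_trains()].
#' @param truth true [state_sequence()] for the test period.
#' @param seed base RNG seed; channel i uses seed + i.
#' @return list with `per_channel` (data frame `channel, r`), `mean_r`,
#'   `max_r`, and `baseline_r` (no substitution).
#' @export
leave_one_out_eval <- function(object, spikes, truth, seed = 1L) {
  stopifnot(inherits(object, "spike_decoder"),
            inherits(spikes, "spike_trains"))
  if (spikes$n_channels < 2L) stop("need at least 2 channels")
  baseline <- trajectory_correlation(
    predict(object, spikes = spikes), truth)
  r <- numeric(spikes$n_channels)
  for (i in seq_len(spikes$n_channels)) {
    noisy <- spikes
    noisy$spikes[[i]] <- make_noise_channel(spikes$spikes[[i]],
                                            spikes$duration,
                                            seed = seed + i)
    r[i] <- trajectory_correlation(
      predict(object, spikes = noisy), truth)
  }
  list(per_channel = data.frame(channel = seq_along(r), r = r),
       mean_r = mean(r), max_r = max(r), baseline_r = baseline)
}
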