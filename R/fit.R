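#' Fit a threshold-template spike decoder
#'
#' Trains the complete two-stage decoder from a labeled training record:
#' (1) accumulates in-state / out-of-state spike-count histograms per
#' (state, channel); (2) learns the reduced template set — for each state
#' the lowest count thresholds meeting the global sensitivity and
#' positive-predictive-value minima, keeping the M most informative
#' channels; (3) runs the internal decoder over the training data and
#' estimates the confusion-matrix emission model from its output; and
#' (4) builds the diffusion-like transition prior from the track
#' geometry. The fitted object performs state estimation on new data via
#' [predict.spike_decoder()].
#'
#' @param counts a [count_matrix()] of training windows (or NULL if
#'   `spikes` is given).
#' @param labels a [state_sequence()] aligned with the training windows.
#' @param spikes optionally, raw training [spike_trains()]; counted with
#'   `window_length` / `counter_bits` when `counts` is NULL.
#' @param sensitivity_min global minimum sensitivity (default 0.3).
#' @param ppv_min global minimum positive predictive value (default 0.5).
#' @param M maximum (channel, threshold) pairs per template (default 2).
#' @param kappa transition-prior diffusivity in m^2/s (default 0.01).
#' @param pseudocount Laplace pseudocount for the confusion matrix
#'   (default 1).
#' @param per_state optional per-state overrides of the minima; see
#'   [learn_templates()].
#' @param window_length,counter_bits counting parameters, used when
#'   `spikes` is supplied; otherwise taken from `counts`.
#' @return an object of class `spike_decoder` with components
#'   `templates`, `confusion`, `transition`, `histograms`, `train_metrics`,
#'   and the fit parameters.
#' @seealso [predict.spike_decoder()], [decode()], [viterbi()]
#' @examples
#' track <- track_config(K = 8, traversals = 2)
#' cells <- tile_place_cells(8, track$length)
#' traj <- simulate_trajectory(track, seed = 1)
#' spk <- simulate_spikes(traj, cells, seed = 2)
#' labs <- discretize_trajectory(traj, track$length, track$K, 0.25)
#' fit <- spike_decoder(spikes = spk, labels = labs, window_length = 0.25)
#' coef(fit)
#' @export
spike_decoder <- function(counts = NULL, labels, spikes = NULL,
                          sensitivity_min = 0.3, ppv_min = 0.5, M = 2L,
                          kappa = 0.01, pseudocount = 1,
                          per_state = NULL, window_length = 0.25,
                          counter_bits = 3L) {
  if (is.null(counts)) {
    if (is.null(spikes)) stop("supply either 'counts' or 'spikes'")
    counts <- window_counts(spikes, window_length, counter_bits)
  }
  stopifnot(inherits(counts, "count_matrix"),
            inherits(labels, "state_sequence"))
  if (nrow(counts) != length(labels))
    stop("training counts and labels must cover the same windows")
  bank <- build_histograms(counts, labels)
  templates <- learn_templates(bank, sensitivity_min, ppv_min, M,
                               per_state = per_state)
  y_train <- decode(counts, templates)
  Q <- estimate_confusion(y_train, labels, pseudocount)
  seg <- attr(labels, "segment_length")
  if (is.na(seg)) seg <- 1
  model <- transition_model(K = attr(labels, "K"), segment_length = seg,
                            kappa = kappa,
                            window_length = attr(counts, "window_length"))
  structure(list(
    templates = templates, confusion = Q, transition = model,
    histograms = bank,
    train_metrics = classification_metrics(y_train, labels),
    sensitivity_min = sensitivity_min, ppv_min = ppv_min, M = M,
    kappa = kappa, pseudocount = pseudocount,
    window_length = attr(counts, "window_length"),
    counter_bits = attr(counts, "counter_bits"),
    n_channels = ncol(counts), K = attr(labels, "K"),
    segment_length = seg,
    n_train_windows = nrow(counts)),
    class = "spike_decoder")
}

#' @export
print.spike_decoder <- function(x, ...) {
  sizes <- vapply(x$templates$templates,
                  function(tp) length(tp$channels), integer(1))
  cat("Threshold-template spike decoder\n")
  cat("  channels:", x$n_channels, " states:", x$K,
      " window:", x$window_length, "s  counter:", x$counter_bits,
      "bits\n")
  cat("  minima: sensitivity >=", x$sensitivity_min, ", PPV >=",
      x$ppv_min, "; M =", x$M, "\n")
  cat("  templates:", sum(sizes > 0L), "non-empty of", x$K,
      "(", sum(sizes), "rules total )\n")
  cat("  trained on", x$n_train_windows, "windows; kappa =", x$kappa,
      "m^2/s, pseudocount =", x$pseudocount, "\n")
  invisible(x)
}

#' @export
summary.spike_decoder <- function(object, ...) {
  tm <- object$train_metrics
  out <- list(decoder = object, rules = coef(object),
              train_sensitivity = mean(tm$sensitivity, na.rm = TRUE),
              train_specificity = mean(tm$specificity, na.rm = TRUE),
              train_ppv = mean(tm$ppv, na.rm = TRUE),
              confusion_diag = mean(diag(unclass(object$confusion))))
  class(out) <- "summary.spike_decoder"
  out
}

#' @export
print.summary.spike_decoder <- function(x, ...) {
  print(x$decoder)
  cat("Training-period decoder performance (per-state mean):\n")
  cat(sprintf("  sensitivity %.3f  specificity %.3f  ppv %.3f\n",
              x$train_sensitivity, x$train_specificity, x$train_ppv))
  cat(sprintf("  mean diagonal of confusion matrix: %.3f\n",
              x$confusion_diag))
  cat("Rules:\n")
  print(utils::head(x$rules, 12))
  if (nrow(x$rules) > 12) cat("  ...", nrow(x$rules) - 12, "more rows\n")
  invisible(x)
}

#' Learned decoding rules as a data frame
#'
#' @param object a fitted [spike_decoder()].
#' @param ... unused.
#' @return data frame with columns `state, channel, threshold`, one row
#'   per learned (channel, threshold) pair.
#' @export
coef.spike_decoder <- function(object, ...) {
  tps <- object$templates$templates
  do.call(rbind, c(list(
    data.frame(state = integer(0), channel = integer(0),
               threshold = integer(0))),
    lapply(tps, function(tp) {
      if (!length(tp$channels)) return(NULL)
      data.frame(state = tp$state, channel = tp$channels,
                 threshold = tp$thresholds)
    })))
}

#' Decode new data with a fitted decoder
#'
#' Runs the internal counting-and-comparison unit and (optionally) the
#' external Viterbi smoother on new spike data.
#'
#' @param object a fitted [spike_decoder()].
#' @param counts a [count_matrix()] of new data, or NULL to count
#'   `spikes` with the fit's window length and counter width.
#' @param spikes new [spike_trains()] (used when `counts` is NULL).
#' @param type `"states"` (default) returns the Viterbi-smoothed
#'   [state_sequence()]; `"bits"` returns the raw internal-unit
#'   [decoder_output()].
#' @param ... unused.
#' @return a [state_sequence()] or [decoder_output()].
#' @export
predict.spike_decoder <- function(object, counts = NULL, spikes = NULL,
                                  type = c("states", "bits"), ...) {
  type <- match.arg(type)
  if (is.null(counts)) {
    if (is.null(spikes)) stop("supply either 'counts' or 'spikes'")
    counts <- window_counts(spikes, object$window_length,
                            object$counter_bits)
  }
  y <- decode(counts, object$templates)
  if (type == "bits") return(y)
  viterbi(y, object$confusion, object$transition)
}

#' Plot the learned rule array
#'
#' Displays the template set as a channel x state image in the style of
#' a decoder "program tape": pixel (i, k) is shaded by the threshold the
#' template of state k places on channel i (white where no rule).
#'
#' @param x a fitted [spike_decoder()].
#' @param ... passed to [graphics::image()].
#' @export
plot.spike_decoder <- function(x, ...) {
  cap <- 2L^x$counter_bits - 1L
  arr <- matrix(NA_real_, x$n_channels, x$K)
  for (tp in x$templates$templates)
    if (length(tp$channels)) arr[tp$channels, tp$state] <- tp$thresholds
  graphics::image(x = seq_len(x$K), y = seq_len(x$n_channels), z = t(arr),
                  zlim = c(0, cap),
                  col = grDevices::gray(seq(0.85, 0, length.out = cap)),
                  xlab = "state", ylab = "channel",
                  main = "Learned decoding rules (threshold per pixel)",
                  ...)
  invisible(x)
}
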