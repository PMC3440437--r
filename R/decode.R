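#' Evaluate one template against one spike-count vector
#'
#' Returns 1 iff the count on every channel referenced by the template
#' attains or exceeds its threshold (logical AND of the component-wise
#' comparisons, the conjunction-of-at-least operation). An empty template
#' returns 0.
#'
#' @param count_vector length-N integer vector of windowed spike counts.
#' @param template one element of a [template_set()]'s `templates` list.
#' @return 0 or 1.
#' @export
apply_template <- function(count_vector, template) {
  op <- .rule_ops[[if (is.null(template$op)) "conjunction_at_least"
                   else template$op]]
  if (is.null(op)) stop("unregistered operation '", template$op, "'")
  if (length(template$channels) &&
      max(template$channels) > length(count_vector))
    stop("template references channel beyond the count vector")
  op(count_vector, template$channels, template$thresholds)
}

#' Internal-unit decoder: counts to binary state scores
#'
#' Evaluates the decoder output bit Y(t, k) for every window t and state
#' k: the OR over all of state k's templates of the conjunction of their
#' threshold comparisons. Causal by construction — row t depends only on
#' window t. States owning no template (or only empty ones) emit a
#' constant 0.
#'
#' @param counts a [count_matrix()].
#' @param templates a [template_set()]; channel indices must not exceed
#'   the number of count columns.
#' @return a [decoder_output()] of dim T x K.
#' @export
decode <- function(counts, templates) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(templates, "template_set"))
  n_win <- nrow(counts)
  K <- templates$K
  bits <- matrix(0L, nrow = n_win, ncol = K)
  cmat <- unclass(counts)
  for (tp in templates$templates) {
    if (!length(tp$channels)) next
    if (max(tp$channels) > ncol(cmat))
      stop("template channel index exceeds channel count")
    if (!identical(tp$op, "conjunction_at_least") && !is.null(tp$op)) {
      # fall back to the registry row by row for non-default operations
      hit <- vapply(seq_len(n_win), function(t)
        apply_template(cmat[t, ], tp), integer(1))
    } else {
      cmp <- cmat[, tp$channels, drop = FALSE] >=
        matrix(tp$thresholds, n_win, length(tp$channels), byrow = TRUE)
      hit <- as.integer(rowSums(cmp) == length(tp$channels))
    }
    bits[, tp$state] <- as.integer(bits[, tp$state] | hit)
  }
  decoder_output(bits, attr(counts, "window_length"))
}

#' Brute-force full-template decoder (reference oracle)
#'
#' Reference implementation of the unreduced decoder: for each state k,
#' Y(t, k) = 1 iff count(t, i) >= full_thresholds(k, i) for every one of
#' the N channels. No reduced storage, no pointer indirection; used to
#' check that the reduced decoder is exact when its templates carry all
#' channels.
#'
#' @param counts a [count_matrix()].
#' @param full_thresholds K x N integer matrix of thresholds.
#' @return a [decoder_output()] of dim T x K.
#' @export
decode_full_oracle <- function(counts, full_thresholds) {
  stopifnot(inherits(counts, "count_matrix"))
  full_thresholds <- as.matrix(full_thresholds)
  if (ncol(full_thresholds) != ncol(counts))
    stop("threshold matrix must have one column per channel")
  K <- nrow(full_thresholds)
  n_win <- nrow(counts)
  bits <- matrix(0L, n_win, K)
  cmat <- unclass(counts)
  for (k in seq_len(K)) {
    cmp <- cmat >= matrix(full_thresholds[k, ], n_win, ncol(cmat),
                          byrow = TRUE)
    bits[, k] <- as.integer(rowSums(cmp) == ncol(cmat))
  }
  decoder_output(bits, attr(counts, "window_length"))
}

#' Two-layer integrate-and-fire network emulation of the decoder
#'
#' Emulates the decoder as a two-layer network of digitized
#' integrate-and-fire neurons: first-layer units relay the windowed
#' counts of the N input channels; each second-layer unit is wired to the
#' channels of one template with synaptic weight 1/threshold, integrates
#' over the window, resets at every window boundary, and fires when its
#' accumulated value reaches the number of its synapses. Each synapse's
#' contribution is capped at 1 (count/threshold clipped at unity), which
#' makes the network's firing rule exactly equivalent to the conjunction
#' of threshold comparisons: the capped sum reaches n iff all n
#' comparisons individually succeed. Units with no synapses never fire.
#'
#' @param counts a [count_matrix()].
#' @param templates a [template_set()] using the conjunction operation
#'   only.
#' @return a [decoder_output()] bit-identical to [decode()].
#' @export
emulate_if_network <- function(counts, templates) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(templates, "template_set"))
  n_win <- nrow(counts)
  bits <- matrix(0L, n_win, templates$K)
  cmat <- unclass(counts)
  for (tp in templates$templates) {
    if (!is.null(tp$op) && !identical(tp$op, "conjunction_at_least"))
      stop("integrate-and-fire emulation supports conjunction logic only")
    n_syn <- length(tp$channels)
    if (!n_syn) next
    w <- 1 / tp$thresholds
    contrib <- cmat[, tp$channels, drop = FALSE] *
      matrix(w, n_win, n_syn, byrow = TRUE)
    contrib <- pmin(contrib, 1)
    fire <- as.integer(rowSums(contrib) >= n_syn)
    bits[, tp$state] <- as.integer(bits[, tp$state] | fire)
  }
  decoder_output(bits, attr(counts, "window_length"))
}
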