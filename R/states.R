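#' State sequence over decoding windows
#'
#' A length-T vector of state indices in 1..K, one per time window. `NA`
#' is the "unknown" sentinel for windows without a label (for example
#' windows with no position sample); such windows are excluded from
#' histogram accumulation during training.
#'
#' @param states integer vector of state indices (NA allowed).
#' @param K number of states.
#' @param segment_length physical length of one state segment in meters
#'   (used for distances in the transition prior and for position-based
#'   correlations); may be NA when unknown.
#' @param window_length window length in seconds (optional metadata).
#' @return an object of class `state_sequence`.
#' @export
state_sequence <- function(states, K, segment_length = NA_real_,
                           window_length = NA_real_) {
  states <- as.integer(states)
  if (K < 1) stop("'K' must be >= 1")
  ok <- is.na(states) | (states >= 1L & states <= K)
  if (!all(ok))
    stop("state index out of 1..K at position ", which(!ok)[1])
  structure(states, K = as.integer(K), segment_length = segment_length,
            window_length = window_length, class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("State sequence: T =", length(x), ", K =", attr(x, "K"),
      ",", sum(is.na(x)), "unknown windows\n")
  invisible(x)
}

#' Discretize a continuous 1-D trajectory into track states
#'
#' Averages position samples within each decoding window and bins the mean
#' into K equal segments: state = 1 + floor(K * pos / L), clamped to K at
#' the right edge so pos == L maps to state K. Windows containing no
#' position sample get the unknown sentinel (NA).
#'
#' @param positions data frame with columns `time` (s) and `position` (m),
#'   or a list of (time, position) pairs coercible to one.
#' @param track_length track length L in meters.
#' @param K number of states.
#' @param window_length decoding window length in seconds.
#' @param n_windows number of windows; defaults to floor(max(time) / W).
#' @return a [state_sequence()] with segment_length = L / K.
#' @export
discretize_trajectory <- function(positions, track_length, K,
                                  window_length, n_windows = NULL) {
  if (K < 1) stop("'K' must be >= 1")
  positions <- as.data.frame(positions)
  if (!all(c("time", "position") %in% names(positions)))
    stop("'positions' needs columns 'time' and 'position'")
  p <- positions$position
  if (any(p < 0 | p > track_length))
    stop("positions must lie within [0, track_length]")
  if (is.null(n_windows))
    n_windows <- floor(max(positions$time) / window_length)
  w <- floor(positions$time / window_length) + 1
  keep <- w >= 1 & w <= n_windows
  mean_pos <- rep(NA_real_, n_windows)
  if (any(keep)) {
    agg <- tapply(p[keep], w[keep], mean)
    mean_pos[as.integer(names(agg))] <- agg
  }
  st <- ifelse(is.na(mean_pos), NA_integer_,
               pmin(1L + floor(K * mean_pos / track_length), K))
  state_sequence(st, K, segment_length = track_length / K,
                 window_length = window_length)
}

#' Read / write state sequences as CSV
#'
#' Columns `window,state`; blank state field encodes the unknown sentinel.
#' Metadata (`K`, `segment_length`, `window_length`) in leading comment
#' lines.
#'
#' @param path file path.
#' @return a [state_sequence()].
#' @export
read_state_sequence <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  getm <- function(key, required = TRUE) {
    m <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (!length(m)) {
      if (required) stop("missing metadata '", key, "' in ", path)
      return(NA_real_)
    }
    as.numeric(sub(".*=", "", m[1]))
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  st <- df$state[order(df$window)]
  state_sequence(st, K = getm("K"),
                 segment_length = getm("segment_length", FALSE),
                 window_length = getm("window_length", FALSE))
}

#' @rdname read_state_sequence
#' @param x a [state_sequence()] object.
#' @export
write_state_sequence <- function(x, path) {
  stopifnot(inherits(x, "state_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#K=", attr(x, "K")),
    paste0("#segment_length=", attr(x, "segment_length")),
    paste0("#window_length=", attr(x, "window_length"))), con)
  df <- data.frame(window = seq_along(x), state = as.integer(x))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Segment-center positions of a state sequence
#'
#' Maps state index k to the physical center of its track segment,
#' (k - 1/2) * segment_length. Used when correlating decoded and true
#' trajectories in meters rather than index units (an affine map, so the
#' Pearson correlation is unchanged).
#'
#' @param x a [state_sequence()].
#' @return numeric vector of positions (meters), NA where unknown.
#' @export
state_positions <- function(x) {
  stopifnot(inherits(x, "state_sequence"))
  seg <- attr(x, "segment_length")
  if (is.na(seg)) seg <- 1
  (as.integer(x) - 0.5) * seg
}
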