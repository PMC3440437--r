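#' Multichannel spike train container
#'
#' Holds per-channel spike event times for a recording of known duration.
#' Channels are indexed 1..N; times are in seconds from the start of the
#' recording and must be non-decreasing within a channel.
#'
#' @param spikes list of numeric vectors, one per channel, event times in
#'   seconds. A channel with no events is an empty numeric vector.
#' @param duration recording duration in seconds.
#' @return an object of class `spike_trains` with elements `spikes`,
#'   `duration` and `n_channels`.
#' @export
spike_trains <- function(spikes, duration) {
  if (!is.list(spikes) || length(spikes) < 1L)
    stop("'spikes' must be a non-empty list of per-channel time vectors")
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0)
    stop("'duration' must be a single non-negative number")
  spikes <- lapply(spikes, function(x) as.numeric(x))
  for (i in seq_along(spikes)) {
    x <- spikes[[i]]
    if (any(!is.finite(x)))
      stop("non-finite spike time on channel ", i)
    if (is.unsorted(x))
      stop("spike times on channel ", i, " are not non-decreasing")
    if (length(x) && (x[1] < 0 || x[length(x)] > duration))
      stop("spike time outside [0, duration] on channel ", i)
  }
  structure(list(spikes = spikes, duration = duration,
                 n_channels = length(spikes)),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  n <- vapply(x$spikes, length, integer(1))
  cat("Spike trains:", x$n_channels, "channels,",
      sum(n), "events over", format(x$duration), "s\n")
  cat("  events/channel: min", min(n), "median", stats::median(n),
      "max", max(n), "\n")
  invisible(x)
}

#' Read spike trains from a delimited text file
#'
#' Expects a CSV with header columns `channel,time_s`; channel indices are
#' 1-based. Channels with indices up to `n_channels` (default: the maximum
#' index present) are created even if silent.
#'
#' @param path file path.
#' @param duration recording duration in seconds; defaults to the latest
#'   event time in the file.
#' @param n_channels number of channels; defaults to the maximum index seen.
#' @return a [spike_trains()] object.
#' @export
read_spike_trains <- function(path, duration = NULL, n_channels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "time_s") %in% names(df)))
    stop("expected columns 'channel' and 'time_s' in ", path)
  ch <- df$channel
  bad <- which(!is.finite(ch) | ch != floor(ch) | ch < 1)
  if (length(bad))
    stop("invalid channel index at data line ", bad[1], " of ", path)
  if (is.null(n_channels)) n_channels <- if (nrow(df)) max(ch) else 1L
  if (any(ch > n_channels))
    stop("channel index exceeds n_channels in ", path)
  if (is.null(duration)) duration <- if (nrow(df)) max(df$time_s) else 0
  spikes <- lapply(seq_len(n_channels),
                   function(i) sort(df$time_s[ch == i]))
  spike_trains(spikes, duration)
}

#' Write spike trains to CSV (columns channel,time_s)
#' @param x a [spike_trains()] object.
#' @param path output file path.
#' @export
write_spike_trains <- function(x, path) {
  stopifnot(inherits(x, "spike_trains"))
  n <- vapply(x$spikes, length, integer(1))
  df <- data.frame(channel = rep(seq_along(x$spikes), n),
                   time_s = unlist(x$spikes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
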