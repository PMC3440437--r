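#' Construct a windowed spike-count matrix
#'
#' @param counts integer matrix, one row per time window, one column per
#'   channel.
#' @param window_length window length W in seconds.
#' @param counter_bits counter width b; every count must lie in
#'   0..2^b - 1.
#' @param start_time time of the left edge of the first window (seconds).
#' @return an object of class `count_matrix`: the integer matrix with
#'   attributes `window_length`, `counter_bits`, `start_time`.
#' @export
count_matrix <- function(counts, window_length, counter_bits,
                         start_time = 0) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (window_length <= 0) stop("'window_length' must be > 0")
  if (counter_bits < 1) stop("'counter_bits' must be >= 1")
  cap <- 2L^counter_bits - 1L
  if (any(is.na(counts))) stop("counts must not contain NA")
  if (any(counts < 0L) || any(counts > cap))
    stop("counts must lie in 0..2^b - 1 (b = ", counter_bits, ")")
  structure(counts, window_length = window_length,
            counter_bits = counter_bits, start_time = start_time,
            class = c("count_matrix", "matrix", "array"))
}

#' Windowed, saturating spike counting
#'
#' Counts spikes per channel in consecutive half-open windows
#' \[tW, (t+1)W), t = 0, 1, ..., clamping each count at the b-bit counter
#' ceiling 2^b - 1 (saturation, never wraparound). A spike exactly on a
#' window boundary belongs to the later window, matching synchronous
#' counter-reset semantics. Windows are formed over \[0, duration); the
#' number of rows is floor(duration / W).
#'
#' @param spikes a [spike_trains()] object.
#' @param window_length window length W in seconds.
#' @param counter_bits counter width b (default 3, giving counts 0..7).
#' @return a [count_matrix()] with `floor(duration / W)` rows.
#' @export
window_counts <- function(spikes, window_length, counter_bits = 3L) {
  stopifnot(inherits(spikes, "spike_trains"))
  if (window_length <= 0) stop("'window_length' must be > 0")
  if (counter_bits < 1) stop("'counter_bits' must be >= 1")
  n_win <- floor(spikes$duration / window_length)
  if (n_win < 1L) stop("no data: duration shorter than one window")
  cap <- 2L^counter_bits - 1L
  out <- matrix(0L, nrow = n_win, ncol = spikes$n_channels)
  for (i in seq_len(spikes$n_channels)) {
    t <- spikes$spikes[[i]]
    if (!length(t)) next
    w <- floor(t / window_length) + 1  # half-open [tW,(t+1)W)
    w <- w[w >= 1 & w <= n_win]
    if (length(w)) out[, i] <- pmin(tabulate(w, nbins = n_win), cap)
  }
  count_matrix(out, window_length, counter_bits)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x), "windows x", ncol(x), "channels, W =",
      attr(x, "window_length"), "s, b =", attr(x, "counter_bits"),
      "bits (counts 0..", 2L^attr(x, "counter_bits") - 1L, ")\n", sep = " ")
  invisible(x)
}

#' Read / write count matrices as CSV with header
#'
#' The CSV carries one column per channel (`ch1`, `ch2`, ...) and metadata
#' in comment lines `#window_length`, `#counter_bits`, `#start_time` before
#' the header. Values violating the b-bit range are rejected.
#'
#' @param path file path.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  getm <- function(key) {
    m <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (!length(m)) stop("missing metadata '", key, "' in ", path)
    as.numeric(sub(".*=", "", m[1]))
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  counts <- as.matrix(df)
  count_matrix(counts, getm("window_length"), getm("counter_bits"),
               getm("start_time"))
}

#' @rdname read_count_matrix
#' @param x a [count_matrix()] object.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#window_length=", attr(x, "window_length")),
    paste0("#counter_bits=", attr(x, "counter_bits")),
    paste0("#start_time=", attr(x, "start_time"))), con)
  df <- as.data.frame(unclass(x))
  names(df) <- paste0("ch", seq_len(ncol(x)))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
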