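#' Decoder template set ("program tape")
#'
#' Each template belongs to one state and carries up to M
#' (channel, threshold) pairs plus an operation selector. The default —
#' and currently only registered — operation is `conjunction_at_least`:
#' the template fires when every referenced channel's windowed spike count
#' attains or exceeds its threshold. A state may own several templates
#' (combined by OR at decode time) or none (its output bit is constantly
#' 0 and is resolved by the smoother through the transition prior).
#'
#' @param templates list of template records, each a list with elements
#'   `state` (index in 1..K), `channels` (integer vector, possibly empty),
#'   `thresholds` (same length), and optional `op` (default
#'   `"conjunction_at_least"`).
#' @param K number of states.
#' @param M maximum number of (channel, threshold) pairs per template.
#' @param n_channels number of input channels N (for index validation);
#'   NA to skip the upper-bound check.
#' @param counter_bits counter width b; thresholds must lie in 1..2^b - 1.
#' @return an object of class `template_set`.
#' @export
template_set <- function(templates, K, M, n_channels = NA_integer_,
                         counter_bits = 3L) {
  cap <- 2L^counter_bits - 1L
  templates <- lapply(templates, function(tp) {
    tp$state <- as.integer(tp$state)
    tp$channels <- as.integer(tp$channels)
    tp$thresholds <- as.integer(tp$thresholds)
    if (is.null(tp$op)) tp$op <- "conjunction_at_least"
    if (!tp$op %in% names(.rule_ops))
      stop("unregistered operation '", tp$op, "'")
    if (tp$state < 1L || tp$state > K)
      stop("template state index out of 1..K")
    if (length(tp$channels) != length(tp$thresholds))
      stop("channels and thresholds differ in length")
    if (length(tp$channels) > M)
      stop("template carries more than M = ", M, " entries")
    if (length(tp$channels)) {
      if (any(tp$channels < 1L) ||
          (!is.na(n_channels) && any(tp$channels > n_channels)))
        stop("template channel index out of range")
      if (any(tp$thresholds < 1L) || any(tp$thresholds > cap))
        stop("template threshold outside 1..2^b - 1")
    }
    tp
  })
  structure(list(templates = templates, K = as.integer(K),
                 M = as.integer(M), n_channels = n_channels,
                 counter_bits = as.integer(counter_bits)),
            class = "template_set")
}

# operation registry: each op maps (count_vector, channels, thresholds)
# to a single bit. The registry is the extension hook for alternative
# combinational logic (level bands, silence rules); only conjunction is
# registered here.
.rule_ops <- list(
  conjunction_at_least = function(counts, channels, thresholds) {
    if (!length(channels)) return(0L)
    as.integer(all(counts[channels] >= thresholds))
  }
)

#' @export
print.template_set <- function(x, ...) {
  sizes <- vapply(x$templates, function(tp) length(tp$channels), integer(1))
  cat("Template set: K =", x$K, "states,", length(x$templates),
      "templates (<=", x$M, "entries each),", sum(sizes == 0L),
      "empty\n")
  invisible(x)
}

#' Serialize a template set to / from JSON
#'
#' The JSON mirrors the rule-table semantics: an object with fields `K`,
#' `M`, `counter_bits`, `n_channels` and an array `templates` of
#' `{state, entries: [[channel, threshold], ...], op}` records. Channel
#' and state indices are 1-based in the file.
#'
#' @param path file path.
#' @return a [template_set()].
#' @export
read_template_set <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("K", "M", "templates"))
    if (is.null(obj[[f]])) stop("missing field '", f, "' in ", path)
  templates <- lapply(obj$templates, function(tp) {
    ent <- tp$entries
    list(state = tp$state,
         channels = vapply(ent, function(e) as.integer(e[[1]]), integer(1)),
         thresholds = vapply(ent, function(e) as.integer(e[[2]]), integer(1)),
         op = if (is.null(tp$op)) "conjunction_at_least" else tp$op)
  })
  template_set(templates, K = obj$K, M = obj$M,
               n_channels = if (is.null(obj$n_channels)) NA_integer_
                            else obj$n_channels,
               counter_bits = if (is.null(obj$counter_bits)) 3L
                              else obj$counter_bits)
}

#' @rdname read_template_set
#' @param x a [template_set()] object.
#' @export
write_template_set <- function(x, path) {
  stopifnot(inherits(x, "template_set"))
  obj <- list(
    K = x$K, M = x$M, counter_bits = x$counter_bits,
    n_channels = x$n_channels,
    templates = lapply(x$templates, function(tp) {
      list(state = tp$state,
           entries = unname(mapply(function(c, t) c(c, t), tp$channels,
                                   tp$thresholds, SIMPLIFY = FALSE)),
           op = tp$op)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Rule-table CSV in the state-indexed column layout
#'
#' Writes (reads) a compact table with one column per state and rows
#' c1, theta1, c2, theta2, ...: the channel indices and thresholds of
#' each state's template, blanks where a state has fewer entries. This is
#' the layout used to print decoding instructions for a 32-state decoder
#' with two rules per state. Only single-template-per-state sets with the
#' conjunction operation can be represented.
#'
#' @param x a [template_set()] with at most one template per state.
#' @param path file path.
#' @export
write_rule_table_csv <- function(x, path) {
  stopifnot(inherits(x, "template_set"))
  states <- vapply(x$templates, function(tp) tp$state, integer(1))
  if (anyDuplicated(states))
    stop("rule-table CSV requires at most one template per state")
  tab <- matrix(NA_integer_, nrow = 2L * x$M, ncol = x$K)
  for (tp in x$templates) {
    n <- length(tp$channels)
    if (n) {
      tab[2L * seq_len(n) - 1L, tp$state] <- tp$channels
      tab[2L * seq_len(n), tp$state] <- tp$thresholds
    }
  }
  df <- as.data.frame(tab)
  names(df) <- paste0("state", seq_len(x$K))
  rownames(df) <- as.vector(rbind(paste0("c", seq_len(x$M)),
                                  paste0("theta", seq_len(x$M))))
  utils::write.csv(df, path, row.names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_rule_table_csv
#' @param n_channels,counter_bits validation metadata, as in
#'   [template_set()].
#' @return `read_rule_table_csv()` returns a [template_set()].
#' @export
read_rule_table_csv <- function(path, n_channels = NA_integer_,
                                counter_bits = 3L) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  K <- ncol(df)
  M <- nrow(df) / 2L
  if (M != floor(M))
    stop("rule table must have an even number of rows (c_i, theta_i pairs)")
  templates <- list()
  for (k in seq_len(K)) {
    col <- df[[k]]
    ch <- col[2L * seq_len(M) - 1L]
    th <- col[2L * seq_len(M)]
    if (any(xor(is.na(ch), is.na(th))))
      stop("state ", k, ": channel without threshold (or vice versa) in ",
           path)
    keep <- !is.na(ch)
    templates[[length(templates) + 1L]] <-
      list(state = k, channels = as.integer(ch[keep]),
           thresholds = as.integer(th[keep]))
  }
  template_set(templates, K = K, M = M, n_channels = n_channels,
               counter_bits = counter_bits)
}

#' Decoder output bit matrix
#'
#' The internal unit's compressed output stream: a T x K binary matrix,
#' one row per window, one column (bit) per state.
#'
#' @param bits 0/1 matrix.
#' @param window_length window length in seconds.
#' @return an object of class `decoder_output`.
#' @export
decoder_output <- function(bits, window_length) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (any(is.na(bits)) || any(!bits %in% c(0L, 1L)))
    stop("decoder output entries must be 0 or 1")
  structure(bits, window_length = window_length,
            class = c("decoder_output", "matrix", "array"))
}

#' @export
print.decoder_output <- function(x, ...) {
  cat("Decoder output:", nrow(x), "windows x", ncol(x), "state bits,",
      sum(x), "bits set (", round(mean(rowSums(x) == 0) * 100, 1),
      "% silent windows)\n")
  invisible(x)
}

#' Read / write decoder output as CSV of 0/1
#' @param path file path.
#' @return a `decoder_output` object.
#' @export
read_decoder_output <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  w <- NA_real_
  if (length(meta_idx)) {
    m <- grep("^#window_length=", lines[meta_idx], value = TRUE)
    if (length(m)) w <- as.numeric(sub(".*=", "", m[1]))
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  decoder_output(as.matrix(df), w)
}

#' @rdname read_decoder_output
#' @param x a `decoder_output` object.
#' @export
write_decoder_output <- function(x, path) {
  stopifnot(inherits(x, "decoder_output"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#window_length=", attr(x, "window_length")), con)
  df <- as.data.frame(unclass(x))
  names(df) <- paste0("state", seq_len(ncol(x)))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
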