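#' Default synthetic decoding scenario
#'
#' The package's reference study condition: 32 place cells tiling 32
#' states on a 3.5 m linear track, 250 ms counting windows with 3-bit
#' saturating counters, up to M = 2 rules per state learned under
#' sensitivity >= 0.3 and PPV >= 0.5, six end-to-end traversals (three
#' per direction) at 0.2 m/s mean speed, training on the first traversal
#' pair (one in each direction) and testing on the rest. All fields can
#' be overridden.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param ... named overrides of any scenario field.
#' @return a named list (class `decoder_scenario`).
#' @export
default_scenario <- function(seed = 1L, ...) {
  sc <- list(
    seed = as.integer(seed),
    n_cells = 32L, track_length = 3.5, K = 32L,
    mean_speed = 0.2, traversals = 6L, speed_jitter = 0.1,
    field_width = 0.15, peak_rate = 20, baseline_rate = 0.5,
    window_length = 0.25, counter_bits = 3L,
    sensitivity_min = 0.3, ppv_min = 0.5, M = 2L,
    kappa = 0.01, pseudocount = 1,
    train_traversals = 2L,
    trajectory_dt = 0.01)
  ov <- list(...)
  for (nm in names(ov)) sc[[nm]] <- ov[[nm]]
  structure(sc, class = c("decoder_scenario", "list"))
}

#' Read / write a scenario configuration as YAML
#' @param path file path.
#' @return `read_scenario()` returns a `decoder_scenario` list.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  do.call(default_scenario, c(list(seed = sc$seed),
                              sc[setdiff(names(sc), "seed")]))
}

#' @rdname read_scenario
#' @param scenario a `decoder_scenario` list.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' Run the full synthetic decoding pipeline
#'
#' Orchestrates simulate -> count -> train -> decode -> smooth ->
#' evaluate from one scenario configuration, with a chronological
#' train/test split: templates and the confusion matrix are learned
#' strictly from the first `train_traversals` traversals, and all
#' reported performance comes from the remaining (held-out) windows.
#' Internal-unit stages (counting, template comparison) and
#' external-unit stages (learning, smoothing, evaluation) are logged
#' separately. Deterministic given the scenario seed.
#'
#' @param scenario a [default_scenario()] list (or overrides via `...`
#'   passed to it when `scenario` is NULL).
#' @param out_dir optional directory; when given, every intermediate
#'   artifact (spikes, trajectory, counts, labels, rules, decoder
#'   output, smoothed path, confusion matrix, metrics report, scenario
#'   YAML) is persisted there.
#' @param quiet suppress progress messages.
#' @param ... overrides forwarded to [default_scenario()].
#' @return list with elements `fit` (the [spike_decoder()]), `r`
#'   (held-out Pearson correlation), `test_metrics` (per-state
#'   classification metrics on held-out bits), `decoded`, `truth`,
#'   `spikes_test`, `scenario`, and the window ranges of the split.
#' @export
run_pipeline <- function(scenario = NULL, out_dir = NULL, quiet = FALSE,
                         ...) {
  if (is.null(scenario)) scenario <- default_scenario(...)
  sc <- scenario
  say <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] ", stage), ...)

  say("simulate", "trajectory: ", sc$traversals, " traversals of ",
      sc$track_length, " m at ", sc$mean_speed, " m/s")
  track <- track_config(sc$track_length, sc$K, sc$mean_speed,
                        sc$traversals, sc$speed_jitter)
  traj <- simulate_trajectory(track, seed = sc$seed,
                              dt = sc$trajectory_dt)
  cells <- tile_place_cells(sc$n_cells, sc$track_length,
                            width = sc$field_width,
                            peak_rate = sc$peak_rate,
                            baseline_rate = sc$baseline_rate)
  spikes <- simulate_spikes(traj, cells, seed = sc$seed + 1L)

  say("internal/count", "windowing ", sum(lengths(spikes$spikes)),
      " spikes into W = ", sc$window_length, " s, b = ",
      sc$counter_bits, " bits")
  counts <- window_counts(spikes, sc$window_length, sc$counter_bits)
  labels <- discretize_trajectory(traj, sc$track_length, sc$K,
                                  sc$window_length,
                                  n_windows = nrow(counts))

  knots <- attr(traj, "knots")
  split_time <- knots[sc$train_traversals + 1L]
  n_train <- floor(split_time / sc$window_length)
  if (n_train < 1L || n_train >= nrow(counts))
    stop("train/test split leaves an empty side")
  idx_train <- seq_len(n_train)
  idx_test <- (n_train + 1L):nrow(counts)

  say("external/train", "learning templates from ", n_train,
      " training windows (traversals 1..", sc$train_traversals, ")")
  counts_train <- count_matrix(counts[idx_train, , drop = FALSE],
                               sc$window_length, sc$counter_bits)
  labels_train <- state_sequence(labels[idx_train], sc$K,
                                 attr(labels, "segment_length"),
                                 sc$window_length)
  fit <- spike_decoder(counts_train, labels_train,
                       sensitivity_min = sc$sensitivity_min,
                       ppv_min = sc$ppv_min, M = sc$M,
                       kappa = sc$kappa, pseudocount = sc$pseudocount)

  say("internal/decode", "decoding ", length(idx_test),
      " held-out windows")
  counts_test <- count_matrix(counts[idx_test, , drop = FALSE],
                              sc$window_length, sc$counter_bits)
  y_test <- predict(fit, counts_test, type = "bits")

  say("external/smooth", "Viterbi smoothing (kappa = ", sc$kappa,
      " m^2/s)")
  decoded <- viterbi(y_test, fit$confusion, fit$transition)

  say("external/evaluate", "scoring against held-out trajectory")
  truth <- state_sequence(labels[idx_test], sc$K,
                          attr(labels, "segment_length"),
                          sc$window_length)
  r <- trajectory_correlation(decoded, truth)
  test_metrics <- classification_metrics(y_test, truth)
  say("external/evaluate", sprintf("held-out Pearson r = %.3f", r))

  spikes_test <- .crop_spikes(spikes, n_train * sc$window_length)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(out_dir, f)
    write_scenario(sc, fp("scenario.yaml"))
    write_spike_trains(spikes, fp("spikes.csv"))
    utils::write.csv(traj, fp("trajectory.csv"), row.names = FALSE)
    write_count_matrix(counts, fp("counts.csv"))
    write_state_sequence(labels, fp("labels.csv"))
    write_template_set(fit$templates, fp("rules.json"))
    write_rule_table_csv(fit$templates, fp("rule_table.csv"))
    write_decoder_output(y_test, fp("y_test.csv"))
    write_state_sequence(decoded, fp("decoded_path.csv"))
    utils::write.csv(as.data.frame(unclass(fit$confusion)),
                     fp("confusion.csv"), row.names = FALSE)
    utils::write.csv(test_metrics, fp("test_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(r = r, n_train_windows = n_train,
           n_test_windows = length(idx_test),
           mean_sensitivity = mean(test_metrics$sensitivity,
                                   na.rm = TRUE),
           mean_specificity = mean(test_metrics$specificity,
                                   na.rm = TRUE)),
      fp("report.json"), auto_unbox = TRUE, digits = NA)
  }

  list(fit = fit, r = r, test_metrics = test_metrics,
       decoded = decoded, truth = truth, y_test = y_test,
       spikes_test = spikes_test, scenario = sc,
       idx_train = idx_train, idx_test = idx_test)
}

# restrict a spike_trains object to events at or after t0, re-zeroing time
.crop_spikes <- function(spikes, t0) {
  cropped <- lapply(spikes$spikes, function(x) x[x >= t0] - t0)
  spike_trains(cropped, spikes$duration - t0)
}
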