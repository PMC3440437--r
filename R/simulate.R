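#' Place-cell tuning parameters
#'
#' One simulated unit with a unimodal, approximately Gaussian receptive
#' field on a 1-D track: firing rate
#' `baseline + (peak - baseline) * exp(-(pos - center)^2 / (2 width^2))`.
#'
#' @param center field center in meters.
#' @param width tuning-curve standard deviation in meters (> 0).
#' @param peak_rate in-field peak firing rate in Hz.
#' @param baseline_rate out-of-field rate in Hz (0 <= baseline <= peak).
#' @return an object of class `place_cell`.
#' @export
place_cell <- function(center, width, peak_rate, baseline_rate = 0) {
  if (width <= 0) stop("'width' must be > 0")
  if (baseline_rate < 0 || peak_rate < baseline_rate)
    stop("need 0 <= baseline_rate <= peak_rate")
  structure(list(center = center, width = width, peak_rate = peak_rate,
                 baseline_rate = baseline_rate), class = "place_cell")
}

#' A population of place cells tiling a track
#'
#' Field centers are evenly spaced at segment midpoints, one cell per
#' segment, emulating a population of units with spatial tuning
#' distributed over the available 1-D space.
#'
#' @param n_cells number of cells.
#' @param track_length track length in meters.
#' @param width,peak_rate,baseline_rate shared tuning parameters; see
#'   [place_cell()].
#' @return list of [place_cell()] objects.
#' @export
tile_place_cells <- function(n_cells, track_length, width = 0.15,
                             peak_rate = 20, baseline_rate = 0.5) {
  centers <- (seq_len(n_cells) - 0.5) * track_length / n_cells
  lapply(centers, place_cell, width = width, peak_rate = peak_rate,
         baseline_rate = baseline_rate)
}

#' Track and behavior configuration
#'
#' @param length track length in meters.
#' @param K number of discretized states.
#' @param mean_speed mean running speed in m/s.
#' @param traversals number of end-to-end traversals (alternating
#'   direction, so 6 = three in each direction).
#' @param speed_jitter fractional per-traversal speed variation
#'   (uniform in `mean_speed * (1 +/- speed_jitter)`).
#' @return an object of class `track_config`.
#' @export
track_config <- function(length = 3.5, K = 32L, mean_speed = 0.2,
                         traversals = 6L, speed_jitter = 0.1) {
  if (length <= 0) stop("'length' must be > 0")
  if (K < 1) stop("'K' must be >= 1")
  if (mean_speed <= 0) stop("'mean_speed' must be > 0")
  if (speed_jitter < 0 || speed_jitter >= 1)
    stop("'speed_jitter' must lie in [0, 1)")
  structure(list(length = length, K = as.integer(K),
                 mean_speed = mean_speed,
                 traversals = as.integer(traversals),
                 speed_jitter = speed_jitter), class = "track_config")
}

#' Simulate a back-and-forth trajectory on a linear track
#'
#' Constant-speed sweeps between the track ends, direction alternating
#' every traversal, with per-traversal speed drawn uniformly from
#' `mean_speed * (1 +/- speed_jitter)`. Positions are sampled on a fixed
#' time grid.
#'
#' @param track a [track_config()].
#' @param seed RNG seed.
#' @param dt sampling interval of the position record in seconds
#'   (default 0.01, i.e. 100 Hz).
#' @return data frame with columns `time` (s) and `position` (m).
#' @export
simulate_trajectory <- function(track, seed = 1L, dt = 0.01) {
  stopifnot(inherits(track, "track_config"))
  set.seed(seed)
  speeds <- track$mean_speed *
    (1 + track$speed_jitter * stats::runif(track$traversals, -1, 1))
  seg_times <- track$length / speeds
  t_knots <- c(0, cumsum(seg_times))
  # endpoint positions 0, L, 0, L, ... (start at 0)
  p_knots <- rep(c(0, track$length), length.out = track$traversals + 1L)
  times <- seq(0, t_knots[length(t_knots)], by = dt)
  pos <- stats::approx(t_knots, p_knots, xout = times, rule = 2)$y
  out <- data.frame(time = times, position = pos)
  attr(out, "knots") <- t_knots  # traversal boundary times
  out
}

#' Simulate place-cell spike trains along a trajectory
#'
#' Inhomogeneous Poisson spiking by thinning: candidate events are drawn
#' from a homogeneous Poisson process at each cell's peak rate and kept
#' with probability rate(position(t)) / peak_rate, where the rate follows
#' the cell's Gaussian tuning curve evaluated at the interpolated
#' position.
#'
#' @param trajectory data frame from [simulate_trajectory()].
#' @param cells list of [place_cell()] objects (one output channel each).
#' @param seed RNG seed.
#' @return a [spike_trains()] with one channel per cell.
#' @export
simulate_spikes <- function(trajectory, cells, seed = 1L) {
  if (!length(cells)) stop("need at least one cell")
  set.seed(seed)
  duration <- max(trajectory$time)
  pos_at <- function(t) stats::approx(trajectory$time,
                                      trajectory$position,
                                      xout = t, rule = 2)$y
  spikes <- lapply(cells, function(cell) {
    lam_max <- cell$peak_rate
    if (lam_max <= 0) return(numeric(0))
    n_cand <- stats::rpois(1, lam_max * duration)
    if (!n_cand) return(numeric(0))
    t_cand <- sort(stats::runif(n_cand, 0, duration))
    p <- pos_at(t_cand)
    rate <- cell$baseline_rate + (cell$peak_rate - cell$baseline_rate) *
      exp(-(p - cell$center)^2 / (2 * cell$width^2))
    t_cand[stats::runif(n_cand) < rate / lam_max]
  })
  spike_trains(spikes, duration)
}

#' Rate-matched random-time noise channel
#'
#' Replaces a channel's spike train by one with the same total event
#' count but with event times i.i.d. uniform over the recording — the
#' same spike rate as the original signal, with all temporal structure
#' destroyed. Used in the leave-one-out robustness analysis.
#'
#' @param times numeric vector of spike times of the original channel.
#' @param duration recording duration in seconds (> 0).
#' @param seed RNG seed.
#' @return sorted numeric vector of the same length as `times`.
#' @export
make_noise_channel <- function(times, duration, seed = 1L) {
  if (duration <= 0) stop("'duration' must be > 0")
  set.seed(seed)
  sort(stats::runif(length(times), 0, duration))
}

#' Synthesize a raw waveform from spike trains
#'
#' Builds a sampled multichannel waveform fixture for the detection
#' stage: i.i.d. Gaussian background noise plus a stereotyped spike
#' shape added at each event time (superposed, with a warning, if
#' injections overlap). Ground-truth times stay available through the
#' input object.
#'
#' @param spikes a [spike_trains()].
#' @param sampling_rate Hz.
#' @param noise_scale Gaussian noise standard deviation.
#' @param spike_shape numeric vector, the injected waveform template
#'   (default: a biphasic negative-leading shape of amplitude 1 over
#'   ~1 ms at the given sampling rate).
#' @param seed RNG seed.
#' @return a [waveform_record()].
#' @export
synth_waveform <- function(spikes, sampling_rate, noise_scale = 1,
                           spike_shape = NULL, seed = 1L) {
  stopifnot(inherits(spikes, "spike_trains"))
  set.seed(seed)
  if (is.null(spike_shape)) {
    n_sh <- max(4L, round(sampling_rate * 1e-3))
    ph <- seq(0, 2 * pi, length.out = n_sh)
    spike_shape <- -sin(ph) * exp(-3 * ph / (2 * pi))
  }
  if (any(!is.finite(spike_shape))) stop("'spike_shape' must be finite")
  n_samp <- ceiling(spikes$duration * sampling_rate) + length(spike_shape)
  n_ch <- spikes$n_channels
  w <- matrix(stats::rnorm(n_samp * n_ch, sd = noise_scale), n_samp, n_ch)
  overlap <- FALSE
  for (i in seq_len(n_ch)) {
    idx0 <- round(spikes$spikes[[i]] * sampling_rate) + 1L
    if (length(idx0) > 1L &&
        any(diff(idx0) < length(spike_shape))) overlap <- TRUE
    for (j in idx0) {
      span <- j:(j + length(spike_shape) - 1L)
      w[span, i] <- w[span, i] + spike_shape
    }
  }
  if (overlap)
    warning("overlapping spike injections; shapes superposed")
  waveform_record(w, sampling_rate)
}
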