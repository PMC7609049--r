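# Synthetic functional recordings: periodic synchronized calcium spikes
# across ROIs and phase-locked multi-tone field potentials.

#' Generate synchronized periodic calcium traces
#'
#' All ROIs share the same planted spike times at the stated period
#' (events at `(k - 1/2) * period_s`, so a 240 s recording with a 30 s
#' period holds 8 synchronized events), each a fast rise with exponential
#' decay on a constant baseline plus Gaussian noise. Optional independent
#' per-ROI events model local activity; `switch_off_s` truncates the
#' shared events at a given time (channel-blocker analogue).
#'
#' @param n_rois Number of ROI traces.
#' @param period_s Shared spike period.
#' @param spike_amplitude Event amplitude (baseline units; 0 gives flat
#'   noisy traces).
#' @param noise_sd Additive Gaussian noise sd.
#' @param rate_hz,duration_s Sampling (default 10 Hz for 4 min, i.e. 2400
#'   samples per ROI).
#' @param baseline Constant fluorescence baseline (> 0).
#' @param decay_s Event decay time constant.
#' @param private_rate_hz Poisson rate of additional per-ROI events
#'   (amplitude half the shared one).
#' @param switch_off_s Drop shared events at/after this time, or `NULL`.
#' @param seed Optional integer seed.
#' @return A [trace_set()]; planted shared event times are stored in
#'   `attr(, "event_times_s")`.
#' @export
generate_calcium_traces <- function(n_rois = 4L, period_s = 30,
                                    spike_amplitude = 50, noise_sd = 2,
                                    rate_hz = 10, duration_s = 240,
                                    baseline = 100, decay_s = 2,
                                    private_rate_hz = 0,
                                    switch_off_s = NULL, seed = NULL) {
  stopifnot(rate_hz > 0, duration_s > 0, baseline > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(rate_hz * duration_s)
  t <- (seq_len(n) - 1) / rate_hz
  events <- (seq_len(floor(duration_s / period_s)) - 0.5) * period_s
  if (!is.null(switch_off_s)) events <- events[events < switch_off_s]
  kernel <- function(t0, amp) {
    v <- numeric(n)
    sel <- t >= t0
    v[sel] <- amp * exp(-(t[sel] - t0) / decay_s)
    v
  }
  tr <- matrix(0, n, n_rois)
  for (j in seq_len(n_rois)) {
    x <- rep(baseline, n)
    for (t0 in events) x <- x + kernel(t0, spike_amplitude)
    if (private_rate_hz > 0) {
      k <- rpois(1L, private_rate_hz * duration_s)
      for (t0 in runif(k, 0, duration_s)) {
        x <- x + kernel(t0, spike_amplitude / 2)
      }
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    tr[, j] <- x
  }
  out <- trace_set(tr, rate_hz)
  attr(out, "event_times_s") <- events
  out
}

#' Generate phase-locked multi-tone field potentials
#'
#' Each electrode records the same sum of sinusoids (shared random phases,
#' per-electrode gain close to 1) plus independent Gaussian noise —
#' synchronous electrical waves across the array. An empty component list
#' gives pure noise.
#'
#' @param components List of `c(freq_hz, amplitude)` pairs; every
#'   frequency must be below the Nyquist rate `rate_hz / 2`.
#' @param rate_hz,duration_s Sampling.
#' @param noise_sd Per-electrode noise sd.
#' @param n_electrodes Number of traces.
#' @param seed Optional integer seed.
#' @return A [trace_set()].
#' @export
generate_field_potential <- function(components = list(c(1, 50), c(14, 25)),
                                     rate_hz = 200, duration_s = 30,
                                     noise_sd = 1, n_electrodes = 4L,
                                     seed = NULL) {
  stopifnot(rate_hz > 0, duration_s > 0)
  for (cmp in components) {
    if (cmp[1] >= rate_hz / 2) {
      stop("component frequency ", cmp[1],
           " Hz is at/above the Nyquist limit ", rate_hz / 2, " Hz")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(rate_hz * duration_s)
  t <- (seq_len(n) - 1) / rate_hz
  base <- numeric(n)
  for (cmp in components) {
    base <- base + cmp[2] * sin(2 * pi * cmp[1] * t + runif(1, 0, 2 * pi))
  }
  tr <- vapply(seq_len(n_electrodes), function(j) {
    g <- if (n_electrodes > 1) runif(1, 0.9, 1.1) else 1
    g * base + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  }, numeric(n))
  colnames(tr) <- paste0("el", seq_len(n_electrodes))
  trace_set(tr, rate_hz)
}

#' Render a synthetic calcium-imaging movie with synchronized flashes
#'
#' Small frame-series in which the whole aggregate flashes at the shared
#' event times of [generate_calcium_traces()]; used to validate ROI trace
#' extraction end to end.
#'
#' @param rows,cols Frame size.
#' @param rate_hz,duration_s Sampling.
#' @param period_s Shared flash period.
#' @param amplitude Flash amplitude over baseline.
#' @param baseline Constant baseline intensity.
#' @param noise_sd Per-pixel Gaussian noise.
#' @param decay_s Flash decay constant.
#' @param seed Optional integer seed.
#' @return List: `movie` (array frame x row x col), `event_times_s`.
#' @export
generate_calcium_movie <- function(rows = 32L, cols = 32L, rate_hz = 10,
                                   duration_s = 60, period_s = 15,
                                   amplitude = 40, baseline = 100,
                                   noise_sd = 2, decay_s = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(rate_hz * duration_s)
  t <- (seq_len(n) - 1) / rate_hz
  events <- (seq_len(floor(duration_s / period_s)) - 0.5) * period_s
  level <- rep(baseline, n)
  for (t0 in events) {
    sel <- t >= t0
    level[sel] <- level[sel] + amplitude * exp(-(t[sel] - t0) / decay_s)
  }
  movie <- array(rep(level, rows * cols), dim = c(n, rows, cols))
  if (noise_sd > 0) {
    movie <- movie + array(rnorm(length(movie), 0, noise_sd), dim = dim(movie))
  }
  list(movie = movie, event_times_s = events)
}
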