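# Functional readouts: ROI trace extraction, calcium spike detection and
# synchrony, Savitzky-Golay smoothing, MEA oscillation metric and spectra.

#' Uniformly sampled trace set
#'
#' Time-indexed fluorescence or voltage traces per ROI/electrode with a
#' shared sampling rate.
#'
#' @param traces Numeric matrix, one column per ROI/electrode.
#' @param rate_hz Sampling rate (> 0).
#' @param time_s Optional sample times; default `(0:(n-1))/rate_hz`.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, rate_hz, time_s = NULL) {
  traces <- as.matrix(traces)
  stopifnot(rate_hz > 0)
  if (is.null(time_s)) time_s <- (seq_len(nrow(traces)) - 1) / rate_hz
  stopifnot(length(time_s) == nrow(traces))
  if (is.null(colnames(traces))) {
    colnames(traces) <- paste0("roi", seq_len(ncol(traces)))
  }
  structure(list(time_s = time_s, traces = traces, rate_hz = rate_hz),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set %d trace(s) x %d samples @ %g Hz (%.1f s)>\n",
              ncol(x$traces), nrow(x$traces), x$rate_hz,
              nrow(x$traces) / x$rate_hz))
  invisible(x)
}

#' Write / read a trace set as CSV (time column + one column per trace)
#'
#' @param ts A [trace_set()].
#' @param path CSV path.
#' @export
write_traces <- function(ts, path) {
  df <- data.frame(time_s = ts$time_s, ts$traces, check.names = FALSE)
  write_results(df, path)
}

#' @rdname write_traces
#' @param rate_hz Sampling rate; inferred from the time column if `NULL`.
#' @export
read_traces <- function(path, rate_hz = NULL) {
  df <- read_results(path)
  t <- df$time_s
  if (is.null(rate_hz)) rate_hz <- 1 / median(diff(t))
  trace_set(as.matrix(df[setdiff(names(df), "time_s")]), rate_hz, time_s = t)
}

#' Extract mean-intensity ROI traces from an image time series
#'
#' For each frame, the mean intensity inside each ROI mask; the standard
#' readout for aggregate-wide calcium imaging. Linear in image intensity.
#'
#' @param movie 3-D array `(frame, row, col)`.
#' @param rois List of logical masks (same frame size); each must be
#'   non-empty.
#' @param rate_hz Sampling rate of the movie.
#' @return A [trace_set()], one column per ROI.
#' @export
extract_roi_traces <- function(movie, rois, rate_hz) {
  stopifnot(length(dim(movie)) == 3L, length(rois) >= 1L)
  for (r in rois) {
    stopifnot(identical(dim(r), dim(movie)[2:3]))
    if (!any(r)) stop("empty ROI")
  }
  n <- dim(movie)[1]
  tr <- vapply(rois, function(mask) {
    idx <- which(mask)
    vapply(seq_len(n), function(f) mean(movie[f, , ][idx]), 0)
  }, numeric(n))
  if (!is.null(names(rois))) colnames(tr) <- names(rois)
  trace_set(tr, rate_hz)
}

#' Quadrant ROI masks
#'
#' Splits a frame into four equal quadrants — the standard subdivision for
#' demonstrating aggregate-wide synchrony.
#'
#' @param rows,cols Frame size.
#' @return Named list of 4 logical masks (`Q1`..`Q4`).
#' @export
quadrant_rois <- function(rows, cols) {
  rh <- rows %/% 2L; ch <- cols %/% 2L
  mk <- function(rr, cc) {
    m <- matrix(FALSE, rows, cols); m[rr, cc] <- TRUE; m
  }
  list(Q1 = mk(1:rh, 1:ch), Q2 = mk(1:rh, (ch + 1):cols),
       Q3 = mk((rh + 1):rows, 1:ch), Q4 = mk((rh + 1):rows, (ch + 1):cols))
}

rolling_quantile <- function(x, width, prob) {
  n <- length(x)
  width <- min(width, n)
  out <- zoo::rollapply(zoo::zoo(x), width = width, partial = TRUE,
                        align = "center",
                        FUN = quantile, probs = prob, names = FALSE)
  as.numeric(out)
}

#' Detect calcium spikes in a fluorescence trace
#'
#' Computes dF/F0 with F0 a rolling lower-percentile baseline, then marks
#' events where dF/F0 exceeds the trace median by `threshold_mads` times
#' its MAD. Event extents are delimited with hysteresis: an event is a
#' contiguous run above half the threshold that contains at least one
#' supra-threshold sample, so that noise flicker on a decaying tail does
#' not split one event into several. Events closer than `min_separation_s`
#' are merged (largest kept). A zero-variance trace yields an empty train.
#'
#' @param x Numeric trace.
#' @param rate_hz Sampling rate.
#' @param params List: `baseline_percentile` (default 0.10),
#'   `baseline_window_s` (30), `threshold_mads` (5), `min_separation_s`
#'   (5; aggregate-wide calcium events are seconds wide, so the refractory
#'   window must exceed the event width).
#' @return Data frame of class `spike_train`: `time_s`, `amplitude_dff`,
#'   strictly increasing times.
#' @export
detect_spikes <- function(x, rate_hz, params = list()) {
  p <- modifyList(list(baseline_percentile = 0.10, baseline_window_s = 30,
                       threshold_mads = 5, min_separation_s = 5), params)
  n <- length(x)
  stopifnot(n > p$baseline_window_s * rate_hz / 2)
  empty <- data.frame(time_s = numeric(0), amplitude_dff = numeric(0))
  class(empty) <- c("spike_train", class(empty))
  if (sd(x) == 0) return(empty)
  w <- max(3L, round(p$baseline_window_s * rate_hz))
  f0 <- rolling_quantile(x, w, p$baseline_percentile)
  f0[f0 <= 0] <- max(mean(f0[f0 > 0]), .Machine$double.eps)
  dff <- (x - f0) / f0
  scale <- mad(dff)
  if (scale == 0) return(empty)
  ctr <- median(dff)
  thr <- ctr + p$threshold_mads * scale
  lo <- ctr + p$threshold_mads * scale / 2
  if (!any(dff > thr)) return(empty)
  r <- rle(dff > lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # event time = onset (first supra-threshold sample of the run): for fast
  # calcium transients the onset is far sharper than the noisy peak sample
  peaks <- integer(0)
  amps <- numeric(0)
  for (i in runs) {
    seg <- starts[i]:ends[i]
    over <- seg[dff[seg] > thr]
    if (!length(over)) next
    peaks <- c(peaks, over[1])
    amps <- c(amps, max(dff[seg]))
  }
  if (!length(peaks)) return(empty)
  # merge events within min_separation, keeping the larger
  ord <- order(peaks)
  peaks <- peaks[ord]; amps <- amps[ord]
  min_gap <- p$min_separation_s * rate_hz
  kept <- integer(0)
  for (k in seq_along(peaks)) {
    last <- if (length(kept)) kept[length(kept)] else NA_integer_
    if (!is.na(last) && (peaks[k] - peaks[last]) < min_gap) {
      if (amps[k] > amps[last]) kept[length(kept)] <- k
    } else {
      kept <- c(kept, k)
    }
  }
  out <- data.frame(time_s = (peaks[kept] - 1) / rate_hz,
                    amplitude_dff = amps[kept])
  class(out) <- c("spike_train", class(out))
  out
}

#' Synchrony of multi-ROI activity
#'
#' Two complementary measures: the mean pairwise Pearson correlation of the
#' raw traces, and — when spike trains are available — the fraction of
#' event clusters in which every trace participates within `±window_s`.
#'
#' @param ts A [trace_set()] with >= 2 traces.
#' @param window_s Co-activity window.
#' @param spike_params Passed to [detect_spikes()].
#' @return List: `pairwise_correlation_mean`, `coactive_fraction`,
#'   `n_events_per_trace`.
#' @export
synchrony_index <- function(ts, window_s = 1, spike_params = list()) {
  tr <- ts$traces
  if (ncol(tr) < 2L) stop("need at least 2 traces")
  cm <- suppressWarnings(cor(tr))
  pc <- mean(cm[upper.tri(cm)], na.rm = TRUE)
  trains <- lapply(seq_len(ncol(tr)), function(j) {
    detect_spikes(tr[, j], ts$rate_hz, spike_params)$time_s
  })
  all_ev <- sort(unique(unlist(trains)))
  coact <- NA_real_
  if (length(all_ev)) {
    # cluster union events closer than window into single reference events
    cl <- cumsum(c(1, diff(all_ev) > window_s))
    centers <- tapply(all_ev, cl, median)
    hit <- vapply(centers, function(tc) {
      all(vapply(trains, function(tt) {
        length(tt) > 0 && min(abs(tt - tc)) <= window_s
      }, TRUE))
    }, TRUE)
    coact <- mean(hit)
  }
  list(pairwise_correlation_mean = pc, coactive_fraction = coact,
       n_events_per_trace = lengths(trains))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing; reproduces polynomials up to
#' `polyorder` exactly in the window interior, which preserves peak shapes
#' while removing noise. An even `window_samples` is widened by one sample
#' (the filter needs a centre point).
#'
#' @param x Numeric trace.
#' @param window_samples Window length; default 51 (a nominal 50-sample
#'   window adjusted to the next odd length).
#' @param polyorder Polynomial order (default 3), must be < window.
#' @return Smoothed trace of the same length.
#' @export
sg_smooth <- function(x, window_samples = 51L, polyorder = 3L) {
  w <- as.integer(window_samples)
  if (w %% 2L == 0L) w <- w + 1L
  stopifnot(polyorder < w)
  if (w > length(x)) stop("window longer than trace")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = w))
}

#' Field-potential oscillation metric relative to basal
#'
#' The sum of absolute field-potential oscillations over a `window_s`
#' segment of the treated recording divided by the same quantity for the
#' basal recording. Both segments are Savitzky-Golay smoothed and
#' mean-removed first, so constant offsets do not contribute; the metric
#' is scale-covariant (doubling the treated amplitude doubles the ratio).
#'
#' @param basal,treated Numeric traces at the same rate.
#' @param rate_hz Sampling rate.
#' @param window_s Analysis window (default 15 s).
#' @param offset_s Segment start within each trace (default 0).
#' @param sg_window,polyorder Smoothing parameters (see [sg_smooth()]).
#' @return Ratio treated/basal.
#' @export
oscillation_metric <- function(basal, treated, rate_hz, window_s = 15,
                               offset_s = 0, sg_window = 51L,
                               polyorder = 3L) {
  n <- round(window_s * rate_hz)
  i0 <- round(offset_s * rate_hz)
  stopifnot(length(basal) >= i0 + n, length(treated) >= i0 + n)
  seg_sum <- function(x) {
    seg <- sg_smooth(x[(i0 + 1):(i0 + n)], sg_window, polyorder)
    sum(abs(seg - mean(seg)))
  }
  sb <- seg_sum(basal)
  if (sb == 0) stop("basal oscillation sum is 0")
  seg_sum(treated) / sb
}

#' Windowed FFT power spectrum with dominant-peak extraction
#'
#' Mean-removes the trace, applies a Blackman window, and returns the
#' one-sided power spectrum. Dominant peaks are local maxima (within
#' `±neighborhood` bins) whose power exceeds `prominence_factor` times the
#' median spectral power, sorted by power.
#'
#' @param x Numeric trace (>= 2 s of data).
#' @param rate_hz Sampling rate.
#' @param window Taper; only `"blackman"` is provided.
#' @param prominence_factor Peak threshold relative to median power.
#' @param neighborhood Half-width (bins) for the local-maximum test; also
#'   suppresses side-lobe duplicates.
#' @return List: `frequencies`, `power`, `dominant_peaks` (data frame
#'   `freq_hz`, `power`, decreasing power).
#' @export
spectrum <- function(x, rate_hz, window = "blackman",
                     prominence_factor = 20, neighborhood = 4L) {
  n <- length(x)
  stopifnot(n >= 2 * rate_hz)
  window <- match.arg(window, "blackman")
  w <- signal::blackman(n)
  xw <- (x - mean(x)) * w
  sp <- abs(fft(xw))^2 / n
  half <- floor(n / 2)
  freqs <- (seq_len(half) ) * rate_hz / n   # exclude DC (k = 0)
  pw <- sp[2:(half + 1)]
  thr <- prominence_factor * median(pw)
  is_peak <- vapply(seq_along(pw), function(i) {
    if (pw[i] <= thr) return(FALSE)
    lo <- max(1L, i - neighborhood); hi <- min(length(pw), i + neighborhood)
    pw[i] >= max(pw[lo:hi])
  }, TRUE)
  pk <- data.frame(freq_hz = freqs[is_peak], power = pw[is_peak])
  pk <- pk[order(pk$power, decreasing = TRUE), , drop = FALSE]
  rownames(pk) <- NULL
  list(frequencies = freqs, power = pw, dominant_peaks = pk)
}
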