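test_that("ROI traces are means, linear, and recover planted flashes", {
  # constant movie -> constant traces
  movie <- array(42, dim = c(5, 16, 16))
  rois <- quadrant_rois(16, 16)
  ts <- extract_roi_traces(movie, rois, 10)
  expect_true(all(ts$traces == 42))

  # whole-frame ROI equals the area-weighted mean of quadrant ROIs
  mv <- generate_calcium_movie(rows = 16, cols = 16, duration_s = 10,
                               seed = 2)
  whole <- list(all = matrix(TRUE, 16, 16))
  t_whole <- extract_roi_traces(mv$movie, whole, 10)
  t_quad <- extract_roi_traces(mv$movie, rois, 10)
  w <- vapply(rois, sum, 0) / (16 * 16)
  expect_equal(as.numeric(t_quad$traces %*% w),
               as.numeric(t_whole$traces), tolerance = 1e-12)

  # synchronized flashes peak at identical frames in all quadrants
  # (first planted event at 7.5 s -> frame 76 at 10 Hz)
  mv2 <- generate_calcium_movie(duration_s = 60, period_s = 15, seed = 3)
  tq <- extract_roi_traces(mv2$movie, quadrant_rois(32, 32), 10)
  peaks <- apply(tq$traces[70:90, ], 2, which.max)
  expect_true(all(peaks == peaks[1]))
  expect_error(extract_roi_traces(movie, list(matrix(FALSE, 16, 16)), 10),
               "empty ROI")
})

test_that("spike detection recovers planted periodic events exactly", {
  ts <- generate_calcium_traces(period_s = 30, duration_s = 240,
                                rate_hz = 10, seed = 41)
  train <- detect_spikes(ts$traces[, 1], ts$rate_hz)
  expect_equal(nrow(train), 8L)
  expect_true(all(abs(train$time_s - attr(ts, "event_times_s")) <= 0.1))
  expect_true(all(diff(train$time_s) > 0))

  # flat trace and zero-amplitude generator -> no events
  expect_equal(nrow(detect_spikes(rep(7, 600), 10)), 0L)
  quiet <- generate_calcium_traces(spike_amplitude = 0, seed = 42)
  expect_equal(nrow(detect_spikes(quiet$traces[, 1], 10)), 0L)
})

test_that("channel-blocker analogue: no events after the switch-off", {
  ts <- generate_calcium_traces(switch_off_s = 120, seed = 43)
  for (j in seq_len(ncol(ts$traces))) {
    train <- detect_spikes(ts$traces[, j], ts$rate_hz)
    expect_equal(sum(train$time_s >= 120), 0L)
    expect_gt(nrow(train), 0L)
  }
})

test_that("synchrony separates shared activity from independent noise", {
  ts <- generate_calcium_traces(seed = 44)
  sy <- synchrony_index(ts)
  expect_gt(sy$pairwise_correlation_mean, 0.9)
  expect_equal(sy$coactive_fraction, 1.0)

  # identical traces -> correlation exactly 1
  same <- trace_set(cbind(ts$traces[, 1], ts$traces[, 1]), ts$rate_hz)
  expect_equal(synchrony_index(same)$pairwise_correlation_mean, 1.0)

  set.seed(45)
  noise <- trace_set(matrix(rnorm(2400 * 4, 100, 2), ncol = 4), 10)
  expect_lt(abs(synchrony_index(noise)$pairwise_correlation_mean), 0.1)
  expect_error(synchrony_index(trace_set(matrix(1:10, ncol = 1), 10)),
               "2 traces")
})

test_that("Savitzky-Golay smoothing reproduces cubics and tames noise", {
  t <- seq(0, 1, length.out = 400)
  cubic <- 3 + 2 * t - 5 * t^2 + 4 * t^3
  sm <- sg_smooth(cubic, 51, 3)
  expect_equal(sm[50:350], cubic[50:350], tolerance = 1e-10)
  expect_equal(sg_smooth(rep(5, 200), 51, 3), rep(5, 200))

  # nominal even window 50 is adjusted to 51 transparently
  expect_equal(sg_smooth(cubic, 50, 3), sg_smooth(cubic, 51, 3))

  set.seed(46)
  wn <- rnorm(2000)
  expect_lt(var(sg_smooth(wn, 51, 3)), var(wn))
  expect_error(sg_smooth(1:10, 51, 3), "window longer")
})

test_that("oscillation metric is exact on identity and scaling", {
  fp <- generate_field_potential(seed = 47)
  x <- fp$traces[, 1]
  expect_equal(oscillation_metric(x, x, fp$rate_hz), 1.0)
  expect_equal(oscillation_metric(x, 2 * x, fp$rate_hz), 2.0)
  # scale covariance holds for arbitrary positive factors, noise-free
  fp0 <- generate_field_potential(noise_sd = 0, seed = 48)
  y <- fp0$traces[, 1]
  for (c in c(0.3, 1.7)) {
    expect_equal(oscillation_metric(y, c * y, fp0$rate_hz), c,
                 tolerance = 1e-12)
  }
  expect_error(oscillation_metric(rep(0, 4000), x, fp$rate_hz), "basal")
})

test_that("agonist-like boost of one tone moves the metric into (1, 2)", {
  base <- list(c(1, 50), c(14, 25))
  boosted <- list(c(1, 50), c(14, 50))
  b <- generate_field_potential(base, noise_sd = 0, n_electrodes = 1,
                                seed = 49)
  t <- generate_field_potential(boosted, noise_sd = 0, n_electrodes = 1,
                                seed = 49)
  m <- oscillation_metric(b$traces[, 1], t$traces[, 1], b$rate_hz)
  expect_gt(m, 1)
  expect_lt(m, 2)
})

test_that("spectra find planted tones and reject white noise", {
  # pure sinusoid -> single dominant peak at its frequency (±1 bin)
  rate <- 1000; dur <- 4
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  sp <- spectrum(sin(2 * pi * 14 * t), rate)
  expect_equal(nrow(sp$dominant_peaks), 1L)
  expect_lt(abs(sp$dominant_peaks$freq_hz[1] - 14), 1 / dur + 1e-9)

  # planted two-tone signal -> exactly two peaks at 1 and 14 Hz
  fp <- generate_field_potential(list(c(1, 50), c(14, 25)), rate_hz = 200,
                                 duration_s = 30, seed = 50)
  sp2 <- spectrum(fp$traces[, 1], fp$rate_hz)
  expect_equal(nrow(sp2$dominant_peaks), 2L)
  expect_equal(sort(sp2$dominant_peaks$freq_hz), c(1, 14),
               tolerance = 1 / 30 + 1e-9)

  # white noise: no dominant peak in >= 90% of seeded repeats
  clean <- 0L
  for (s in 1:10) {
    set.seed(s)
    spn <- spectrum(rnorm(2000), 100)
    if (nrow(spn$dominant_peaks) == 0L) clean <- clean + 1L
  }
  expect_gte(clean, 9L)
})

test_that("trace sets round-trip through CSV", {
  ts <- generate_field_potential(seed = 51, duration_s = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_traces(ts, f)
  rt <- read_traces(f)
  expect_equal(rt$traces, ts$traces)
  expect_equal(rt$rate_hz, ts$rate_hz, tolerance = 1e-6)
})
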