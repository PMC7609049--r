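test_that("well summary totals equal the per-plane breakdown exactly", {
  g <- demo_stack(n_nuclei = 250, seed = 17)
  s <- quantify_nuclear_marker(
    g$stack, "Sox2", gate = gate_spec(5, NULL, 1500, NULL),
    well_id = "A1", background = list(method = "parabola", curvature = 500),
    seg_params = list(expected_diameter_um = 4, detection_threshold = 30))
  expect_equal(s$n_objects, sum(s$per_plane$n_objects))
  expect_equal(s$total_brightness_abu, sum(s$per_plane$total_brightness_abu))
  expect_equal(s$aggregate_area_um2, sum(s$per_plane$aggregate_area_um2))
  # marker-positive counts recover the planted Sox2+ population within 10%
  planted <- sum(g$truth$Sox2)
  expect_lt(abs(s$n_objects - planted) / planted, 0.10)
})

test_that("QC-failed wells are refused unless overridden", {
  g <- demo_stack(n_nuclei = 100, seed = 18)
  st <- plant_dust(g$stack)
  qc <- qc_classify(st)
  expect_false(qc$pass)
  expect_error(quantify_nuclear_marker(st, "Sox2", gate_preset("sox2"),
                                       well_id = "B2", qc = qc),
               "failed QC")
  s <- quantify_nuclear_marker(
    st, "Sox2", gate = gate_spec(5, NULL, 1500, NULL), well_id = "B2",
    background = list(method = "parabola", curvature = 500), qc = qc,
    override_qc = TRUE)
  expect_false(s$qc_pass)
})

test_that("filamentous quantification sums masked mean intensities", {
  # constant intensity 100 inside the mask on every plane -> planes x 100
  vox <- array(0, dim = c(2, 4, 128, 128))
  rr <- seq_len(128)
  disc <- outer((rr - 64)^2, (rr - 64)^2, "+") <= 45^2
  for (p in 1:4) {
    m <- matrix(0, 128, 128); m[disc] <- 400
    vox[1, p, , ] <- m                   # detection channel
    m2 <- matrix(0, 128, 128); m2[disc] <- 100
    vox[2, p, , ] <- m2                  # filament channel
  }
  st <- image_stack(vox, 1, 20, list(channel_spec("DAPI", "nuclear"),
                                     channel_spec("Map2", "filamentous")))
  s <- quantify_filamentous_marker(st, "Map2", well_id = "C3")
  # the cleaned mask includes a thin dark rim, so the per-plane mean is
  # slightly below 100; totals must still be the exact sum of planes
  expect_equal(s$filament_intensity_abu, sum(s$per_plane$mean_intensity_abu))
  expect_gt(s$filament_intensity_abu, 4 * 100 * 0.7)
  expect_lte(s$filament_intensity_abu, 400)

  # doubling filament density increases the metric (generator monotonicity)
  mk <- function(dens, seed) {
    ph <- organoid_phenotype(radius_um = 45, n_nuclei = 80,
                             filament_density = c(Map2 = dens))
    g <- generate_organoid_stack(
      ph, channels = list(channel_spec("DAPI", "nuclear"),
                          channel_spec("Map2", "filamentous")),
      planes = 2, rows = 112, cols = 112, plane_spacing_um = 22, seed = seed)
    quantify_filamentous_marker(g$stack, "Map2")$filament_intensity_abu
  }
  expect_gt(mk(16, 4), mk(4, 4))
})

test_that("empty masks yield a zero filament metric", {
  vox <- array(1, dim = c(1, 2, 64, 64))  # uniform dim plane: no aggregate
  st <- image_stack(vox, 1, 20, list(channel_spec("Map2", "filamentous")))
  s <- quantify_filamentous_marker(st, "Map2")
  expect_equal(s$filament_intensity_abu, 0)
})

test_that("marker-negative fraction follows its formula and bounds", {
  expect_equal(as.numeric(sox2_negative_fraction(30, 100)), 0.70)
  expect_equal(as.numeric(sox2_negative_fraction(0, 50)), 1.0)
  expect_equal(as.numeric(sox2_negative_fraction(100, 100)), 0.0)
  expect_error(sox2_negative_fraction(10, 0), "> 0")
  clipped <- sox2_negative_fraction(120, 100)
  expect_equal(as.numeric(clipped), 0)
  expect_true(attr(clipped, "flagged"))
})

test_that("maturity fraction of a synthetic well recovers the planted mix", {
  ph <- organoid_phenotype(radius_um = 50, n_nuclei = 400,
                           zone_fractions = list(Sox2 = c(0.25, 0.25, 0.25)))
  g <- generate_organoid_stack(
    ph, channels = list(channel_spec("DAPI", "nuclear"),
                        channel_spec("Sox2", "nuclear-marker")),
    planes = 3, rows = 128, cols = 128, plane_spacing_um = 25, seed = 19)
  args <- list(gate = gate_spec(5, NULL, 1500, NULL),
               background = list(method = "parabola", curvature = 500),
               seg_params = list(expected_diameter_um = 4,
                                 detection_threshold = 30))
  s_sox <- do.call(quantify_nuclear_marker, c(list(g$stack, "Sox2"), args))
  s_dapi <- do.call(quantify_nuclear_marker, c(list(g$stack, "DAPI"), args))
  est <- as.numeric(sox2_negative_fraction(s_sox, s_dapi))
  planted <- 1 - sum(g$truth$Sox2) / nrow(g$truth)
  expect_lt(abs(est - planted), 0.05)
})

test_that("batch CV is the sample sd over the mean and scale-invariant", {
  b <- batch_cv(c(2, 2, 2))
  expect_equal(b$cv, 0)
  b2 <- batch_cv(c(1, 2, 3))
  expect_equal(b2$cv, 0.5)   # sample sd 1, mean 2
  b3 <- batch_cv(10 * c(1, 2, 3))
  expect_equal(b3$cv, b2$cv)
  expect_error(batch_cv(c(5)), "at least 2")
  expect_error(batch_cv(c(-1, 1)), "mean is zero")
})

test_that("edge-effect report is exact on identical wells", {
  rep0 <- edge_effect_report(rep(100, 12),
                             rep(c("edge", "inside"), each = 6),
                             n_boot = 200, seed = 1)
  expect_equal(rep0$relative_difference, 0)
  expect_error(edge_effect_report(1:4, c("edge", "edge", "inside", "inside")),
               "at least 3")
})

test_that("dilution linearity handles exact, noisy and shuffled inputs", {
  fr <- rep(c(0.0125, 0.025, 0.05, 0.1, 0.2, 0.4), each = 2)
  exact <- 5 + 100 * fr
  fit <- dilution_linearity(fr, exact)
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$slope, 100)

  set.seed(2)
  shuffled <- dilution_linearity(fr, sample(exact))
  expect_lt(shuffled$r_squared, 0.5)
  expect_error(dilution_linearity(c(1, 1, 2, 2), 1:4), "3 distinct")
})

test_that("brightfield size measurement matches the analytic disc", {
  rr <- seq_len(400)
  img <- ifelse(outer((rr - 200)^2, (rr - 200)^2, "+") <= 150^2, 200, 10)
  set.seed(4)
  img <- img + abs(rnorm(160000, 0, 3))
  sz <- size_from_brightfield(img, pixel_size_um = 1)
  expect_lt(abs(sz$area_um2 - pi * 150^2) / (pi * 150^2), 0.03)

  # aggregate + debris: the larger component is returned
  img2 <- img
  img2[20:40, 20:40] <- 200
  sz2 <- size_from_brightfield(img2)
  expect_equal(sz2$area_um2, sz$area_um2, tolerance = 0.02)

  expect_error(size_from_brightfield(matrix(5, 50, 50)), "constant")
})
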