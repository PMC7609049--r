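test_that("sum_channels equals element-wise addition", {
  g <- demo_stack(n_nuclei = 80, seed = 14)
  s <- sum_channels(g$stack)
  manual <- g$stack$voxels[1, , , ] + g$stack$voxels[2, , , ]
  expect_equal(s$voxels[1, , , ], manual)
  # single-channel subset is the identity
  s1 <- sum_channels(g$stack, "DAPI")
  expect_equal(s1$voxels[1, , , ], g$stack$voxels[1, , , ])
  # constant channels: 3 x 10 -> 30
  vox <- array(10, dim = c(3, 1, 6, 6))
  st <- image_stack(vox, 1, 1, list(channel_spec("a", "nuclear"),
                                    channel_spec("b", "nuclear"),
                                    channel_spec("c", "nuclear")))
  expect_true(all(sum_channels(st)$voxels == 30))
  expect_error(sum_channels(g$stack, "nope"), "unknown channel")
})

test_that("a bright disc is detected with its analytic area", {
  rr <- seq_len(300)
  d2 <- outer((rr - 150)^2, (rr - 150)^2, "+")
  plane <- ifelse(d2 <= 100^2, 1000, 0) + abs(matrix(rnorm(9e4, 0, 5), 300))
  regs <- detect_aggregate(plane, pixel_size_um = 1)
  expect_length(regs, 1L)
  # cleaned region = disc grown by the kept dilate/erode asymmetry (+7 px)
  expect_lt(abs(regs[[1]]$area_um2 - pi * 107^2) / (pi * 107^2), 0.05)
  expect_gt(regs[[1]]$roundness, 0.8)

  # blank noise plane -> empty
  blank <- abs(matrix(rnorm(9e4, 0, 5), 300))
  expect_length(detect_aggregate(blank), 0L)

  # a small debris disc fails the 4000 um^2 gate; note the gate applies to
  # the cleaned region, which the verbatim dilate-10/erode-3 step grows by
  # ~7 px of radius, so the raw disc must be well below the gate
  small <- ifelse(outer((rr - 150)^2, (rr - 150)^2, "+") <= 26^2, 1000, 0)
  expect_length(detect_aggregate(small), 0L)
  # but passes once the gate is relaxed
  expect_length(detect_aggregate(small,
    params = detect_params(min_area_um2 = 2000)), 1L)
})

test_that("dilate-then-erode only smooths boundaries of large discs", {
  # the ~7 px net radius growth is kept by design; at organoid scale
  # (radius >= 100 px) it changes disc area by < 15%
  rr <- seq_len(300)
  for (radius in c(100, 120)) {
    plane <- ifelse(outer((rr - 150)^2, (rr - 150)^2, "+") <= radius^2,
                    1000, 0)
    raw_area <- sum(plane > 0)
    regs <- detect_aggregate(plane, params = detect_params(
      threshold = list(method = "absolute", value = 500)))
    expect_length(regs, 1L)
    expect_lt(abs(regs[[1]]$area_um2 - raw_area) / raw_area, 0.15)
  }
})

test_that("detected area is monotone in the generator disc radius", {
  rr <- seq_len(260)
  areas <- vapply(c(50, 70, 90), function(radius) {
    plane <- ifelse(outer((rr - 130)^2, (rr - 130)^2, "+") <= radius^2,
                    800, 0)
    detect_aggregate(plane)[[1]]$area_um2
  }, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("per-plane areas follow the sphere's circle-of-latitude profile", {
  g <- demo_stack(n_nuclei = 250, seed = 16, planes = 5, rows = 144,
                  radius_um = 55)
  dets <- detect_aggregate_stack(g$stack)
  areas <- vapply(dets, function(d) {
    if (is.null(d$region)) 0 else d$region$area_um2
  }, 0)
  mid <- ceiling(length(areas) / 2)
  expect_equal(which.max(areas), mid, tolerance = 1)
  expect_true(all(areas[mid] >= areas[c(1, length(areas))]))
  # accepted-nucleus counts peak at the equator too (planted geometry)
  counts <- table(factor(g$truth$plane, levels = 1:5))
  expect_true(counts[3] >= max(counts[1], counts[5]))
})

test_that("QC flags planted artifacts and positioning problems", {
  g <- demo_stack(n_nuclei = 200, seed = 9)
  expect_true(qc_classify(g$stack)$pass)

  vd <- qc_classify(plant_dust(g$stack))
  expect_false(vd$pass)
  expect_true("dust" %in% vd$reasons)

  vf <- qc_classify(plant_fiber(g$stack))
  expect_false(vf$pass)
  expect_true("fiber" %in% vf$reasons)

  # aggregate shifted against the field border -> incomplete
  cropped <- g$stack
  cropped$voxels <- cropped$voxels[, , , 40:128, drop = FALSE]
  vi <- qc_classify(cropped)
  expect_true("incomplete" %in% vi$reasons)

  # no aggregate anywhere -> missing
  ph <- organoid_phenotype(radius_um = 40, n_nuclei = 0)
  acq <- acquisition_model(tissue_background_abu = 0, haze_amplitude = 0)
  g0 <- generate_organoid_stack(ph, acq,
                                list(channel_spec("DAPI", "nuclear")),
                                planes = 2, rows = 96, cols = 96,
                                plane_spacing_um = 20, seed = 2)
  vm <- qc_classify(g0$stack)
  expect_false(vm$pass)
  expect_true("missing" %in% vm$reasons)
  # pass implies empty reasons (invariant)
  expect_length(qc_classify(g$stack)$reasons, 0L)
})
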