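test_that("well-separated blobs are each found exactly once", {
  bp <- generate_blob_plane(50, rows = 256, cols = 256, amplitude = 150,
                            noise_sd = 5, min_sep_px = 12, seed = 21)
  objs <- find_nuclei(sliding_parabola(bp$plane, kappa = 0.5),
                      raw = bp$plane,
                      params = list(expected_diameter_um = 5,
                                    detection_threshold = 30))
  expect_true(abs(nrow(objs) - 50) <= 2)
  m <- match_centers(cbind(objs$row, objs$col), bp$centers, 3)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("blobs outside the mask are not returned; blank planes are empty", {
  bp <- generate_blob_plane(20, rows = 128, cols = 128, noise_sd = 2,
                            min_sep_px = 15, seed = 22)
  mask <- matrix(FALSE, 128, 128)
  mask[1:64, ] <- TRUE
  objs <- find_nuclei(bp$plane, mask = mask,
                      params = list(expected_diameter_um = 5,
                                    detection_threshold = 30))
  inside <- bp$centers[, 1] <= 64
  expect_equal(nrow(objs), sum(inside), tolerance = 1)
  expect_true(all(objs$row <= 66))

  blank <- matrix(0, 64, 64)
  expect_equal(nrow(find_nuclei(blank)), 0L)
  expect_equal(nrow(find_cells(blank)), 0L)
})

test_that("soma-scale cells are recovered at high recall", {
  bp <- generate_blob_plane(40, rows = 256, cols = 256, amplitude = 200,
                            sigma_px = 8 / 2.355, noise_sd = 5,
                            min_sep_px = 20, margin_px = 14, seed = 23)
  objs <- find_cells(subtract_blur(bp$plane, 10), raw = bp$plane,
                     params = list(detection_threshold = 20))
  m <- match_centers(cbind(objs$row, objs$col), bp$centers, 5)
  expect_gte(m$recall, 0.9)
})

test_that("the Sox2 gate window accepts/rejects the worked examples", {
  gate <- gate_preset("sox2")
  objs <- apply_gate(objects_table(area = c(12, 80, 12, 12),
                                   brightness = c(1500, 1500, 6500, 1000)),
                     gate)
  expect_equal(objs$accepted, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(objs$rejection_reason,
               c(NA, "too_large", "too_bright", "too_dim"))

  # cCasp3 window: 11 < area < 100, brightness > 2700
  cc <- apply_gate(objects_table(area = c(50, 10, 120, 50),
                                 brightness = c(3000, 3000, 3000, 2000)),
                   gate_preset("ccasp3"))
  expect_equal(cc$accepted, c(TRUE, FALSE, FALSE, FALSE))

  # TH cell gate: > 25 um^2, > 200 abu; 20 um^2 rejected
  th <- apply_gate(objects_table(area = c(30, 20), brightness = c(500, 500)),
                   gate_preset("th"))
  expect_equal(th$accepted, c(TRUE, FALSE))

  # strict inequalities: exactly-at-bound objects are rejected
  at <- apply_gate(objects_table(area = c(10, 70), brightness = c(1200, 1201)),
                   gate)
  expect_equal(at$accepted, c(FALSE, FALSE))
})

test_that("gating is idempotent, order-independent and monotone", {
  set.seed(3)
  objs <- objects_table(area = runif(60, 1, 120),
                        brightness = runif(60, 100, 8000))
  gate <- gate_preset("sox2")
  g1 <- apply_gate(objs, gate)
  expect_identical(apply_gate(g1, gate), g1)        # idempotent
  perm <- sample(nrow(objs))
  g2 <- apply_gate(objs[perm, ], gate)
  expect_equal(g2$accepted, g1$accepted[perm])      # order-independent

  # tightening any bound never increases the accepted count
  n0 <- sum(g1$accepted)
  tighter <- list(gate_spec(20, 70, 1200, 6000),
                  gate_spec(10, 50, 1200, 6000),
                  gate_spec(10, 70, 2400, 6000),
                  gate_spec(10, 70, 1200, 4000))
  for (g in tighter) expect_lte(sum(apply_gate(objs, g)$accepted), n0)
})

test_that("fused nuclei are rejected by the area/brightness caps", {
  # two blobs planted 3 px apart fuse into one object
  m <- matrix(0, 64, 64)
  m <- organoidhcs:::add_blob(m, 32, 31, 1.8, 300)
  m <- organoidhcs:::add_blob(m, 32, 34, 1.8, 300)
  objs <- find_nuclei(m, params = list(expected_diameter_um = 5,
                                       detection_threshold = 30))
  objs <- apply_gate(objs, gate_spec(10, 40, 1200, 6000))
  expect_true(nrow(objs) >= 1)
  expect_false(any(objs$accepted))
  expect_true(all(objs$rejection_reason %in% c("too_large", "too_bright")))
})

test_that("double-positive matching is capped, unique and complete", {
  mk <- function(rc) {
    o <- objects_table(area = rep(30, nrow(rc)), brightness = rep(3000, nrow(rc)))
    o$row <- rc[, 1]; o$col <- rc[, 2]
    o$accepted <- TRUE
    o
  }
  # identical centroids -> all matched
  set.seed(8)
  rc <- cbind(runif(10, 10, 90), runif(10, 10, 90))
  pairs <- classify_double_positive(mk(rc), mk(rc), 2)
  expect_equal(nrow(pairs), 10L)
  expect_equal(pairs$distance_um, rep(0, 10))
  expect_false(anyDuplicated(pairs$index_a) > 0)
  expect_false(anyDuplicated(pairs$index_b) > 0)

  # disjoint centroids farther than the cap -> zero matches
  far <- classify_double_positive(mk(rc), mk(rc + 50), 2)
  expect_equal(nrow(far), 0L)

  # 10 coincident + 5 solo per channel -> exactly 10 pairs
  solo_a <- cbind(runif(5, 150, 190), runif(5, 150, 190))
  solo_b <- cbind(runif(5, 210, 250), runif(5, 210, 250))
  pairs2 <- classify_double_positive(mk(rbind(rc, solo_a)),
                                     mk(rbind(rc, solo_b)), 2)
  expect_equal(nrow(pairs2), 10L)
  expect_true(all(pairs2$index_a <= 10 & pairs2$index_b <= 10))
})
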