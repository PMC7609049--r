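# Independent oracles and small fixtures used across the suite.

# brute-force 2-D parabolic erosion: min over all offsets of
# f(x+u) + kappa * |u|^2 (full support)
brute_parabolic_erode <- function(m, kappa) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(Inf, nr, nc)
  for (du in -(nr - 1):(nr - 1)) {
    for (dv in -(nc - 1):(nc - 1)) {
      rs <- max(1, 1 - du):min(nr, nr - du)
      cs <- max(1, 1 - dv):min(nc, nc - dv)
      out[rs, cs] <- pmin(out[rs, cs],
                          m[rs + du, cs + dv] + kappa * (du^2 + dv^2))
    }
  }
  out
}

brute_parabolic_opening <- function(m, kappa) {
  -brute_parabolic_erode(-brute_parabolic_erode(m, kappa), kappa)
}

# match detected centroids against ground-truth centers; returns counts
match_centers <- function(obj_rc, truth_rc, radius_px) {
  if (!nrow(obj_rc) || !nrow(truth_rc)) {
    return(list(recall = 0, precision = 0,
                n_matched_truth = 0, n_matched_obj = 0))
  }
  dmat <- sqrt(outer(obj_rc[, 1], truth_rc[, 1], "-")^2 +
                 outer(obj_rc[, 2], truth_rc[, 2], "-")^2)
  n_mt <- sum(apply(dmat, 2, min) <= radius_px)
  n_mo <- sum(apply(dmat, 1, min) <= radius_px)
  list(recall = n_mt / nrow(truth_rc), precision = n_mo / nrow(obj_rc),
       n_matched_truth = n_mt, n_matched_obj = n_mo)
}

# truth centers in pixel coordinates for one plane of a generated stack
truth_plane_centers <- function(truth, plane, rows, cols,
                                marker = NULL) {
  tr <- truth[truth$plane == plane, , drop = FALSE]
  if (!is.null(marker)) tr <- tr[tr[[marker]], , drop = FALSE]
  cbind((rows + 1) / 2 + tr$y_um, (cols + 1) / 2 + tr$x_um)
}

# small two-channel organoid stack reused by several detection tests
demo_stack <- function(n_nuclei = 300, seed = 9, planes = 3, rows = 128,
                       radius_um = 50, labeled_fraction = 0.3) {
  ph <- organoid_phenotype(radius_um = radius_um, n_nuclei = n_nuclei,
                           labeled_fraction = labeled_fraction)
  chans <- list(channel_spec("DAPI", "nuclear"),
                channel_spec("Sox2", "nuclear-marker"))
  generate_organoid_stack(ph, channels = chans, planes = planes,
                          rows = rows, cols = rows,
                          plane_spacing_um = radius_um / 2, seed = seed)
}

# synthetic objects table for gate tests
objects_table <- function(area, brightness) {
  data.frame(plane = 1L, row = seq_along(area), col = seq_along(area),
             area_um2 = area, total_brightness_abu = brightness,
             mean_brightness_abu = brightness / pmax(area, 1),
             marker = "m", accepted = NA,
             rejection_reason = NA_character_,
             stringsAsFactors = FALSE)
}
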