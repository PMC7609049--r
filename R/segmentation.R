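# Stage 3: detect nuclei/cells inside the aggregate region and gate them
# by size and brightness windows.

#' Size/brightness gate specification
#'
#' An accept/reject window on object area (µm²) and brightness (abu). All
#' bounds are strict inequalities ("larger than", "brighter than"): an
#' object is accepted iff `area > min_area_um2`, `area < max_area_um2`
#' (where present), `brightness > min_brightness_abu` and
#' `brightness < max_brightness_abu` (where present). Upper caps exist to
#' exclude image artifacts, small dust particles and fused/overlapping
#' nuclei, which present as abnormally large or bright objects.
#'
#' @param min_area_um2,max_area_um2 Area window; `max` may be `NULL`.
#' @param min_brightness_abu,max_brightness_abu Brightness window on the
#'   object's total (summed) raw brightness; `max` may be `NULL`.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(min_area_um2 = 0, max_area_um2 = NULL,
                      min_brightness_abu = 0, max_brightness_abu = NULL) {
  if (!is.null(max_area_um2)) stopifnot(min_area_um2 < max_area_um2)
  if (!is.null(max_brightness_abu)) {
    stopifnot(min_brightness_abu < max_brightness_abu)
  }
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_brightness_abu = min_brightness_abu,
                 max_brightness_abu = max_brightness_abu),
            class = "gate_spec")
}

#' Standard marker gates
#'
#' Preset windows for the markers routinely quantified in midbrain-organoid
#' screens: Sox2+ nuclei (area > 10 µm², < 70 µm²; brightness > 1200 abu,
#' < 6000 abu), TH+ and Map2+ cells (> 25 µm², > 200 abu), cCasp3+
#' apoptotic nuclei (> 11 µm², < 100 µm², > 2700 abu).
#'
#' @param marker One of `"sox2"`, `"th"`, `"map2"`, `"ccasp3"`.
#' @return A [gate_spec()].
#' @export
gate_preset <- function(marker = c("sox2", "th", "map2", "ccasp3")) {
  switch(match.arg(marker),
         sox2 = gate_spec(10, 70, 1200, 6000),
         th = gate_spec(25, NULL, 200, NULL),
         map2 = gate_spec(25, NULL, 200, NULL),
         ccasp3 = gate_spec(11, 100, 2700, NULL))
}

empty_objects <- function() {
  data.frame(plane = integer(0), row = numeric(0), col = numeric(0),
             area_um2 = numeric(0), total_brightness_abu = numeric(0),
             mean_brightness_abu = numeric(0), marker = character(0),
             accepted = logical(0), rejection_reason = character(0),
             stringsAsFactors = FALSE)
}

#' Detect blob-like objects (nuclei or cells) on a corrected plane
#'
#' Re-implementation of the "find nuclei"/"find cells" stage: candidate
#' seeds are local maxima of a difference-of-Gaussians (Laplacian-of-
#' Gaussian approximation) response at the expected object scale, grown by
#' marker-controlled region growing on the corrected intensity
#' ([EBImage::propagate()], a seeded watershed on the intensity landscape),
#' and clipped to the aggregate mask. Object brightness is measured on the
#' RAW channel (the corrected image is used for detection only); the total
#' is the sum over the object footprint, as downstream reporting sums
#' counts and total brightness.
#'
#' @param corrected Background-corrected plane (matrix).
#' @param mask Logical matrix: aggregate region (from
#'   [detect_aggregate()]); objects are confined to it. `NULL` means the
#'   whole frame.
#' @param raw Raw plane for brightness measurement; defaults to
#'   `corrected`.
#' @param pixel_size_um Lateral calibration.
#' @param params List: `expected_diameter_um` (object scale),
#'   `detection_threshold` (abu, on the scale-smoothed corrected image),
#'   `grow_fraction` (region-growing threshold as a fraction of
#'   `detection_threshold`), `max_radius_factor` (objects are clipped to
#'   this multiple of the expected diameter around their seed, so that a
#'   lone seed cannot flood a large connected low-intensity area),
#'   `marker` (label carried into the output), `plane` (index carried into
#'   the output).
#' @return Data frame of segmented objects: `plane`, centroid `row`/`col`
#'   (pixels), `area_um2`, `total_brightness_abu`, `mean_brightness_abu`,
#'   `marker`, `accepted` (all `NA` until gated), `rejection_reason`.
#' @export
find_objects <- function(corrected, mask = NULL, raw = corrected,
                         pixel_size_um = 1,
                         params = list()) {
  p <- modifyList(list(expected_diameter_um = 7, detection_threshold = 25,
                       grow_fraction = 0.5, max_radius_factor = 1.25,
                       marker = NA_character_, plane = NA_integer_), params)
  stopifnot(is.matrix(corrected))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(corrected), ncol(corrected))
  d_px <- p$expected_diameter_um / pixel_size_um
  sigma <- max(0.8, d_px / (2 * sqrt(2)))
  s1 <- gaussian_blur(corrected, sigma)
  s2 <- gaussian_blur(corrected, 1.6 * sigma)
  dog <- s1 - s2
  nb <- disc_brush(max(1L, round(d_px / 2)))
  local_max <- EBImage::imageData(EBImage::dilate(dog, nb))
  seed_px <- (dog >= local_max - 1e-9) & (dog > 0) &
    (s1 > p$detection_threshold) & mask
  if (!any(seed_px)) return(empty_objects())
  seeds <- EBImage::imageData(EBImage::bwlabel(seed_px))
  grow <- mask & (s1 > p$detection_threshold * p$grow_fraction)
  lab <- EBImage::imageData(
    EBImage::propagate(corrected, seeds, mask = grow, lambda = 1e-4))
  nlab <- max(lab)
  if (nlab == 0L) return(empty_objects())
  # seed centroids, for the radius cap
  sidx <- which(seeds > 0)
  slab <- seeds[sidx]
  srow <- vapply(split(((sidx - 1L) %% nrow(seeds)) + 1L, slab), mean, 0)
  scol <- vapply(split(((sidx - 1L) %/% nrow(seeds)) + 1L, slab), mean, 0)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  cap <- p$max_radius_factor * d_px
  in_cap <- (rows - srow[labs])^2 + (cols - scol[labs])^2 <= cap^2
  idx <- idx[in_cap]; labs <- labs[in_cap]
  rows <- rows[in_cap]; cols <- cols[in_cap]
  if (!length(idx)) return(empty_objects())
  vals <- raw[idx]
  area_px <- tabulate(labs, nbins = nlab)
  keep <- which(area_px > 0)
  tot <- vapply(split(vals, labs), sum, 0)
  crow <- vapply(split(rows, labs), mean, 0)
  ccol <- vapply(split(cols, labs), mean, 0)
  data.frame(plane = p$plane,
             row = unname(crow), col = unname(ccol),
             area_um2 = area_px[keep] * pixel_size_um^2,
             total_brightness_abu = unname(tot),
             mean_brightness_abu = unname(tot) / area_px[keep],
             marker = p$marker,
             accepted = NA,
             rejection_reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Find nuclei within the aggregate region
#'
#' [find_objects()] tuned for nucleus-scale blobs (expected diameter 7 µm).
#'
#' @inheritParams find_objects
#' @export
find_nuclei <- function(corrected, mask = NULL, raw = corrected,
                        pixel_size_um = 1, params = list()) {
  params <- modifyList(list(expected_diameter_um = 7,
                            detection_threshold = 25), params)
  find_objects(corrected, mask, raw, pixel_size_um, params)
}

#' Find cells (soma-scale objects) within the aggregate region
#'
#' [find_objects()] tuned for larger soma-scale objects: expected diameter
#' 12 µm and a lower detection threshold, paired downstream with the
#' 25 µm² / 200 abu gates.
#'
#' @inheritParams find_objects
#' @export
find_cells <- function(corrected, mask = NULL, raw = corrected,
                       pixel_size_um = 1, params = list()) {
  params <- modifyList(list(expected_diameter_um = 12,
                            detection_threshold = 15), params)
  find_objects(corrected, mask, raw, pixel_size_um, params)
}

#' Apply a size/brightness gate to segmented objects
#'
#' Sets `accepted` and `rejection_reason` (`too_small`, `too_large`,
#' `too_dim`, `too_bright`; the first violated bound in that order) on the
#' object table. Input order is preserved; gating is idempotent.
#'
#' @param objects Data frame from [find_nuclei()]/[find_cells()].
#' @param gate A [gate_spec()].
#' @return The object table with `accepted`/`rejection_reason` filled in.
#' @export
apply_gate <- function(objects, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  if (!nrow(objects)) return(objects)
  reason <- rep(NA_character_, nrow(objects))
  a <- objects$area_um2
  b <- objects$total_brightness_abu
  reason[is.na(reason) & !(a > gate$min_area_um2)] <- "too_small"
  if (!is.null(gate$max_area_um2)) {
    reason[is.na(reason) & !(a < gate$max_area_um2)] <- "too_large"
  }
  reason[is.na(reason) & !(b > gate$min_brightness_abu)] <- "too_dim"
  if (!is.null(gate$max_brightness_abu)) {
    reason[is.na(reason) & !(b < gate$max_brightness_abu)] <- "too_bright"
  }
  objects$accepted <- is.na(reason)
  objects$rejection_reason <- reason
  objects
}

#' Match accepted objects across two channels (double positives)
#'
#' Greedy nearest-neighbour matching of accepted objects from the same
#' plane across two channels under a centre-distance cap; each object is
#' matched at most once. A cell is double-positive when it fulfils both
#' channel filters at the same location.
#'
#' @param objects_a,objects_b Gated object tables (only `accepted` rows are
#'   matched).
#' @param max_center_distance_um Distance cap.
#' @param pixel_size_um Converts centroid pixels to µm.
#' @return Data frame: `index_a`, `index_b` (row indices into the accepted
#'   subsets' parent tables), `distance_um`.
#' @export
classify_double_positive <- function(objects_a, objects_b,
                                     max_center_distance_um,
                                     pixel_size_um = 1) {
  ia <- which(isTRUE_vec(objects_a$accepted))
  ib <- which(isTRUE_vec(objects_b$accepted))
  out <- data.frame(index_a = integer(0), index_b = integer(0),
                    distance_um = numeric(0))
  if (!length(ia) || !length(ib)) return(out)
  dmat <- outer(objects_a$row[ia], objects_b$row[ib], "-")^2 +
    outer(objects_a$col[ia], objects_b$col[ib], "-")^2
  dmat <- sqrt(dmat) * pixel_size_um
  dmat[dmat > max_center_distance_um] <- Inf
  while (any(is.finite(dmat))) {
    k <- arrayInd(which.min(dmat), dim(dmat))
    out <- rbind(out, data.frame(index_a = ia[k[1]], index_b = ib[k[2]],
                                 distance_um = dmat[k[1], k[2]]))
    dmat[k[1], ] <- Inf
    dmat[, k[2]] <- Inf
  }
  out[order(out$index_a), , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x
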