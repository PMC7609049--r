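# Stage 1: identify the bona fide organoid region on each confocal plane
# and flag contaminated or invalid wells.

#' Sum a subset of channels into a single detection channel
#'
#' Summing all channels widens the usable intensity range and makes the
#' aggregate outline robust to markers with sparse signal; the summed image
#' is used for sample identification only.
#'
#' @param stack An [image_stack()].
#' @param channels Character vector of channel names; default all channels.
#' @return A single-channel [image_stack()] named `"sum"`.
#' @export
sum_channels <- function(stack, channels = NULL) {
  if (is.null(channels)) channels <- channel_names(stack)
  stopifnot(length(channels) >= 1)
  idx <- vapply(channels, function(ch) channel_index(stack, ch), 1L)
  d <- dim(stack$voxels)
  out <- array(0, dim = c(1L, d[2], d[3], d[4]))
  for (i in idx) out[1, , , ] <- out[1, , , ] + stack$voxels[i, , , ]
  image_stack(out, stack$pixel_size_um, stack$plane_spacing_um,
              list(channel_spec("sum", stack$channels[[idx[1]]]$role)))
}

#' Aggregate-detection parameters
#'
#' Defaults follow common high-content screening practice: median smoothing,
#' automatic (Otsu) thresholding of the summed image, edge cleaning by
#' dilation (10 px) then erosion (3 px), and gates requiring a minimum of
#' 4000 µm² area and 300 abu region brightness. The brightness gate applies
#' to the region mean by default (`brightness_measure = "mean"`), switchable
#' to the integrated total.
#'
#' @param smooth List: `method` (`"median"` or `"gaussian"`), `width_px`.
#' @param threshold List: `method` (`"otsu"` or `"absolute"`), `value`
#'   (abu, for `"absolute"`).
#' @param dilate_px,erode_px Disc radii for edge cleaning, in pixels. The
#'   asymmetric default (10/3) is kept verbatim from the described
#'   procedure and therefore grows the mask by ~7 px.
#' @param min_area_um2 Minimum region area.
#' @param min_brightness_abu Minimum region brightness.
#' @param brightness_measure `"mean"` or `"total"`.
#' @return A parameter list.
#' @export
detect_params <- function(smooth = list(method = "median", width_px = 5L),
                          threshold = list(method = "otsu", value = NULL),
                          dilate_px = 10L, erode_px = 3L,
                          min_area_um2 = 4000,
                          min_brightness_abu = 300,
                          brightness_measure = c("mean", "total")) {
  list(smooth = smooth, threshold = threshold,
       dilate_px = as.integer(dilate_px), erode_px = as.integer(erode_px),
       min_area_um2 = min_area_um2,
       min_brightness_abu = min_brightness_abu,
       brightness_measure = match.arg(brightness_measure))
}

disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

region_features <- function(lab, raw, pixel_size_um) {
  nlab <- max(lab)
  if (nlab == 0L) return(NULL)
  shp <- EBImage::computeFeatures.shape(lab)
  shp <- matrix(shp, nrow = nlab, ncol = 6,
                dimnames = list(NULL, c("s.area", "s.perimeter",
                                        "s.radius.mean", "s.radius.sd",
                                        "s.radius.min", "s.radius.max")))
  out <- vector("list", nlab)
  for (i in seq_len(nlab)) {
    mask <- lab == i
    vals <- raw[mask]
    area_px <- shp[i, "s.area"]
    per <- max(shp[i, "s.perimeter"], 1)
    out[[i]] <- list(
      mask = mask,
      area_um2 = area_px * pixel_size_um^2,
      mean_brightness_abu = mean(vals),
      total_brightness_abu = sum(vals),
      roundness = min(1, 4 * pi * area_px / per^2),
      touches_border = any(mask[1, ]) || any(mask[nrow(mask), ]) ||
        any(mask[, 1]) || any(mask[, ncol(mask)])
    )
  }
  out
}

#' Detect the aggregate region on one confocal plane
#'
#' Smooths the (summed-channel) plane, thresholds it, cleans the region
#' edge by dilation and erosion, and keeps connected regions passing the
#' minimum area and brightness gates. An empty result is valid: planes
#' above or below the organoid contain no aggregate.
#'
#' @param plane Numeric matrix from [sum_channels()].
#' @param pixel_size_um Lateral calibration (µm/px).
#' @param params See [detect_params()].
#' @return List of region masks, sorted by decreasing area. Each is a list
#'   with `mask` (logical matrix), `area_um2`, `mean_brightness_abu`,
#'   `total_brightness_abu`, `roundness` (4*pi*area/perimeter²),
#'   `touches_border`, `plane` (`NA`, filled by stack-level callers).
#' @export
detect_aggregate <- function(plane, pixel_size_um = 1,
                             params = detect_params()) {
  stopifnot(is.matrix(plane))
  mx <- max(plane)
  if (mx <= 0) return(list())
  sm <- params$smooth
  smoothed <- switch(sm$method,
    median = {
      w <- as.integer(sm$width_px) %/% 2L
      EBImage::imageData(EBImage::medianFilter(plane / mx, max(w, 1L))) * mx
    },
    gaussian = gaussian_blur(plane, sm$width_px),
    stop("unknown smoothing method: ", sm$method))
  thr <- switch(params$threshold$method,
    otsu = {
      rng <- range(smoothed)
      if (diff(rng) <= 0) return(list())
      EBImage::otsu(EBImage::Image((smoothed - rng[1]) / diff(rng))) *
        diff(rng) + rng[1]
    },
    absolute = params$threshold$value,
    stop("unknown threshold method: ", params$threshold$method))
  bw <- smoothed > thr
  if (!any(bw)) return(list())
  bw <- EBImage::imageData(EBImage::dilate(bw, disc_brush(params$dilate_px))) > 0.5
  bw <- EBImage::imageData(EBImage::erode(bw, disc_brush(params$erode_px))) > 0.5
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  regions <- region_features(lab, plane, pixel_size_um)
  if (is.null(regions)) return(list())
  keep <- vapply(regions, function(r) {
    b <- if (params$brightness_measure == "mean") r$mean_brightness_abu
         else r$total_brightness_abu
    r$area_um2 >= params$min_area_um2 && b >= params$min_brightness_abu
  }, TRUE)
  regions <- regions[keep]
  regions <- regions[order(vapply(regions, `[[`, 0, "area_um2"),
                           decreasing = TRUE)]
  lapply(regions, function(r) { r$plane <- NA_integer_; r })
}

#' Detect the aggregate on every plane of a stack
#'
#' Runs [detect_aggregate()] on the summed-channel image of each plane.
#' When several regions pass all gates on one plane, the largest is kept
#' and the plane is flagged for review (the workflow assumes one aggregate
#' per well).
#'
#' @param stack An [image_stack()].
#' @param channels Channels to sum for detection (default all).
#' @param params See [detect_params()].
#' @return List with one entry per plane: `region` (or `NULL`),
#'   `n_candidates`, `multiple` flag.
#' @export
detect_aggregate_stack <- function(stack, channels = NULL,
                                   params = detect_params()) {
  summed <- sum_channels(stack, channels)
  lapply(seq_len(n_planes(stack)), function(p) {
    regs <- detect_aggregate(summed$voxels[1, p, , ],
                             stack$pixel_size_um, params)
    region <- if (length(regs)) {
      r <- regs[[1]]
      r$plane <- p
      r
    } else NULL
    list(region = region, n_candidates = length(regs),
         multiple = length(regs) > 1L)
  })
}

#' QC artifact-screening parameters
#'
#' @param artifact_min_abu Absolute intensity threshold (summed image) above
#'   which pixels are treated as artifact candidates; `NULL` (default)
#'   derives it as `artifact_rel_factor` times the brightest pixel inside
#'   the aggregate mask (artifacts like dust and fibers out-shine tissue).
#' @param artifact_rel_factor Relative factor for the automatic threshold.
#' @param dust_min_area_um2 Minimum dust footprint.
#' @param dust_roundness_min Compactness floor for dust (roundness >= this).
#' @param fiber_roundness_max Roundness ceiling for fibers (default 0.2).
#' @param fiber_min_um Minimum fiber length (major axis).
#' @return Parameter list.
#' @export
qc_params <- function(artifact_min_abu = NULL,
                      artifact_rel_factor = 1.5,
                      dust_min_area_um2 = 15,
                      dust_roundness_min = 0.4,
                      fiber_roundness_max = 0.2,
                      fiber_min_um = 50) {
  list(artifact_min_abu = artifact_min_abu,
       artifact_rel_factor = artifact_rel_factor,
       dust_min_area_um2 = dust_min_area_um2,
       dust_roundness_min = dust_roundness_min,
       fiber_roundness_max = fiber_roundness_max,
       fiber_min_um = fiber_min_um)
}

#' Classify a well's QC status
#'
#' Inspects detection results and the summed image for the rejection
#' reasons used in screening bookkeeping: `dust` (compact bright
#' off-aggregate object), `fiber` (elongated bright streak), `incomplete`
#' (aggregate mask touches the field border on any plane, i.e. improperly
#' positioned/partially imaged), `missing` (no plane contains an
#' aggregate). A well passes iff no reason applies.
#'
#' @param stack The well's [image_stack()].
#' @param detections Result of [detect_aggregate_stack()]; computed here if
#'   `NULL`.
#' @param params See [qc_params()].
#' @param well_id Optional well id carried into the verdict.
#' @param detect_parameters Passed to [detect_aggregate_stack()] when
#'   `detections` is `NULL`.
#' @return A `qc_verdict`: list with `well_id`, `pass`, `reasons`.
#' @export
qc_classify <- function(stack, detections = NULL, params = qc_params(),
                        well_id = NA_character_,
                        detect_parameters = detect_params()) {
  if (is.null(detections)) {
    detections <- detect_aggregate_stack(stack, params = detect_parameters)
  }
  reasons <- character(0)
  regions <- Filter(Negate(is.null), lapply(detections, `[[`, "region"))
  if (!length(regions)) {
    reasons <- c(reasons, "missing")
  } else {
    if (any(vapply(regions, `[[`, TRUE, "touches_border"))) {
      reasons <- c(reasons, "incomplete")
    }
  }
  summed <- sum_channels(stack)
  px <- stack$pixel_size_um
  thr <- params$artifact_min_abu
  if (is.null(thr)) {
    # reference: brightest tissue pixel inside any detected aggregate; a
    # per-plane reference would be corrupted on planes where the artifact
    # itself defeats aggregate detection
    ref <- -Inf
    for (p in seq_len(n_planes(stack))) {
      agg <- detections[[p]]$region
      if (!is.null(agg)) {
        ref <- max(ref, max(summed$voxels[1, p, , ][agg$mask]))
      }
    }
    if (!is.finite(ref)) ref <- quantile(summed$voxels, 0.999)
    thr <- params$artifact_rel_factor * ref
  }
  for (p in seq_len(n_planes(stack))) {
    img <- summed$voxels[1, p, , ]
    agg <- detections[[p]]$region
    bw <- img > thr
    if (!any(bw)) next
    lab <- EBImage::imageData(EBImage::bwlabel(bw))
    nlab <- max(lab)
    mom <- EBImage::computeFeatures.moment(lab)
    mom <- matrix(mom, nrow = nlab, ncol = 5,
                  dimnames = list(NULL, c("m.cx", "m.cy", "m.majoraxis",
                                          "m.eccentricity", "m.theta")))
    feats <- region_features(lab, img, px)
    for (i in seq_along(feats)) {
      f <- feats[[i]]
      len_um <- mom[i, "m.majoraxis"] * px
      if (f$roundness < params$fiber_roundness_max &&
          len_um >= params$fiber_min_um) {
        reasons <- union(reasons, "fiber")
        next
      }
      centroid_in_agg <- if (!is.null(agg)) {
        # computeFeatures.moment: m.cx along first array dim (rows)
        agg$mask[max(1, min(nrow(img), round(mom[i, "m.cx"]))),
                 max(1, min(ncol(img), round(mom[i, "m.cy"])))]
      } else FALSE
      if (!centroid_in_agg &&
          f$area_um2 >= params$dust_min_area_um2 &&
          f$roundness >= params$dust_roundness_min) {
        reasons <- union(reasons, "dust")
      }
    }
  }
  structure(list(well_id = well_id, pass = length(reasons) == 0L,
                 reasons = reasons),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<QC %s: %s%s>\n",
              ifelse(is.na(x$well_id), "well", x$well_id),
              if (x$pass) "PASS" else "FAIL",
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]") else ""))
  invisible(x)
}
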