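# Synthetic confocal stacks of spherical organoid-like aggregates with full
# ground truth: Gaussian nuclear blobs, concentric marker zones, filamentous
# texture, depth attenuation, smooth haze, noise, and plantable artifacts.

#' Organoid phenotype for the synthetic generator
#'
#' Describes the aggregate geometry and composition that
#' [generate_organoid_stack()] renders: a roughly spherical aggregate of
#' `radius_um` containing `n_nuclei` nuclei, marker-positive with
#' per-concentric-zone probabilities.
#'
#' @param radius_um Aggregate radius (µm); must exceed the nucleus radius.
#' @param n_nuclei Number of nuclei to plant (>= 0).
#' @param nucleus_radius_um Length-2 vector, mean and sd of nucleus radius.
#' @param zone_fractions Named list, one entry per marker channel: a vector
#'   of marker-positive probabilities for equal-thickness concentric zones,
#'   ordered core to surface. Markers without an entry fall back to
#'   `labeled_fraction` (uniform), or to 1 if that is `NULL`.
#' @param filament_density Named numeric; expected filament segments per
#'   1000 µm² of cross-section for each filamentous channel.
#' @param labeled_fraction Fraction of nuclei carrying a tracker label
#'   (dilution series), in \[0, 1\], or `NULL`.
#' @param min_separation_factor Minimum nucleus centre distance as a
#'   multiple of the mean nucleus radius (dart-throwing placement). Lower
#'   values allow overlapping nuclei to stress-test segmentation.
#' @return An object of class `organoid_phenotype`.
#' @export
organoid_phenotype <- function(radius_um = 200,
                               n_nuclei = 1000L,
                               nucleus_radius_um = c(3, 0.3),
                               zone_fractions = list(),
                               filament_density = c(),
                               labeled_fraction = NULL,
                               min_separation_factor = 1.5) {
  stopifnot(radius_um > nucleus_radius_um[1], n_nuclei >= 0)
  fr <- unlist(zone_fractions, use.names = FALSE)
  if (length(fr) && (any(fr < 0) || any(fr > 1))) {
    stop("all zone fractions must lie in [0, 1]")
  }
  if (!is.null(labeled_fraction)) {
    stopifnot(labeled_fraction >= 0, labeled_fraction <= 1)
  }
  structure(list(radius_um = radius_um,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_um = nucleus_radius_um,
                 zone_fractions = zone_fractions,
                 filament_density = filament_density,
                 labeled_fraction = labeled_fraction,
                 min_separation_factor = min_separation_factor),
            class = "organoid_phenotype")
}

#' Acquisition model for the synthetic generator
#'
#' Simple model of why large cleared spherical samples show a non-uniform
#' background: exponential intensity loss with imaging depth, a smooth
#' additive haze, and additive sensor noise.
#'
#' @param attenuation_per_um Exponential decay of intensity per µm of depth
#'   below the top of the aggregate (>= 0). The default 0.0015/µm halves
#'   intensity after ~460 µm, a residual effect consistent with
#'   well-cleared tissue.
#' @param haze_amplitude Peak amplitude (abu) of the smooth additive
#'   background dome inside the aggregate.
#' @param haze_scale_um Correlation length of the random smooth component
#'   of the haze.
#' @param noise_sd Additive Gaussian noise sd (abu), >= 0.
#' @param abu_per_fluorophore Gain: peak abu of a fully labeled nucleus.
#' @param tissue_background_abu Diffuse stained-tissue level (abu) inside
#'   the aggregate cross-section; makes the aggregate a coherent bright
#'   region against the empty well, as whole-mount-stained tissue is.
#'   Applied in full to `nuclear` and `filamentous` channels (counterstains
#'   and abundant markers label the whole tissue) and scaled by
#'   `marker_tissue_factor` in `nuclear-marker` channels (sparse labels
#'   contribute only nonspecific background).
#' @param marker_tissue_factor Tissue-background scale for
#'   `nuclear-marker` channels, in \[0, 1\].
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(attenuation_per_um = 0.0015,
                              haze_amplitude = 120,
                              haze_scale_um = 40,
                              noise_sd = 7,
                              abu_per_fluorophore = 250,
                              tissue_background_abu = 300,
                              marker_tissue_factor = 0.15) {
  stopifnot(attenuation_per_um >= 0, noise_sd >= 0, abu_per_fluorophore > 0,
            tissue_background_abu >= 0,
            marker_tissue_factor >= 0, marker_tissue_factor <= 1)
  structure(list(attenuation_per_um = attenuation_per_um,
                 haze_amplitude = haze_amplitude,
                 haze_scale_um = haze_scale_um,
                 noise_sd = noise_sd,
                 abu_per_fluorophore = abu_per_fluorophore,
                 tissue_background_abu = tissue_background_abu,
                 marker_tissue_factor = marker_tissue_factor),
            class = "acquisition_model")
}

# dart-throwing placement of n points uniform in a sphere of radius R with
# a minimum pairwise centre distance; returns a (n x 3) matrix (x, y, z) um.
# When z_centers_um is given (plane snapping), the separation constraint is
# applied in-plane (xy) among nuclei that snap to the same confocal plane,
# which is what keeps rendered blobs resolvable on each optical section.
place_nuclei <- function(n, radius_um, min_sep_um, z_centers_um = NULL,
                         max_tries = 60L) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  pts <- matrix(NA_real_, n, 3)
  plane <- integer(n)
  k <- 0L
  tries <- 0L
  min_sep2 <- min_sep_um^2
  while (k < n && tries < max_tries * n) {
    tries <- tries + 1L
    p <- runif(3, -radius_um, radius_um)
    if (sum(p^2) > radius_um^2) next
    if (!is.null(z_centers_um)) {
      pl <- which.min(abs(z_centers_um - p[3]))
      if (k > 0L) {
        same <- which(plane[seq_len(k)] == pl)
        if (length(same)) {
          d2 <- (pts[same, 1] - p[1])^2 + (pts[same, 2] - p[2])^2
          if (min(d2) < min_sep2) next
        }
      }
      k <- k + 1L
      pts[k, ] <- p
      plane[k] <- pl
    } else {
      if (k > 0L) {
        d2 <- (pts[seq_len(k), 1] - p[1])^2 + (pts[seq_len(k), 2] - p[2])^2 +
          (pts[seq_len(k), 3] - p[3])^2
        if (min(d2) < min_sep2) next
      }
      k <- k + 1L
      pts[k, ] <- p
    }
  }
  if (k < n) {
    stop(sprintf("could only place %d of %d nuclei; sphere too crowded for the requested minimum separation",
                 k, n))
  }
  pts
}

# add a 2-D Gaussian blob in place; r0/c0 in pixel units (1-based, fractional)
add_blob <- function(mat, r0, c0, sigma_px, amplitude) {
  w <- ceiling(3 * sigma_px)
  rr <- max(1L, floor(r0 - w)):min(nrow(mat), ceiling(r0 + w))
  cc <- max(1L, floor(c0 - w)):min(ncol(mat), ceiling(c0 + w))
  if (!length(rr) || !length(cc)) return(mat)
  g <- exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * sigma_px^2))
  mat[rr, cc] <- mat[rr, cc] + amplitude * g
  mat
}

# filament texture: short Gaussian-profile chords inside a disc of radius
# c_px centred at (cr, cc); returns the updated matrix
add_filaments <- function(mat, cr, cc, c_px, density_per_1000um2,
                          pixel_size_um, amplitude) {
  area_um2 <- pi * (c_px * pixel_size_um)^2
  k <- rpois(1L, density_per_1000um2 * area_um2 / 1000)
  if (k == 0L) return(mat)
  for (i in seq_len(k)) {
    # random chord: point inside the disc plus direction and length
    repeat {
      p <- runif(2, -c_px, c_px)
      if (sum(p^2) <= c_px^2) break
    }
    theta <- runif(1, 0, pi)
    len <- runif(1, 0.3, 0.9) * c_px
    t_seq <- seq(-len / 2, len / 2, by = 0.8)
    xs <- cr + p[1] + t_seq * cos(theta)
    ys <- cc + p[2] + t_seq * sin(theta)
    keep <- (xs - cr)^2 + (ys - cc)^2 <= c_px^2
    xs <- xs[keep]; ys <- ys[keep]
    for (j in seq_along(xs)) {
      mat <- add_blob(mat, xs[j], ys[j], 1.2, amplitude)
    }
  }
  mat
}

smooth_noise_field <- function(rows, cols, scale_px, sd_abu) {
  if (sd_abu <= 0) return(matrix(0, rows, cols))
  f <- matrix(rnorm(rows * cols), rows, cols)
  f <- gaussian_blur(f, scale_px)
  s <- sd(as.vector(f))
  if (s == 0) return(matrix(0, rows, cols))
  f * (sd_abu / s)
}

#' Generate a calibrated synthetic organoid stack with ground truth
#'
#' Renders a spherical aggregate: the `nuclear` channel holds one
#' Gaussian-like blob per nucleus, `nuclear-marker` and `cytoplasmic`
#' channels hold blobs only for marker-positive cells (the latter with full
#' tissue background, as abundant cell-body stains light up the whole
#' tissue), `filamentous` channels hold oriented curvilinear texture inside
#' the aggregate cross-section. Signal and haze
#' are attenuated by `exp(-attenuation_per_um * depth)` where depth is
#' measured from the top of the sphere; Gaussian sensor noise is added last
#' and intensities clipped at zero.
#'
#' By default nucleus centres are snapped axially to the nearest confocal
#' plane (`snap_to_planes = TRUE`), reflecting that each optical section
#' resolves a thin slab of the sample; per-plane ground-truth counts are
#' then exact, matching the per-plane-and-sum quantification convention.
#'
#' @param phenotype An [organoid_phenotype()].
#' @param acq An [acquisition_model()].
#' @param channels List of [channel_spec()] to render.
#' @param planes,rows,cols Stack dimensions.
#' @param pixel_size_um,plane_spacing_um Calibration; `plane_spacing_um`
#'   defaults to spreading the planes over the central 75% of the sphere
#'   diameter, so every section crosses enough tissue to be detected.
#' @param snap_to_planes Snap nucleus z to the nearest plane centre.
#' @param signal_gain Multiplier applied to rendered signal and haze (not
#'   noise); used to plant plate-position effects.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with elements `stack` ([image_stack()]) and `truth`
#'   (data frame: nucleus id, position in µm, nearest plane, radial
#'   fraction, plus one logical column per marker channel).
#' @export
generate_organoid_stack <- function(phenotype,
                                    acq = acquisition_model(),
                                    channels = list(channel_spec("DAPI", "nuclear")),
                                    planes = 8L, rows = 160L, cols = 160L,
                                    pixel_size_um = 1,
                                    plane_spacing_um = NULL,
                                    snap_to_planes = TRUE,
                                    signal_gain = 1,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  R <- phenotype$radius_um
  if (is.null(plane_spacing_um)) {
    plane_spacing_um <- if (planes > 1) 1.5 * R / (planes - 1) else R
  }
  rpx <- R / pixel_size_um
  if (2 * rpx > rows || 2 * rpx > cols) {
    stop("sphere exceeds grid: 2*radius is larger than the field of view")
  }
  cr <- (rows + 1) / 2
  cc <- (cols + 1) / 2
  z_centers <- (seq_len(planes) - (planes + 1) / 2) * plane_spacing_um
  # nuclei
  mean_rn <- phenotype$nucleus_radius_um[1]
  pts <- place_nuclei(phenotype$n_nuclei, R,
                      phenotype$min_separation_factor * mean_rn,
                      z_centers_um = if (snap_to_planes) z_centers else NULL)
  n <- nrow(pts)
  nearest_plane <- if (n) {
    vapply(pts[, 3], function(z) which.min(abs(z_centers - z)), 1L)
  } else integer(0)
  if (snap_to_planes && n) pts[, 3] <- z_centers[nearest_plane]
  r_frac <- if (n) pmin(1, sqrt(rowSums(pts^2)) / R) else numeric(0)
  rn <- if (n) pmax(0.5, rnorm(n, mean_rn, phenotype$nucleus_radius_um[2])) else numeric(0)
  brightness <- if (n) exp(rnorm(n, 0, 0.08)) else numeric(0)

  truth <- data.frame(id = seq_len(n),
                      x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                      plane = nearest_plane, r_frac = r_frac)

  # marker labels
  marker_names <- vapply(channels, `[[`, "", "name")
  roles <- vapply(channels, `[[`, "", "role")
  for (i in which(roles %in% c("nuclear-marker", "cytoplasmic"))) {
    nm <- marker_names[i]
    if (nm %in% names(phenotype$zone_fractions)) {
      zf <- phenotype$zone_fractions[[nm]]
      zone <- pmax(1L, ceiling(length(zf) * r_frac))
      p <- zf[zone]
    } else if (!is.null(phenotype$labeled_fraction)) {
      p <- rep(phenotype$labeled_fraction, n)
    } else {
      p <- rep(1, n)
    }
    truth[[nm]] <- if (n) runif(n) < p else logical(0)
  }

  sigma_xy <- rn / (1.7 * pixel_size_um)
  sigma_z <- pmax(mean_rn, 0.2 * plane_spacing_um)
  top_z <- -R
  atten <- exp(-acq$attenuation_per_um * pmax(0, z_centers - top_z))

  vox <- array(0, dim = c(length(channels), planes, rows, cols))
  for (p in seq_len(planes)) {
    zp <- z_centers[p]
    dz2 <- (R^2 - zp^2)
    c_px <- if (dz2 > 0) sqrt(dz2) / pixel_size_um else 0
    haze <- matrix(0, rows, cols)
    tissue <- matrix(0, rows, cols)
    if (c_px > 0) {
      rr <- seq_len(rows); ccol <- seq_len(cols)
      if (acq$haze_amplitude > 0) {
        dome <- exp(-outer((rr - cr)^2, (ccol - cc)^2, "+") /
                      (2 * (0.7 * rpx)^2))
        haze <- acq$haze_amplitude * dome +
          smooth_noise_field(rows, cols, acq$haze_scale_um / pixel_size_um,
                             acq$haze_amplitude / 5)
        haze[haze < 0] <- 0
      }
      if (acq$tissue_background_abu > 0) {
        # diffuse stained-tissue level with a soft edge at the cross-section
        dd <- sqrt(outer((rr - cr)^2, (ccol - cc)^2, "+"))
        tissue <- acq$tissue_background_abu / (1 + exp((dd - c_px) / 2))
      }
    }
    for (ci in seq_along(channels)) {
      m <- matrix(0, rows, cols)
      role <- roles[ci]
      if (role %in% c("nuclear", "nuclear-marker", "cytoplasmic") && n) {
        lab <- if (role == "nuclear") rep(TRUE, n) else truth[[marker_names[ci]]]
        zfac <- exp(-(pts[, 3] - zp)^2 / (2 * sigma_z^2))
        sel <- which(lab & zfac > 0.05)
        for (k in sel) {
          m <- add_blob(m,
                        cr + pts[k, 2] / pixel_size_um,
                        cc + pts[k, 1] / pixel_size_um,
                        sigma_xy[k],
                        acq$abu_per_fluorophore * brightness[k] * zfac[k])
        }
      } else if (role == "filamentous" && c_px > 1) {
        dens <- phenotype$filament_density[[marker_names[ci]]]
        if (is.null(dens)) dens <- 0
        if (dens > 0) {
          m <- add_filaments(m, cr, cc, c_px, dens, pixel_size_um,
                             0.5 * acq$abu_per_fluorophore)
        }
      }
      tfac <- if (role == "nuclear-marker") acq$marker_tissue_factor else 1
      plane_img <- signal_gain * atten[p] * (m + haze + tfac * tissue)
      if (acq$noise_sd > 0) {
        plane_img <- plane_img + rnorm(rows * cols, 0, acq$noise_sd)
      }
      plane_img[plane_img < 0] <- 0
      vox[ci, p, , ] <- plane_img
    }
  }
  list(stack = image_stack(vox, pixel_size_um, plane_spacing_um, channels),
       truth = truth)
}

#' Generate a 2-D plane of well-separated nuclear blobs with ground truth
#'
#' Convenience generator for validating plane-level operations (background
#' correction, segmentation) against exact centres without 3D sectioning
#' effects. Optionally adds a smooth haze dome underneath.
#'
#' @param n Number of blobs.
#' @param rows,cols Plane dimensions in pixels.
#' @param amplitude Peak blob intensity (abu).
#' @param sigma_px Blob Gaussian sigma in pixels.
#' @param noise_sd Additive Gaussian noise sd (abu).
#' @param haze_amplitude Peak of a smooth background dome (abu).
#' @param min_sep_px Minimum centre distance in pixels.
#' @param margin_px Keep centres at least this far from the border.
#' @param seed Optional integer seed.
#' @return List: `plane` (matrix), `centers` (n x 2 matrix, row/col),
#'   `amplitude`, `sigma_px`.
#' @export
generate_blob_plane <- function(n, rows = 512L, cols = 512L,
                                amplitude = 150, sigma_px = 1.8,
                                noise_sd = 5, haze_amplitude = 0,
                                min_sep_px = 10, margin_px = 8,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(NA_real_, n, 2)
  k <- 0L; tries <- 0L
  while (k < n && tries < 200L * max(n, 1L)) {
    tries <- tries + 1L
    p <- c(runif(1, margin_px, rows - margin_px),
           runif(1, margin_px, cols - margin_px))
    if (k > 0L) {
      d2 <- (centers[seq_len(k), 1] - p[1])^2 + (centers[seq_len(k), 2] - p[2])^2
      if (min(d2) < min_sep_px^2) next
    }
    k <- k + 1L
    centers[k, ] <- p
  }
  if (k < n) stop("plane too crowded for the requested minimum separation")
  m <- matrix(0, rows, cols)
  if (haze_amplitude > 0) {
    rr <- seq_len(rows); ccol <- seq_len(cols)
    m <- m + haze_amplitude *
      exp(-outer((rr - (rows + 1) / 2)^2, (ccol - (cols + 1) / 2)^2, "+") /
            (2 * (0.5 * max(rows, cols))^2))
  }
  for (i in seq_len(n)) {
    m <- add_blob(m, centers[i, 1], centers[i, 2], sigma_px, amplitude)
  }
  if (noise_sd > 0) m <- m + rnorm(rows * cols, 0, noise_sd)
  m[m < 0] <- 0
  list(plane = m, centers = centers[seq_len(n), , drop = FALSE],
       amplitude = amplitude, sigma_px = sigma_px)
}

#' Generate a dilution-series plate of labeled-cell aggregates
#'
#' One aggregate per labeled fraction per replicate; each nucleus carries
#' the tracker label with probability equal to the requested fraction
#' (binomial realization, recorded in the ground truth). Mirrors mixing
#' dye-labeled cells into unlabeled carrier cells at known percentages
#' before aggregation.
#'
#' @param fractions Labeled fractions in \[0, 1\]; the workflow's standard
#'   series is `c(0.0125, 0.025, 0.05, 0.1, 0.2, 0.4)`.
#' @param n_cells Nuclei per aggregate.
#' @param n_replicates Replicates per fraction.
#' @param acq An [acquisition_model()].
#' @param radius_um,planes,rows,cols,pixel_size_um,plane_spacing_um Geometry
#'   passed to [generate_organoid_stack()].
#' @param tracker_name Name of the tracker marker channel.
#' @param seed Optional integer seed.
#' @return List of wells; each well is a list with `well_id`, `fraction`,
#'   `replicate`, `stack`, `truth`, `n_labeled`.
#' @export
generate_dilution_series <- function(fractions = c(0.0125, 0.025, 0.05, 0.1, 0.2, 0.4),
                                     n_cells = 1000L,
                                     n_replicates = 3L,
                                     acq = acquisition_model(),
                                     radius_um = 60,
                                     planes = 6L, rows = 160L, cols = 160L,
                                     pixel_size_um = 1,
                                     plane_spacing_um = NULL,
                                     tracker_name = "tracker",
                                     seed = NULL) {
  if (!length(fractions)) stop("empty fraction list")
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  if (!is.null(seed)) set.seed(seed)
  layout <- plate_layout()
  ids <- well_ids(layout)
  chans <- list(channel_spec("DAPI", "nuclear"),
                channel_spec(tracker_name, "nuclear-marker"))
  wells <- list()
  w <- 0L
  for (rep_i in seq_len(n_replicates)) {
    for (f in fractions) {
      w <- w + 1L
      ph <- organoid_phenotype(radius_um = radius_um, n_nuclei = n_cells,
                               labeled_fraction = f)
      g <- generate_organoid_stack(ph, acq, chans,
                                   planes = planes, rows = rows, cols = cols,
                                   pixel_size_um = pixel_size_um,
                                   plane_spacing_um = plane_spacing_um)
      wells[[w]] <- list(well_id = ids[w], fraction = f, replicate = rep_i,
                         stack = g$stack, truth = g$truth,
                         n_labeled = sum(g$truth[[tracker_name]]))
    }
  }
  wells
}

#' Generate a toxin dose-response plate with subpopulation ablation
#'
#' Plants dose-dependent loss of marker-positive cells: at each dose the
#' surviving count for a marker is a binomial draw from the control count
#' with survival probability `1 - kill(dose)`. Kill curves must be monotone
#' non-decreasing in dose unless explicitly overridden.
#'
#' @param doses Ordered dose levels (0 = vehicle control first).
#' @param ablation_curve Named list of functions, one per marker, mapping a
#'   dose to a kill fraction in \[0, 1\].
#' @param base_counts Named integer vector: control cell count per marker.
#' @param n_replicates Wells per dose.
#' @param acq An [acquisition_model()].
#' @param radius_um,planes,rows,cols,pixel_size_um,plane_spacing_um Geometry.
#' @param cell_radius_um Soma-scale blob radius for the marker channels.
#' @param allow_non_monotone Skip the monotonicity check.
#' @param seed Optional integer seed.
#' @return List with `wells` (each: `well_id`, `dose`, `replicate`, `stack`)
#'   and `truth` (data frame: well, dose, replicate, marker, planted and
#'   surviving counts, kill fraction).
#' @export
generate_toxin_plate <- function(doses = c(0, 50, 100, 250, 500),
                                 ablation_curve,
                                 base_counts = c(TH = 100L, Map2 = 100L),
                                 n_replicates = 2L,
                                 acq = acquisition_model(),
                                 radius_um = 55,
                                 planes = 3L, rows = 144L, cols = 144L,
                                 pixel_size_um = 1,
                                 plane_spacing_um = NULL,
                                 cell_radius_um = 4,
                                 allow_non_monotone = FALSE,
                                 seed = NULL) {
  stopifnot(is.list(ablation_curve), length(ablation_curve) >= 1)
  markers <- names(ablation_curve)
  stopifnot(all(markers %in% names(base_counts)))
  for (m in markers) {
    kf <- vapply(sort(doses), ablation_curve[[m]], 0)
    if (any(kf < 0) || any(kf > 1)) stop("kill fractions must lie in [0, 1]")
    if (!allow_non_monotone && any(diff(kf) < -1e-9)) {
      stop("ablation curve for ", m,
           " is not monotone non-decreasing in dose; ",
           "set allow_non_monotone = TRUE to override")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- well_ids(plate_layout())
  wells <- list()
  truth <- NULL
  w <- 0L
  for (rep_i in seq_len(n_replicates)) {
    for (d in doses) {
      w <- w + 1L
      vox <- NULL
      chans <- list()
      for (mi in seq_along(markers)) {
        m <- markers[mi]
        kill <- ablation_curve[[m]](d)
        n_surv <- rbinom(1L, base_counts[[m]], 1 - kill)
        ph <- organoid_phenotype(radius_um = radius_um, n_nuclei = n_surv,
                                 nucleus_radius_um = c(cell_radius_um,
                                                       0.1 * cell_radius_um),
                                 min_separation_factor = 2)
        # haze/noise rendered once (first marker) to avoid double-counting
        acq_i <- acq
        if (mi > 1L) { acq_i$haze_amplitude <- 0; acq_i$noise_sd <- 0 }
        g <- generate_organoid_stack(ph, acq_i,
                                     list(channel_spec(m, "cytoplasmic")),
                                     planes = planes, rows = rows, cols = cols,
                                     pixel_size_um = pixel_size_um,
                                     plane_spacing_um = if (is.null(plane_spacing_um))
                                       radius_um / max(2, planes - 1) else plane_spacing_um)
        chans[[mi]] <- channel_spec(m, "nuclear-marker")
        v <- g$stack$voxels
        if (is.null(vox)) {
          vox <- array(0, dim = c(length(markers), dim(v)[2], dim(v)[3], dim(v)[4]))
          spacing <- g$stack$plane_spacing_um
        }
        vox[mi, , , ] <- v[1, , , ]
        truth <- rbind(truth, data.frame(
          well_id = ids[w], dose = d, replicate = rep_i, marker = m,
          n_planted = base_counts[[m]], kill_fraction = kill,
          n_surviving = n_surv))
      }
      wells[[w]] <- list(well_id = ids[w], dose = d, replicate = rep_i,
                         stack = image_stack(vox, pixel_size_um, spacing, chans))
    }
  }
  list(wells = wells, truth = truth)
}

#' Four-parameter logistic kill curve helper
#'
#' Returns `function(dose)` giving `max_kill / (1 + (ec50/dose)^hill)`
#' (0 at dose 0), a monotone kill fraction for [generate_toxin_plate()].
#'
#' @param ec50 Dose of half-maximal kill.
#' @param hill Hill slope (> 0).
#' @param max_kill Asymptotic kill fraction in \[0, 1\].
#' @export
ablation_curve_4pl <- function(ec50, hill = 1.5, max_kill = 0.9) {
  stopifnot(ec50 > 0, hill > 0, max_kill >= 0, max_kill <= 1)
  function(dose) {
    ifelse(dose <= 0, 0, max_kill / (1 + (ec50 / dose)^hill))
  }
}

#' Generate a plate with a planted plate-position (edge) effect
#'
#' Renders small aggregates in a subset of edge and inside wells of a
#' 96-well layout; inside wells have their rendered signal scaled by
#' `1 - center_reduction` in all channels, emulating a reduced-brightness
#' centre for a filamentous marker.
#'
#' @param n_edge,n_inside Number of wells rendered per position class.
#' @param center_reduction Fractional signal reduction for inside wells
#'   (0.10 plants a 10 percent effect; 0 gives a null plate).
#' @param marker Filamentous marker channel name.
#' @param filament_density Segments per 1000 µm² of cross-section.
#' @param acq An [acquisition_model()].
#' @param radius_um,planes,rows,cols Geometry.
#' @param layout Plate layout used to pick well ids.
#' @param seed Optional integer seed.
#' @return List of wells; each: `well_id`, `position_class`, `stack`.
#' @export
generate_edge_effect_plate <- function(n_edge = 10L, n_inside = 10L,
                                       center_reduction = 0.10,
                                       marker = "Map2",
                                       filament_density = 8,
                                       acq = acquisition_model(),
                                       radius_um = 40,
                                       planes = 2L, rows = 112L, cols = 112L,
                                       layout = plate_layout(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- well_ids(layout)
  cls <- vapply(ids, classify_well_position, "", layout = layout)
  pick <- function(class, k) {
    cand <- ids[cls == class]
    cand[round(seq(1, length(cand), length.out = k))]
  }
  chosen <- c(pick("edge", n_edge), pick("inside", n_inside))
  fd <- setNames(filament_density, marker)
  chans <- list(channel_spec("DAPI", "nuclear"),
                channel_spec(marker, "filamentous"))
  lapply(chosen, function(id) {
    pc <- cls[[id]]
    gain <- if (pc == "inside") 1 - center_reduction else 1
    ph <- organoid_phenotype(radius_um = radius_um, n_nuclei = 120L,
                             filament_density = fd)
    g <- generate_organoid_stack(ph, acq, chans,
                                 planes = planes, rows = rows, cols = cols,
                                 plane_spacing_um = 0.5 * radius_um,
                                 signal_gain = gain)
    list(well_id = id, position_class = pc, stack = g$stack)
  })
}

#' Plant a dust artifact into a stack
#'
#' Dust: a small, compact, very bright blob off (or partially over) the
#' aggregate, in all channels. Used as a positive control for QC.
#'
#' @param stack An [image_stack()].
#' @param plane Plane index to contaminate.
#' @param center_px Length-2 (row, col); default upper-left quadrant corner.
#' @param radius_px Dust radius in pixels.
#' @param amplitude Peak abu; default 3x the current stack maximum.
#' @return The modified stack; planted artifacts are recorded in
#'   `attr(stack, "artifacts")`.
#' @export
plant_dust <- function(stack, plane = 1L, center_px = NULL, radius_px = 4,
                       amplitude = NULL) {
  d <- dim(stack$voxels)
  if (is.null(center_px)) center_px <- c(round(d[3] * 0.12), round(d[4] * 0.12))
  if (is.null(amplitude)) amplitude <- 3 * max(stack$voxels)
  for (ch in seq_len(d[1])) {
    m <- stack$voxels[ch, plane, , ]
    m <- add_blob(m, center_px[1], center_px[2], radius_px / 1.5, amplitude)
    stack$voxels[ch, plane, , ] <- m
  }
  rec <- data.frame(kind = "dust", plane = plane,
                    row = center_px[1], col = center_px[2],
                    amplitude = amplitude)
  attr(stack, "artifacts") <- rbind(attr(stack, "artifacts"), rec)
  stack
}

#' Plant a fiber artifact into a stack
#'
#' Fiber: a long, thin, bright streak across part of the field, in all
#' channels; high eccentricity and low roundness.
#'
#' @param stack An [image_stack()].
#' @param plane Plane index.
#' @param from_px,to_px Endpoints (row, col); default a streak across the
#'   upper part of the field.
#' @param width_px Streak Gaussian width.
#' @param amplitude Peak abu; default 3x the current stack maximum.
#' @return The modified stack (artifact recorded as for [plant_dust()]).
#' @export
plant_fiber <- function(stack, plane = 1L, from_px = NULL, to_px = NULL,
                        width_px = 1.5, amplitude = NULL) {
  d <- dim(stack$voxels)
  if (is.null(from_px)) from_px <- c(round(d[3] * 0.08), round(d[4] * 0.05))
  if (is.null(to_px)) to_px <- c(round(d[3] * 0.16), round(d[4] * 0.85))
  if (is.null(amplitude)) amplitude <- 3 * max(stack$voxels)
  n_steps <- ceiling(sqrt(sum((to_px - from_px)^2)) / 0.7)
  for (ch in seq_len(d[1])) {
    m <- stack$voxels[ch, plane, , ]
    for (t in seq(0, 1, length.out = n_steps)) {
      p <- from_px + t * (to_px - from_px)
      m <- add_blob(m, p[1], p[2], width_px, amplitude)
    }
    stack$voxels[ch, plane, , ] <- m
  }
  rec <- data.frame(kind = "fiber", plane = plane,
                    row = from_px[1], col = from_px[2], amplitude = amplitude)
  attr(stack, "artifacts") <- rbind(attr(stack, "artifacts"), rec)
  stack
}
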