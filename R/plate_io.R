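# Data model for plates, wells, channels and calibrated image stacks,
# plus TIFF and CSV readers/writers.

CHANNEL_ROLES <- c("nuclear", "nuclear-marker", "filamentous",
                   "cytoplasmic", "brightfield")

#' Channel specification
#'
#' Describes one fluorescence (or brightfield) channel of an acquisition by
#' a free-text name (e.g. `"DAPI"`, `"Sox2-488"`) and a functional role drawn
#' from a closed set. The role, not the wavelength, decides how the channel
#' is quantified downstream: `nuclear` channels count all nuclei,
#' `nuclear-marker` channels count marker-positive nuclei, `filamentous`
#' channels are quantified by aggregate-masked mean intensity.
#'
#' @param name Character scalar; unique within a stack.
#' @param role One of `"nuclear"`, `"nuclear-marker"`, `"filamentous"`,
#'   `"cytoplasmic"`, `"brightfield"`.
#' @return An object of class `channel_spec`.
#' @export
#' @examples
#' channel_spec("Sox2-488", "nuclear-marker")
channel_spec <- function(name, role) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, CHANNEL_ROLES)
  structure(list(name = name, role = role), class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel '%s' (%s)>\n", x$name, x$role))
  invisible(x)
}

#' Calibrated multi-channel confocal image stack
#'
#' A per-well, per-field 3D intensity grid in arbitrary brightness units
#' (abu), indexed `(channel, plane, row, column)`, together with the lateral
#' pixel size and the axial inter-plane spacing in micrometres.
#'
#' @param voxels Numeric array, either `(channel, plane, row, col)` or
#'   `(plane, row, col)` for a single channel. All intensities must be >= 0.
#' @param pixel_size_um Lateral calibration, µm per pixel (> 0).
#' @param plane_spacing_um Axial spacing between plane centres, µm (> 0).
#' @param channels List of [channel_spec()] objects, one per first-axis slot.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(voxels, pixel_size_um, plane_spacing_um, channels) {
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  if (length(dim(voxels)) == 3L) {
    dim(voxels) <- c(1L, dim(voxels))
  }
  stopifnot(length(dim(voxels)) == 4L)
  if (any(voxels < 0)) stop("all intensities must be >= 0")
  stopifnot(pixel_size_um > 0, plane_spacing_um > 0)
  if (dim(voxels)[1] != length(channels)) {
    stop("channel count (", length(channels),
         ") does not equal first-axis extent (", dim(voxels)[1], ")")
  }
  nm <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("channel names must be unique within a stack")
  structure(list(voxels = voxels,
                 pixel_size_um = pixel_size_um,
                 plane_spacing_um = plane_spacing_um,
                 channels = channels),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ImageStack %d channel(s) x %d plane(s) x %d x %d px, %.3g um/px, %.3g um/plane>\n",
              d[1], d[2], d[3], d[4], x$pixel_size_um, x$plane_spacing_um))
  cat(" channels:", paste(channel_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname image_stack
#' @param stack An `ImageStack`.
#' @export
channel_names <- function(stack) {
  vapply(stack$channels, `[[`, "", "name")
}

#' @rdname image_stack
#' @export
n_planes <- function(stack) dim(stack$voxels)[2]

#' @rdname image_stack
#' @export
n_channels <- function(stack) dim(stack$voxels)[1]

channel_index <- function(stack, channel) {
  i <- match(channel, channel_names(stack))
  if (is.na(i)) stop("unknown channel name: ", channel)
  i
}

#' Extract one image plane of one channel
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param plane 1-based plane index.
#' @return Numeric matrix `(row, col)`.
#' @export
get_plane <- function(stack, channel, plane) {
  i <- channel_index(stack, channel)
  stopifnot(plane >= 1L, plane <= n_planes(stack))
  stack$voxels[i, plane, , ]
}

#' Axial span of a z-stack
#'
#' Distance between the first and last plane centres,
#' `(n_planes - 1) * plane_spacing_um`. A 16-plane stack at 36.6 µm spacing
#' spans 549 µm.
#'
#' @param stack An [image_stack()].
#' @return Span in micrometres.
#' @export
stack_axial_span_um <- function(stack) {
  (n_planes(stack) - 1) * stack$plane_spacing_um
}

# Intensities are stored as 16-bit TIFF samples; abu values are rounded to
# integers and clamped to [0, 65535] on write, so read(write(x)) is the
# identity on integer-valued stacks within that range.
TIFF_MAX <- 65535

#' Write an image stack as a multi-page TIFF
#'
#' Pages are plane-major: for each plane, one page per channel in stack
#' order (page index `(plane - 1) * n_channels + channel`). Intensities are
#' rounded to integer abu and stored as 16-bit samples.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (p in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      m <- round(stack$voxels[ch, p, , ])
      m[m > TIFF_MAX] <- TIFF_MAX
      m[m < 0] <- 0
      pages[[k]] <- m / TIFF_MAX
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF into a calibrated image stack
#'
#' The file layout (plane-major pages, channel order) is declared by the
#' caller/config, not inferred from vendor metadata. The page count must
#' equal `n_planes * length(channels)`.
#'
#' @param path TIFF file written by [write_stack()] or equivalent layout.
#' @param calibration List with `pixel_size_um` and `plane_spacing_um`.
#' @param channels List of [channel_spec()] in page order within a plane.
#' @param n_planes Declared number of confocal planes.
#' @return An [image_stack()]; intensities in integer abu.
#' @export
read_stack <- function(path, calibration, channels, n_planes) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channels)
  if (length(pages) != nc * n_planes) {
    stop(sprintf("page count mismatch: file has %d pages, config declares %d planes x %d channels",
                 length(pages), n_planes, nc))
  }
  d <- dim(pages[[1]])
  vox <- array(0, dim = c(nc, n_planes, d[1], d[2]))
  k <- 1L
  for (p in seq_len(n_planes)) {
    for (ch in seq_len(nc)) {
      vox[ch, p, , ] <- round(pages[[k]] * TIFF_MAX)
      k <- k + 1L
    }
  }
  image_stack(vox, calibration$pixel_size_um, calibration$plane_spacing_um,
              channels)
}

#' Multiwell plate layout
#'
#' @param rows,columns Plate dimensions (default 8 x 12, a 96-well plate).
#' @param annotations Optional data frame with a `well_id` column plus
#'   arbitrary per-well annotation columns (condition, dose, replicate, ...).
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(rows = 8L, columns = 12L, annotations = NULL) {
  stopifnot(rows >= 1L, columns <= 99L, columns >= 1L, rows <= 26L)
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations), "well_id" %in% names(annotations))
    ids <- well_ids(structure(list(rows = rows, columns = columns),
                              class = "plate_layout"))
    bad <- setdiff(annotations$well_id, ids)
    if (length(bad)) stop("annotations reference non-existent wells: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(rows = as.integer(rows), columns = as.integer(columns),
                 annotations = annotations),
            class = "plate_layout")
}

#' @rdname plate_layout
#' @param layout A `plate_layout`.
#' @export
well_ids <- function(layout) {
  as.vector(t(outer(LETTERS[seq_len(layout$rows)],
                    seq_len(layout$columns), paste0)))
}

parse_well_id <- function(well_id, layout) {
  if (!grepl("^[A-Z][0-9]{1,2}$", well_id)) stop("invalid well id: ", well_id)
  r <- match(substr(well_id, 1, 1), LETTERS)
  c <- as.integer(substring(well_id, 2))
  if (is.na(r) || r > layout$rows || c < 1L || c > layout$columns) {
    stop("invalid well id for this layout: ", well_id)
  }
  c(row = r, col = c)
}

#' Classify a well as edge or inside
#'
#' Wells in the outermost ring (first/last row or first/last column) are
#' `"edge"`; all others `"inside"`. On a 96-well plate this yields 36 edge
#' and 60 inside wells. Edge wells often show systematically different
#' readouts (evaporation, temperature gradients), so plate analytics compare
#' the two classes.
#'
#' @param well_id Well id such as `"A1"` or `"H12"`.
#' @param layout A [plate_layout()].
#' @return `"edge"` or `"inside"`.
#' @export
classify_well_position <- function(well_id, layout = plate_layout()) {
  rc <- parse_well_id(well_id, layout)
  if (rc["row"] == 1L || rc["row"] == layout$rows ||
      rc["col"] == 1L || rc["col"] == layout$columns) "edge" else "inside"
}

#' Write per-well result records to CSV
#'
#' One row per well per marker. Numeric columns are serialized with full
#' (17 significant digit) precision so that [read_results()] reproduces the
#' values exactly; an empty record set produces a header-only file.
#'
#' @param records Data frame of well summaries (see [summary_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      v <- df[[j]]
      if (all(v %in% c("TRUE", "FALSE", NA))) {
        df[[j]] <- as.logical(v)
      } else if (length(v) && !anyNA(suppressWarnings(as.numeric(v[!is.na(v)])))) {
        df[[j]] <- as.numeric(v)
      }
    }
  }
  df
}
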