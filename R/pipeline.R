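# Orchestration: config-driven end-to-end runs (simulate -> quantify ->
# validate) with provenance, QC bookkeeping and retention reporting.

#' Read and validate a run configuration
#'
#' YAML with the sections used by the `run_*` drivers: `seed`,
#' `calibration` (`pixel_size_um`, `plane_spacing_um`), `channels` (list of
#' `{name, role}`), optional `simulate`, `quantify`, `detection`,
#' `background` blocks. Validation happens before any work.
#'
#' @param path YAML file path.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  cfg$config_path <- path
  cfg
}

#' @rdname read_run_config
#' @param cfg Config list.
#' @export
validate_run_config <- function(cfg) {
  req <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  req(is.list(cfg), "not a mapping")
  req(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a number")
  req(is.list(cfg$calibration) &&
        is.numeric(cfg$calibration$pixel_size_um) &&
        cfg$calibration$pixel_size_um > 0 &&
        is.numeric(cfg$calibration$plane_spacing_um) &&
        cfg$calibration$plane_spacing_um > 0,
      "calibration needs positive pixel_size_um and plane_spacing_um")
  req(is.list(cfg$channels) && length(cfg$channels) >= 1,
      "channels must be a non-empty list")
  for (ch in cfg$channels) {
    req(is.character(ch$name) && nzchar(ch$name), "channel without name")
    req(is.character(ch$role) && ch$role %in% CHANNEL_ROLES,
        paste0("channel role must be one of: ",
               paste(CHANNEL_ROLES, collapse = ", ")))
  }
  invisible(TRUE)
}

config_channels <- function(cfg) {
  lapply(cfg$channels, function(ch) channel_spec(ch$name, ch$role))
}

config_gate <- function(g) {
  if (is.character(g)) return(gate_preset(g))
  gate_spec(min_area_um2 = if (is.null(g$min_area_um2)) 0 else g$min_area_um2,
            max_area_um2 = g$max_area_um2,
            min_brightness_abu = if (is.null(g$min_brightness_abu)) 0 else g$min_brightness_abu,
            max_brightness_abu = g$max_brightness_abu)
}

write_provenance <- function(cfg, out_dir, extra = list()) {
  prov <- c(list(
    config_md5 = if (!is.null(cfg$config_path))
      unname(tools::md5sum(cfg$config_path)) else NA_character_,
    seed = cfg$seed,
    package = "organoidhcs",
    package_version = as.character(packageVersion("organoidhcs")),
    r_version = R.version.string), extra)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a synthetic plate to disk
#'
#' Writes one multi-page TIFF per well (via [write_stack()]), a
#' ground-truth CSV, a plate manifest (YAML) and a provenance record.
#' Driven by the config's `simulate` block: currently a dilution-series
#' plate (`kind: dilution`), with optional planted dust wells
#' (`n_dust_wells`) as QC positive controls. Seed-deterministic.
#'
#' @param cfg Config list from [read_run_config()] (or equivalent).
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_simulate <- function(cfg, out_dir = cfg$output_dir) {
  validate_run_config(cfg)
  sim <- cfg$simulate
  if (is.null(sim)) stop("config has no simulate block")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  cal <- cfg$calibration
  wells <- generate_dilution_series(
    fractions = if (is.null(sim$fractions))
      c(0.0125, 0.025, 0.05, 0.1, 0.2, 0.4) else unlist(sim$fractions),
    n_cells = if (is.null(sim$n_cells)) 600L else sim$n_cells,
    n_replicates = if (is.null(sim$n_replicates)) 2L else sim$n_replicates,
    radius_um = if (is.null(sim$radius_um)) 55 else sim$radius_um,
    planes = if (is.null(sim$planes)) 5L else sim$planes,
    rows = if (is.null(sim$rows)) 144L else sim$rows,
    cols = if (is.null(sim$cols)) 144L else sim$cols,
    pixel_size_um = cal$pixel_size_um,
    plane_spacing_um = cal$plane_spacing_um)
  n_dust <- if (is.null(sim$n_dust_wells)) 0L else sim$n_dust_wells
  dust_ids <- character(0)
  if (n_dust > 0L) {
    pick <- round(seq(1, length(wells), length.out = n_dust))
    for (k in pick) wells[[k]]$stack <- plant_dust(wells[[k]]$stack)
    dust_ids <- vapply(wells[pick], `[[`, "", "well_id")
  }
  truth_rows <- NULL
  manifest_wells <- list()
  for (w in wells) {
    fn <- paste0(w$well_id, ".tif")
    write_stack(w$stack, file.path(out_dir, fn))
    manifest_wells[[length(manifest_wells) + 1L]] <-
      list(well_id = w$well_id, file = fn, fraction = w$fraction,
           replicate = w$replicate, dust = w$well_id %in% dust_ids)
    truth_rows <- rbind(truth_rows, data.frame(
      well_id = w$well_id, fraction = w$fraction, replicate = w$replicate,
      n_nuclei = nrow(w$truth), n_labeled = w$n_labeled))
  }
  manifest <- list(
    kind = "dilution",
    calibration = cal,
    channels = lapply(cfg$channels, function(ch) ch[c("name", "role")]),
    n_planes = if (is.null(sim$planes)) 5L else sim$planes,
    wells = manifest_wells)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  write_results(truth_rows, file.path(out_dir, "ground_truth.csv"))
  write_provenance(cfg, out_dir, list(step = "simulate"))
  invisible(manifest)
}

#' Quantify a plate end to end
#'
#' Loads the plate manifest, and for each well: reads the stack, runs QC,
#' and quantifies each configured marker (nuclear markers through
#' detect/correct/segment/gate, filamentous markers through masked mean
#' intensity). Writes `well_summaries.csv`, `batch_stats.csv`,
#' `qc_report.csv` (rejected wells with reasons), a retention line
#' (fraction of wells passing QC) and a provenance record. Per-well
#' failures are logged and skipped; the run continues.
#'
#' @param cfg Config list; its `quantify$markers` block lists
#'   `{name, kind (nuclear|cells|filamentous), gate (preset name or
#'   window), background {method, curvature, width_px}}`.
#' @param input_dir Directory holding `manifest.yaml` and the stacks.
#' @param out_dir Output directory.
#' @return Data frame of well summaries, invisibly.
#' @export
run_quantify <- function(cfg, input_dir, out_dir = cfg$output_dir) {
  validate_run_config(cfg)
  qcfg <- cfg$quantify
  if (is.null(qcfg) || is.null(qcfg$markers)) {
    stop("config has no quantify$markers block")
  }
  manifest <- yaml::read_yaml(file.path(input_dir, "manifest.yaml"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  chans <- config_channels(cfg)
  layout <- plate_layout()
  dparams <- do.call(detect_params, if (is.null(cfg$detection)) list()
                     else cfg$detection)
  summaries <- list()
  qc_rows <- NULL
  log_lines <- character(0)
  n_total <- length(manifest$wells)
  n_pass <- 0L
  for (winfo in manifest$wells) {
    wid <- winfo$well_id
    res <- tryCatch({
      st <- read_stack(file.path(input_dir, winfo$file),
                       manifest$calibration, chans, manifest$n_planes)
      dets <- detect_aggregate_stack(st, params = dparams)
      qc <- qc_classify(st, dets, well_id = wid)
      pos <- classify_well_position(wid, layout)
      if (qc$pass) {
        for (mk in qcfg$markers) {
          bg <- if (is.null(mk$background)) list(method = "parabola", curvature = 2)
                else mk$background
          s <- if (identical(mk$kind, "filamentous")) {
            quantify_filamentous_marker(st, mk$name, well_id = wid,
                                        detect_parameters = dparams,
                                        qc = qc, position_class = pos)
          } else {
            quantify_nuclear_marker(
              st, mk$name, gate = config_gate(mk$gate), well_id = wid,
              background = bg,
              segment = if (identical(mk$kind, "cells")) "cells" else "nuclei",
              detect_parameters = dparams, qc = qc, position_class = pos)
          }
          summaries[[length(summaries) + 1L]] <- s
        }
        n_pass <- n_pass + 1L
      }
      qc
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines, sprintf("well %s: ERROR %s", wid,
                                        conditionMessage(res)))
      qc_rows <- rbind(qc_rows, data.frame(well_id = wid, qc_pass = FALSE,
                                           reasons = "processing_error"))
    } else {
      log_lines <- c(log_lines,
                     sprintf("well %s: %s%s", wid,
                             if (res$pass) "PASS" else "FAIL",
                             if (length(res$reasons))
                               paste0(" (", paste(res$reasons, collapse = ","), ")")
                             else ""))
      qc_rows <- rbind(qc_rows, data.frame(
        well_id = wid, qc_pass = res$pass,
        reasons = paste(res$reasons, collapse = ";")))
    }
  }
  tbl <- if (length(summaries)) summary_table(summaries) else
    summary_table(list())
  write_results(tbl, file.path(out_dir, "well_summaries.csv"))
  write_results(qc_rows, file.path(out_dir, "qc_report.csv"))
  if (length(summaries)) {
    batch <- do.call(rbind, lapply(split(tbl, tbl$marker), function(g) {
      metric <- if (all(is.na(g$filament_intensity_abu)))
        g$total_brightness_abu else g$filament_intensity_abu
      if (length(metric) >= 2 && mean(metric) != 0) {
        b <- batch_cv(metric)
        data.frame(marker = g$marker[1], mean = b$mean, sd = b$sd,
                   cv = b$cv, n = b$n)
      } else NULL
    }))
    if (!is.null(batch)) {
      write_results(batch, file.path(out_dir, "batch_stats.csv"))
    }
  }
  retention <- data.frame(stage = "imaging_qc", n_total = n_total,
                          n_retained = n_pass,
                          retention_pct = 100 * n_pass / max(1, n_total))
  write_results(retention, file.path(out_dir, "retention.csv"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  write_provenance(cfg, out_dir, list(step = "quantify"))
  invisible(tbl)
}

#' Validate dilution-series linearity from a quantified plate
#'
#' Joins the well summaries produced by [run_quantify()] with the labeled
#' fractions from the plate manifest and regresses the summed labeled
#' brightness on the fraction; reports slope, intercept, R² and a PASS
#' flag at the configured threshold (default R² >= 0.99).
#'
#' @param cfg Config list; `cfg$linearity$marker` names the tracker
#'   channel, `cfg$linearity$r2_threshold` overrides the default.
#' @param input_dir Directory with `manifest.yaml`.
#' @param out_dir Directory with `well_summaries.csv`; the report JSON is
#'   written here.
#' @return The linearity report list, invisibly.
#' @export
run_validate_linearity <- function(cfg, input_dir, out_dir = cfg$output_dir) {
  manifest <- yaml::read_yaml(file.path(input_dir, "manifest.yaml"))
  ann <- do.call(rbind, lapply(manifest$wells, function(w) {
    data.frame(well_id = w$well_id,
               fraction = if (is.null(w$fraction)) NA_real_ else w$fraction)
  }))
  if (all(is.na(ann$fraction))) stop("manifest has no dilution annotations")
  tbl <- read_results(file.path(out_dir, "well_summaries.csv"))
  marker <- if (!is.null(cfg$linearity$marker)) cfg$linearity$marker else "tracker"
  thr <- if (!is.null(cfg$linearity$r2_threshold)) cfg$linearity$r2_threshold else 0.99
  sub <- merge(tbl[tbl$marker == marker, ], ann, by = "well_id")
  fit <- dilution_linearity(sub$fraction, sub$total_brightness_abu)
  report <- list(marker = marker, slope = fit$slope,
                 intercept = fit$intercept, r_squared = fit$r_squared,
                 n_wells = fit$n, r2_threshold = thr,
                 pass = fit$r_squared >= thr)
  jsonlite::write_json(report, file.path(out_dir, "linearity_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
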