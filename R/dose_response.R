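# Subpopulation-specific toxicity analysis: normalization of per-marker
# quantities to vehicle control across a dose series, specificity ratios
# and four-parameter logistic fitting.

#' Normalize per-marker metrics to vehicle control
#'
#' For every marker the per-well metric is first normalized to the organoid
#' area (when `area_um2` is supplied) and then divided by the mean of the
#' dose-0 (vehicle) wells, so the control replicates average to exactly 1.
#' The normalization is invariant to global intensity gain.
#'
#' @param df Data frame with columns `marker`, `dose`, `value`, optional
#'   `area_um2` and `replicate`.
#' @return A `dose_series` data frame: `marker`, `dose`, `replicate`,
#'   `normalized`.
#' @export
normalize_to_control <- function(df) {
  stopifnot(all(c("marker", "dose", "value") %in% names(df)))
  if (!"replicate" %in% names(df)) df$replicate <- seq_len(nrow(df))
  v <- df$value
  if ("area_um2" %in% names(df)) {
    if (any(df$area_um2 <= 0)) stop("non-positive aggregate area")
    v <- v / df$area_um2
  }
  out <- NULL
  for (m in unique(df$marker)) {
    sel <- df$marker == m
    ctrl <- v[sel & df$dose == 0]
    if (!length(ctrl)) stop("no dose-0 control wells for marker ", m)
    out <- rbind(out, data.frame(marker = m, dose = df$dose[sel],
                                 replicate = df$replicate[sel],
                                 normalized = v[sel] / mean(ctrl)))
  }
  class(out) <- c("dose_series", class(out))
  out
}

#' Target/reference specificity profile
#'
#' Per-dose ratio of the normalized target-marker value to the normalized
#' reference-marker value (means over replicates). Ratios below 1 indicate
#' target-specific loss; a decreasing trend with dose indicates
#' subpopulation-specific toxicity.
#'
#' @param series A `dose_series` from [normalize_to_control()].
#' @param marker_target,marker_reference Marker names.
#' @return Data frame: `dose`, `target`, `reference`, `ratio`.
#' @export
specificity_profile <- function(series, marker_target, marker_reference) {
  doses <- sort(unique(series$dose))
  mean_at <- function(m, d) {
    mean(series$normalized[series$marker == m & series$dose == d])
  }
  tg <- vapply(doses, function(d) mean_at(marker_target, d), 0)
  rf <- vapply(doses, function(d) mean_at(marker_reference, d), 0)
  if (any(!is.finite(rf)) || any(rf == 0)) stop("reference value is 0")
  data.frame(dose = doses, target = tg, reference = rf, ratio = tg / rf)
}

#' Four-parameter logistic (4PL) dose-response fit
#'
#' Fits `y = bottom + (top - bottom) / (1 + (dose/ec50)^hill)` by bounded,
#' seeded multi-start Levenberg-Marquardt least squares in log-dose
#' (`bottom >= 0`, `top <= 1.5`). Dose 0 is placed at a pseudo-log position
#' one decade below the lowest non-zero dose, standard practice for
#' plotting and fitting vehicle controls on a log axis. Non-convergence is
#' reported, not raised; a fitted dynamic range below 0.1 flags the fit as
#' degenerate (flat series).
#'
#' @param series A `dose_series` (or data frame with `dose`,
#'   `normalized`, optionally filtered by `marker`).
#' @param marker Optional marker to subset on.
#' @param n_starts Number of EC50 starting points across the dose range.
#' @return List: `top`, `bottom`, `ec50`, `hill_slope`, `goodness` (R²),
#'   `converged`, `degenerate`.
#' @export
fit_sigmoid <- function(series, marker = NULL, n_starts = 8L) {
  df <- series
  if (!is.null(marker)) df <- df[df$marker == marker, , drop = FALSE]
  stopifnot(all(c("dose", "normalized") %in% names(df)))
  if (length(unique(df$dose)) < 4L) stop("need at least 4 doses for a 4PL fit")
  nz <- df$dose[df$dose > 0]
  x0 <- log10(min(nz)) - 1
  x <- ifelse(df$dose > 0, log10(df$dose), x0)
  y <- df$normalized
  best <- NULL
  starts <- 10^seq(log10(min(nz)) - 0.5, log10(max(nz)) + 0.5,
                   length.out = n_starts)
  for (e0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (x - lec50))),
        start = list(top = max(y), bottom = max(0, min(y)),
                     hill = 1, lec50 = log10(e0)),
        lower = c(top = 0, bottom = 0, hill = 0.1,
                  lec50 = x0),
        upper = c(top = 1.5, bottom = 1.5, hill = 8,
                  lec50 = log10(max(nz)) + 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(list(top = NA_real_, bottom = NA_real_, ec50 = NA_real_,
                hill_slope = NA_real_, goodness = NA_real_,
                converged = FALSE, degenerate = NA))
  }
  cf <- coef(best$fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else NA_real_
  list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
       ec50 = 10^unname(cf["lec50"]), hill_slope = unname(cf["hill"]),
       goodness = r2, converged = TRUE,
       degenerate = unname(abs(cf["top"] - cf["bottom"]) < 0.1))
}
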