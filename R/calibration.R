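#' Baseline-corrected peak current from a voltammogram
#'
#' Fits a straight baseline through the two margins flanking the search
#' window (just outside it, on the chosen sweep segment) and returns the
#' extremal signed deviation of the current from that baseline inside the
#' window, together with the potential at which it occurs. The extremum is
#' located on a lightly smoothed copy of the deviation so a single noise
#' spike cannot claim the peak; the reported current is the unsmoothed
#' deviation at that location, so noiseless peaks are recovered exactly.
#'
#' @param v A `voltammogram` (from [generate_voltammogram()] or
#'   [read_voltammogram_csv()]).
#' @param window Length-2 potential interval, mV.
#' @param segment `"forward"` or `"reverse"`.
#' @param baseline_margin Width of each flanking baseline margin, mV.
#' @return An object of class `peak_measurement`: list with
#'   `peak_potential`, `peak_current` (baseline-subtracted, signed),
#'   `window`, `segment`.
#' @export
#' @examples
#' cv <- generate_voltammogram(list(peak_spec(-450, -500)),
#'                             cv_noise_model(noise_sd = 0))
#' extract_peak_current(cv, c(-520, -380), "reverse")
extract_peak_current <- function(v, window, segment = c("reverse", "forward"),
                                 baseline_margin = 30) {
  segment <- match.arg(segment)
  stopifnot(is.data.frame(v), length(window) == 2L)
  window <- sort(window)
  d <- v[v$segment == segment, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("insufficient data: segment not present", call. = FALSE)
  }
  in_win <- d$potential_mV >= window[1] & d$potential_mV <= window[2]
  if (!any(in_win)) {
    stop("insufficient data: no samples inside the window", call. = FALSE)
  }
  in_margin <- (d$potential_mV >= window[1] - baseline_margin &
                  d$potential_mV < window[1]) |
    (d$potential_mV > window[2] &
       d$potential_mV <= window[2] + baseline_margin)
  if (sum(in_margin) < 2L ||
      length(unique(d$potential_mV[in_margin])) < 2L) {
    stop("insufficient data: baseline margins outside the window have too few samples",
         call. = FALSE)
  }
  fit <- stats::lm(current_nA ~ potential_mV, data = d[in_margin, ])
  base <- stats::predict(fit, newdata = d[in_win, , drop = FALSE])
  dev <- d$current_nA[in_win] - base
  # locate the extremum on a lightly smoothed curve (7-sample running mean)
  # so a single noise spike cannot claim the peak; the reported current is
  # the raw baseline-subtracted value at that location
  loc <- dev
  if (length(dev) >= 7L) {
    sm <- stats::filter(dev, rep(1 / 7, 7), sides = 2)
    loc[!is.na(sm)] <- sm[!is.na(sm)]
  }
  i <- which.max(abs(loc))
  structure(list(peak_potential = unname(d$potential_mV[in_win][i]),
                 peak_current = unname(dev[i]),
                 window = window, segment = segment),
            class = "peak_measurement")
}

#' Linear calibration fit
#'
#' Ordinary least squares of the absolute peak current on concentration. The
#' slope is the sensor sensitivity in nA/uM; cathodic and anodic peaks share
#' one convention through the absolute value.
#'
#' @param concentrations Concentrations, uM (>= 3 points, >= 2 distinct).
#' @param peak_currents Signed peak currents, nA.
#' @return List with `slope`, `intercept`, `r_squared`, `slope_se`, `n`.
#' @export
#' @examples
#' fit_calibration(c(0, 1, 2), c(0, 10, 20))
fit_calibration <- function(concentrations, peak_currents) {
  stopifnot(length(concentrations) == length(peak_currents))
  if (length(concentrations) < 3L || length(unique(concentrations)) < 2L) {
    stop("insufficient data: need >= 3 points with >= 2 distinct concentrations",
         call. = FALSE)
  }
  y <- abs(peak_currents)
  fit <- stats::lm(y ~ concentrations)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= .Machine$double.eps * sum(y^2) || sst == 0) {
    if (sse <= 1e-12 * max(1, sum(y^2))) 1 else 0
  } else {
    max(0, min(1, 1 - sse / sst))
  }
  # summary() warns on zero-residual fits; r2 is handled above
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       slope_se = if (nrow(cf) > 1L) cf[2, 2] else NA_real_,
       n = length(y))
}

#' Three-sigma detection limit
#'
#' The limit of detection is three times the standard deviation of the
#' signal measured in the absence of analyte, divided by the slope of the
#' calibration line.
#'
#' @param blank_currents Peak currents of >= 3 blank replicates, nA.
#' @param slope Calibration slope, nA/uM; must be positive.
#' @return Detection limit, uM.
#' @export
#' @examples
#' detection_limit(c(0, 1, 2), 6) # 0.5
detection_limit <- function(blank_currents, slope) {
  if (length(blank_currents) < 3L) {
    stop("insufficient data: need >= 3 blank replicates", call. = FALSE)
  }
  if (!is.finite(slope) || slope <= 0) {
    stop("invalid parameter: slope must be positive", call. = FALSE)
  }
  3 * stats::sd(blank_currents) / slope
}

#' Per-area sensitivity
#'
#' @param slope Calibration slope, nA/uM.
#' @param electrode_area Working electrode area, mm^2 (default 12.56).
#' @return Sensitivity per unit electrode area, nA/(uM*mm^2).
#' @export
#' @examples
#' sensitivity_per_area(925.7) # ~73.7
sensitivity_per_area <- function(slope, electrode_area = 12.56) {
  if (!is.finite(electrode_area) || electrode_area <= 0) {
    stop("invalid parameter: electrode area must be positive", call. = FALSE)
  }
  slope / electrode_area
}

# Internal: monitored-peak window for a preset. The +/- 45 mV window with a
# 20 mV outside margin keeps the neighbouring peak regions (120+ mV away,
# sigma 15 mV) out of both the window and the baseline margins.
.preset_window <- function(preset, half_width = 45) {
  preset$monitored_peak_mV + c(-half_width, half_width)
}

#' Calibrate one synthetic concentration series
#'
#' Extracts the monitored peak from every voltammogram of the series, fits
#' the calibration line restricted to the preset's pharmacological range
#' (blanks included), and computes the three-sigma detection limit from the
#' blank replicates.
#'
#' @param series A `cv_series` from [generate_calibration_series()].
#' @param window Optional peak window, mV; defaults to the monitored peak
#'   +/- 45 mV.
#' @param baseline_margin Baseline margin for [extract_peak_current()], mV
#'   (narrower than the standalone default so the margins stay clear of the
#'   companion peak regions).
#' @return An object of class `calibration_result`: list with `drug`,
#'   `isoform`, `matrix`, `slope`, `slope_per_area`, `intercept`,
#'   `r_squared`, `lod`, `linear_range`, `n_points`, `peaks` (the per-record
#'   extraction table).
#' @export
fit_series <- function(series, window = NULL, baseline_margin = 20) {
  stopifnot(inherits(series, "cv_series"))
  preset <- attr(series, "preset")
  if (is.null(window)) window <- .preset_window(preset)
  tbl <- do.call(rbind, lapply(series, function(rec) {
    pm <- extract_peak_current(rec$cv, window, preset$segment,
                               baseline_margin)
    data.frame(concentration = rec$concentration,
               replicate = rec$replicate,
               peak_potential = pm$peak_potential,
               peak_current = pm$peak_current)
  }))
  blanks <- tbl$peak_current[tbl$concentration == 0]
  if (length(blanks) < 3L) {
    stop("insufficient data: detection limit requires >= 3 blank replicates",
         call. = FALSE)
  }
  in_range <- tbl$concentration == 0 |
    (tbl$concentration >= preset$range_lo_uM &
       tbl$concentration <= preset$range_hi_uM)
  fit <- fit_calibration(tbl$concentration[in_range],
                         tbl$peak_current[in_range])
  lod <- detection_limit(blanks, fit$slope)
  structure(list(
    drug = preset$drug, isoform = preset$isoform,
    matrix = attr(series, "matrix"),
    slope = fit$slope,
    slope_per_area = sensitivity_per_area(fit$slope,
                                          preset$electrode_area_mm2),
    intercept = fit$intercept,
    r_squared = fit$r_squared,
    slope_se = fit$slope_se,
    lod = lod,
    linear_range = c(preset$range_lo_uM, preset$range_hi_uM),
    n_points = fit$n,
    peaks = tbl
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("%s / %s (%s): sensitivity %.1f nA/uM (%.2f nA/uM/mm2), LOD %.3g uM, r2 %.4f\n",
              x$drug, x$isoform, x$matrix, x$slope, x$slope_per_area,
              x$lod, x$r_squared))
  invisible(x)
}

#' Calibrate a panel of concentration series
#'
#' Runs extract -> fit -> detection limit on every series of a panel and
#' tabulates the results in the layout of a sensor performance table: one
#' row per drug/isoform/matrix with sensitivity, per-area sensitivity,
#' detection limit and fit diagnostics.
#'
#' @param panel List of `cv_series` objects.
#' @param ... Passed to [fit_series()].
#' @return Data frame with columns `drug`, `isoform`, `matrix`,
#'   `slope_nA_per_uM`, `slope_per_area`, `intercept_nA`, `r_squared`,
#'   `lod_uM`, `n_points`.
#' @export
analyze_panel <- function(panel, ...) {
  stopifnot(length(panel) >= 1L)
  rows <- lapply(panel, function(series) {
    res <- fit_series(series, ...)
    data.frame(drug = res$drug, isoform = res$isoform, matrix = res$matrix,
               slope_nA_per_uM = res$slope,
               slope_per_area = res$slope_per_area,
               intercept_nA = res$intercept,
               r_squared = res$r_squared,
               lod_uM = res$lod,
               n_points = res$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-drug hetero-activation analysis
#'
#' Takes a family of calibration series measured at different fixed
#' concentrations of a second (modulator) drug, fits the sensitivity of each
#' family member, and regresses sensitivity on modulator concentration. The
#' `activation_slope` quantifies hetero-activation; `monotone_increase` is
#' true when every successive sensitivity increases; `overlap` is true when
#' the activation slope is statistically indistinguishable from zero
#' (two-sided t-test on the regression coefficient at level 0.05, requiring
#' at least three modulator levels).
#'
#' @param families List of `cv_series`, one per modulator concentration
#'   (taken from each series' `modulator_conc` attribute unless
#'   `modulator_concs` is supplied).
#' @param modulator_concs Optional explicit modulator concentrations, uM.
#' @param level Significance level of the overlap test.
#' @param ... Passed to [fit_series()].
#' @return An object of class `pair_interaction`: list with
#'   `modulator_concs`, `sensitivities`, `activation_slope`, `p_value`,
#'   `monotone_increase`, `overlap`.
#' @export
analyze_drug_pair <- function(families, modulator_concs = NULL, level = 0.05,
                              ...) {
  if (length(families) < 2L) {
    stop("insufficient data: need >= 2 modulator concentrations",
         call. = FALSE)
  }
  if (is.null(modulator_concs)) {
    modulator_concs <- vapply(families, function(s) {
      m <- attr(s, "modulator_conc")
      if (is.null(m)) NA_real_ else m
    }, numeric(1))
  }
  if (any(is.na(modulator_concs))) {
    stop("invalid parameter: modulator concentrations are missing",
         call. = FALSE)
  }
  ord <- order(modulator_concs)
  modulator_concs <- modulator_concs[ord]
  families <- families[ord]
  sens <- vapply(families, function(s) fit_series(s, ...)$slope, numeric(1))
  fit <- stats::lm(sens ~ modulator_concs)
  slope <- unname(stats::coef(fit)[2])
  p <- if (length(sens) >= 3L) {
    suppressWarnings(summary(fit)$coefficients[2, 4])
  } else {
    NA_real_
  }
  structure(list(
    modulator_concs = modulator_concs,
    sensitivities = unname(sens),
    activation_slope = slope,
    p_value = p,
    monotone_increase = all(diff(sens) > 0),
    overlap = if (is.na(p)) NA else p > level
  ), class = "pair_interaction")
}

#' @export
print.pair_interaction <- function(x, ...) {
  cat(sprintf(
    "Drug-pair analysis over %d modulator levels: activation slope %.4g (nA/uM)/uM, p = %.3g\n",
    length(x$modulator_concs), x$activation_slope, x$p_value))
  cat(sprintf("  monotone increase: %s; curves overlap: %s\n",
              x$monotone_increase, x$overlap))
  invisible(x)
}
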