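#' Gaussian faradaic peak specification
#'
#' @param center Peak potential, mV; must lie within the sweep range.
#' @param amplitude Signed peak current, nA (cathodic/reduction peaks
#'   negative, anodic/oxidation peaks positive).
#' @param width Gaussian sigma, mV. The default 15 mV (FWHM ~35 mV) keeps
#'   the peak regions at -330, -450 and -200 mV spectrally separable.
#' @param segment Sweep segment carrying the peak: oxidation peaks appear on
#'   the `"forward"` (anodic-going) branch, reduction peaks on the
#'   `"reverse"` branch.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, amplitude, width = 15,
                      segment = c("reverse", "forward")) {
  segment <- match.arg(segment)
  if (!is.finite(width) || width <= 0) {
    stop("invalid parameter: width must be positive", call. = FALSE)
  }
  structure(list(center = center, amplitude = amplitude, width = width,
                 segment = segment), class = "peak_spec")
}

#' Background and noise model for synthetic voltammograms
#'
#' The non-faradaic background is a capacitive current proportional to the
#' scan rate (positive on the anodic-going branch, negative on the
#' cathodic-going branch, producing the familiar hysteresis envelope) plus a
#' linear ohmic baseline; measurement noise is i.i.d. Gaussian per sample.
#' The absolute background magnitudes are free parameters of the emulation.
#'
#' @param capacitance_scale Capacitive current per unit scan rate,
#'   nA/(mV/s).
#' @param baseline_slope Ohmic baseline slope, nA/mV.
#' @param noise_sd Gaussian noise standard deviation, nA.
#' @param seed Optional integer seed making a single generated voltammogram
#'   reproducible on its own.
#' @return An object of class `cv_noise_model`.
#' @export
cv_noise_model <- function(capacitance_scale = 25, baseline_slope = 0.2,
                           noise_sd = 5, seed = NULL) {
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("invalid parameter: noise_sd must be non-negative", call. = FALSE)
  }
  structure(list(capacitance_scale = capacitance_scale,
                 baseline_slope = baseline_slope,
                 noise_sd = noise_sd, seed = seed),
            class = "cv_noise_model")
}

#' Generate a synthetic cyclic voltammogram
#'
#' Emulates a triangular potential sweep (default -600 -> +300 -> -600 mV at
#' 20 mV/s): the current is the capacitive background (sign set by the sweep
#' direction), a linear baseline, the sum of Gaussian faradaic peaks each
#' living on its own segment, and additive Gaussian noise.
#'
#' @param peaks List of [peak_spec()] objects (possibly empty).
#' @param noise A [cv_noise_model()].
#' @param step Potential step between samples, mV.
#' @param scan_rate Scan rate, mV/s.
#' @param potential_range Sweep limits, mV.
#' @return An object of classes `voltammogram` and `data.frame` with columns
#'   `potential_mV`, `current_nA`, `segment`; the scan rate is stored in
#'   attribute `scan_rate_mV_s`.
#' @export
#' @examples
#' cv <- generate_voltammogram(list(peak_spec(-450, -500)),
#'                             cv_noise_model(noise_sd = 0))
#' range(cv$potential_mV)
generate_voltammogram <- function(peaks = list(),
                                  noise = cv_noise_model(),
                                  step = 1, scan_rate = 20,
                                  potential_range = c(-600, 300)) {
  stopifnot(inherits(noise, "cv_noise_model"))
  if (!is.finite(step) || step <= 0) {
    stop("invalid parameter: step must be positive", call. = FALSE)
  }
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  for (p in peaks) {
    stopifnot(inherits(p, "peak_spec"))
    if (p$center < potential_range[1] || p$center > potential_range[2]) {
      stop("invalid parameter: peak center outside the sweep range",
           call. = FALSE)
    }
  }
  fwd <- seq(potential_range[1], potential_range[2], by = step)
  rev_ <- seq(potential_range[2], potential_range[1], by = -step)
  pot <- c(fwd, rev_)
  seg <- rep(c("forward", "reverse"), c(length(fwd), length(rev_)))
  cap <- noise$capacitance_scale * scan_rate
  cur <- ifelse(seg == "forward", cap, -cap) + noise$baseline_slope * pot
  for (p in peaks) {
    on_seg <- seg == p$segment
    cur[on_seg] <- cur[on_seg] +
      p$amplitude * exp(-(pot[on_seg] - p$center)^2 / (2 * p$width^2))
  }
  if (noise$noise_sd > 0) {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    cur <- cur + stats::rnorm(length(cur), 0, noise$noise_sd)
  }
  structure(
    data.frame(potential_mV = pot, current_nA = cur, segment = seg,
               stringsAsFactors = FALSE),
    scan_rate_mV_s = scan_rate,
    class = c("voltammogram", "data.frame")
  )
}

#' Drug/isoform presets for the P450--nanotube biosensor
#'
#' Per-area sensitivities (nA/(uM*mm^2)) in phosphate buffer (PBS) and in
#' human serum, pharmacological concentration ranges (uM) and monitored peak
#' potentials for each drug/isoform electrode. The serum values encode the
#' sensitivity loss from plasma-protein drug binding as a preset reduction;
#' no binding kinetics are modelled. The working electrode area is 12.56 mm^2.
#'
#' The cytochrome-modified electrodes are monitored at the cathodic peak near
#' -330 mV (a companion cathodic region near -450 mV is also generated); the
#' plain nanotube electrode used for etoposide is monitored at the anodic
#' peak near +220 mV.
#'
#' @return Data frame with one row per drug/isoform electrode.
#' @export
#' @examples
#' drug_presets()
drug_presets <- function() {
  data.frame(
    id = c("cyclophosphamide_2b6", "cyclophosphamide_3a4",
           "ifosfamide_2b6", "ifosfamide_3a4",
           "ftorafur_1a2", "etoposide_cnt"),
    drug = c("cyclophosphamide", "cyclophosphamide", "ifosfamide",
             "ifosfamide", "ftorafur", "etoposide"),
    isoform = c("2B6", "3A4", "2B6", "3A4", "1A2", "CNT"),
    range_lo_uM = c(2.68, 2.68, 10, 10, 1, 33.98),
    range_hi_uM = c(76.6, 76.6, 160, 160, 10, 101.94),
    sens_pbs = c(1.0, 0.6, 1.2, 1.6, 8.8, 73.7),
    sens_serum = c(0.3, 0.3, 0.1, 0.4, 3.9, 9.1),
    monitored_peak_mV = c(-330, -330, -330, -330, -330, 220),
    segment = c("reverse", "reverse", "reverse", "reverse", "reverse",
                "forward"),
    polarity = c(-1, -1, -1, -1, -1, 1),
    electrode_area_mm2 = 12.56,
    stringsAsFactors = FALSE
  )
}

#' Fetch one preset by id
#'
#' @param id Preset id, e.g. `"ftorafur_1a2"`; see [drug_presets()].
#' @return Single-row preset as a list.
#' @export
cyp_preset <- function(id) {
  tbl <- drug_presets()
  i <- match(id, tbl$id)
  if (is.na(i)) {
    stop(sprintf("unknown preset '%s'; valid ids: %s", id,
                 paste(tbl$id, collapse = ", ")), call. = FALSE)
  }
  as.list(tbl[i, ])
}

#' Sensitivity under hetero-activation by a second drug
#'
#' Several P450 isoforms show atypical (allotropic) kinetics: a second
#' substrate bound to the enzyme can increase its activity toward the first.
#' The modulation is modelled as a linear multiplier on the calibration
#' sensitivity: `base * (1 + gamma * modulator_conc)`. `gamma = 0` recovers
#' the no-interaction case in which calibration curves at different modulator
#' levels overlap.
#'
#' @param base Unmodulated sensitivity, nA/uM; must be positive.
#' @param modulator_conc Concentration of the modulating drug, uM.
#' @param gamma Fractional sensitivity gain per uM of modulator.
#' @return Effective sensitivity, nA/uM.
#' @export
#' @examples
#' effective_sensitivity(100, 100, 0.005) # 150
effective_sensitivity <- function(base, modulator_conc, gamma = 0) {
  if (!is.finite(base) || base <= 0) {
    stop("invalid parameter: base sensitivity must be positive", call. = FALSE)
  }
  if (any(modulator_conc < 0)) {
    stop("invalid parameter: modulator concentration must be non-negative",
         call. = FALSE)
  }
  out <- base * (1 + gamma * modulator_conc)
  if (any(out <= 0)) {
    stop("invalid parameter: modulated sensitivity must stay positive",
         call. = FALSE)
  }
  out
}

#' Generate a concentration series of synthetic voltammograms
#'
#' Emulates a calibration experiment: for each concentration (always
#' including a blank at 0 uM for detection-limit estimation) and replicate, a
#' voltammogram is generated whose monitored-peak amplitude is
#' `sensitivity_per_area * electrode_area * concentration + blank_nA`, signed
#' by the peak polarity. The matrix selects the PBS or serum per-area
#' sensitivity, and an optional second drug at `modulator_conc` scales the
#' sensitivity through [effective_sensitivity()].
#'
#' Besides the monitored peak, each voltammogram carries the secondary
#' features seen on these electrodes: for cytochrome electrodes a companion
#' cathodic region near -450 mV (at 0.6 of the monitored amplitude) and the
#' nanotube oxygen-moiety peak near -200 mV; for the plain nanotube
#' (etoposide) electrode a second oxidation peak at +450 mV, reduction peaks
#' at +150 and +350 mV, and the oxygen-moiety peak.
#'
#' @param preset Preset id or the list from [cyp_preset()].
#' @param concentrations Drug concentrations, uM; default five points evenly
#'   spanning the preset's pharmacological range.
#' @param n_replicates Replicates per concentration (blanks get at least 3).
#' @param matrix `"pbs"` or `"serum"`.
#' @param noise A [cv_noise_model()].
#' @param seed Integer seed for the whole series.
#' @param modulator_conc Second-drug concentration, uM.
#' @param gamma Hetero-activation coefficient, per uM.
#' @param blank_nA Blank (zero-analyte) monitored-peak amplitude, nA.
#' @param step Potential step, mV.
#' @return An object of class `cv_series`: list of records, each
#'   `list(concentration, replicate, cv)`, with the preset, matrix, seed and
#'   modulator stored as attributes.
#' @export
generate_calibration_series <- function(preset, concentrations = NULL,
                                        n_replicates = 3,
                                        matrix = c("pbs", "serum"),
                                        noise = cv_noise_model(),
                                        seed = 1L,
                                        modulator_conc = 0, gamma = 0,
                                        blank_nA = 50, step = 1) {
  if (is.character(preset)) preset <- cyp_preset(preset)
  matrix <- match.arg(matrix)
  if (is.null(concentrations)) {
    concentrations <- seq(preset$range_lo_uM, preset$range_hi_uM,
                          length.out = 5)
  }
  if (any(concentrations < 0)) {
    stop("invalid parameter: concentrations must be non-negative",
         call. = FALSE)
  }
  base <- if (matrix == "pbs") preset$sens_pbs else preset$sens_serum
  s_eff <- effective_sensitivity(base, modulator_conc, gamma)
  concs <- sort(unique(c(0, concentrations)))
  set.seed(seed)
  records <- list()
  for (conc in concs) {
    reps <- if (conc == 0) max(n_replicates, 3L) else n_replicates
    amp <- preset$polarity *
      (s_eff * preset$electrode_area_mm2 * conc + blank_nA)
    peaks <- .series_peaks(preset, amp)
    for (r in seq_len(reps)) {
      cv <- generate_voltammogram(peaks, noise, step = step)
      records[[length(records) + 1L]] <-
        list(concentration = conc, replicate = r, cv = cv)
    }
  }
  structure(records, class = "cv_series",
            preset = preset, matrix = matrix, seed = seed,
            modulator_conc = modulator_conc, gamma = gamma,
            blank_nA = blank_nA)
}

# Internal: full peak set for one voltammogram of a calibration series.
.series_peaks <- function(preset, monitored_amplitude) {
  if (preset$polarity < 0) {
    # cytochrome-modified electrode: cathodic chemistry
    list(
      peak_spec(preset$monitored_peak_mV, monitored_amplitude,
                segment = "reverse"),
      peak_spec(-450, 0.6 * monitored_amplitude, segment = "reverse"),
      peak_spec(-200, -80, segment = "reverse") # CNT oxygen moieties
    )
  } else {
    # plain nanotube electrode (etoposide): oxidation at +220 mV (monitored),
    # the matching reduction at +150 mV, and the oxygen-moiety peak. The
    # +450/+350 mV features lie beyond the +300 mV sweep limit and are not
    # generated.
    list(
      peak_spec(preset$monitored_peak_mV, monitored_amplitude,
                segment = "forward"),
      peak_spec(150, -0.4 * monitored_amplitude, segment = "reverse"),
      peak_spec(-200, -80, segment = "reverse")
    )
  }
}
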