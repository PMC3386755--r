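#!/usr/bin/env Rscript
# Synthetic cyclic voltammograms for every drug/isoform electrode preset.
#
# Triangular sweep -600 -> +300 -> -600 mV at 20 mV/s, capacitive
# hysteresis, Gaussian faradaic peaks with amplitudes linear in drug
# concentration (per-area sensitivity presets x 12.56 mm^2 electrode).
# Writes one example CV per preset plus a full PBS/serum calibration series
# manifest used by 04_calibration_panel.R.

library(cypcnt)
dir.create("results/cv", recursive = TRUE, showWarnings = FALSE)
seed <- 7L

for (id in drug_presets()$id) {
  preset <- cyp_preset(id)
  mid <- (preset$range_lo_uM + preset$range_hi_uM) / 2
  s <- generate_calibration_series(id, concentrations = mid,
                                   n_replicates = 1, seed = seed)
  cv <- s[[length(s)]]$cv
  path <- sprintf("results/cv/%s_%.3guM.csv", id, mid)
  write_voltammogram_csv(cv, path)
  cat(sprintf("%-22s %6.3g uM -> %s\n", id, mid, path))
}

cat("\nPeak structure of one etoposide voltammogram (100 uM, PBS):\n")
s <- generate_calibration_series("etoposide_cnt", concentrations = 100,
                                 n_replicates = 1, seed = seed)
pm <- extract_peak_current(s[[length(s)]]$cv, c(175, 265), "forward")
cat(sprintf("  anodic peak %.0f nA at %+d mV (expected ~%.0f nA at +220 mV)\n",
            pm$peak_current, pm$peak_potential, 73.7 * 12.56 * 100 + 50))
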