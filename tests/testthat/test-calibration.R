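test_that("peak extraction subtracts a linear baseline", {
  # flat, peak-free voltammogram: no deviation from the baseline
  cv <- generate_voltammogram(noise = cv_noise_model(noise_sd = 0))
  pm <- extract_peak_current(cv, c(-520, -380), "reverse")
  expect_equal(pm$peak_current, 0, tolerance = 1e-9)
  # the ohmic slope alone must not register as a peak
  cv2 <- generate_voltammogram(noise = cv_noise_model(baseline_slope = 2,
                                                      noise_sd = 0))
  expect_equal(extract_peak_current(cv2, c(-520, -380), "reverse")$peak_current,
               0, tolerance = 1e-9)
  expect_error(extract_peak_current(cv, c(1000, 1100), "reverse"),
               "insufficient data")
})

test_that("extraction recovers programmed amplitudes across widths", {
  for (w in c(10, 15, 25)) {
    cv <- generate_voltammogram(list(peak_spec(-330, -400, width = w)),
                                cv_noise_model(noise_sd = 0))
    pm <- extract_peak_current(cv, c(-330 - 5 * w, -330 + 5 * w), "reverse")
    expect_equal(pm$peak_current, -400, tolerance = 0.005)
    expect_equal(pm$peak_potential, -330, tolerance = 1)
  }
})

test_that("calibration fit is ordinary least squares on |peak current|", {
  f <- fit_calibration(c(0, 1, 2), c(0, 10, 20))
  expect_equal(f$slope, 10)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # cathodic (negative) currents give the same sensitivity
  f2 <- fit_calibration(c(0, 1, 2), c(0, -10, -20))
  expect_equal(f2$slope, 10)
  f3 <- fit_calibration(c(0, 1, 2), c(5, 5, 5))
  expect_equal(f3$slope, 0)
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "insufficient data")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "insufficient data")
})

test_that("detection limit is three sigma over slope", {
  expect_equal(detection_limit(c(0, 1, 2), 6), 0.5)
  expect_equal(detection_limit(c(0, 1, 2), 3), 1)
  expect_equal(detection_limit(2 * c(0, 1, 2), 6),
               2 * detection_limit(c(0, 1, 2), 6))
  expect_error(detection_limit(c(0, 1), 3), "insufficient data")
  expect_error(detection_limit(c(0, 1, 2), 0), "invalid parameter")
})

test_that("per-area sensitivity inverts the preset construction", {
  expect_equal(sensitivity_per_area(925.672), 73.7, tolerance = 1e-6)
  expect_equal(sensitivity_per_area(110.528), 8.8, tolerance = 1e-6)
  expect_equal(sensitivity_per_area(42, 1), 42)
  expect_error(sensitivity_per_area(10, 0), "invalid parameter")
})

test_that("series calibration recovers the generator sensitivity", {
  s <- generate_calibration_series("ftorafur_1a2", seed = 7,
                                   noise = cv_noise_model(noise_sd = 1))
  res <- fit_series(s)
  expect_equal(res$slope, 8.8 * 12.56, tolerance = 0.05)
  expect_equal(res$slope_per_area, 8.8, tolerance = 0.05)
  expect_gt(res$r_squared, 0.99)
  expect_gt(res$lod, 0)
})

test_that("panel analysis mirrors the sensor performance table", {
  noise <- cv_noise_model(noise_sd = 2)
  ids <- c("ftorafur_1a2", "ifosfamide_2b6")
  panel <- list()
  for (id in ids) {
    for (m in c("pbs", "serum")) {
      panel[[paste(id, m)]] <-
        generate_calibration_series(id, matrix = m, seed = 17, noise = noise)
    }
  }
  tbl <- analyze_panel(panel)
  expect_equal(nrow(tbl), 4L)
  expect_true(all(c("drug", "isoform", "matrix", "slope_nA_per_uM",
                    "slope_per_area", "lod_uM", "r_squared") %in% names(tbl)))
  # detection limits fall inside the pharmacological ranges
  hi <- c(ftorafur = 10, ifosfamide = 160)
  expect_true(all(tbl$lod_uM < hi[tbl$drug]))
  # serum sensitivity below PBS sensitivity for matched seeds
  for (id in ids) {
    drug <- cyp_preset(id)$drug
    sub <- tbl[tbl$drug == drug, ]
    expect_lt(sub$slope_nA_per_uM[sub$matrix == "serum"],
              sub$slope_nA_per_uM[sub$matrix == "pbs"])
  }
})

test_that("noiseless panels calibrate essentially exactly", {
  panel <- lapply(c("cyclophosphamide_3a4", "etoposide_cnt"), function(id) {
    generate_calibration_series(id, noise = cv_noise_model(noise_sd = 0))
  })
  tbl <- suppressWarnings(analyze_panel(panel))
  expect_true(all(tbl$r_squared > 0.999))
})

test_that("drug-pair analysis sees hetero-activation and its absence", {
  noise <- cv_noise_model(noise_sd = 5)
  mk_family <- function(gamma, seed0) {
    lapply(c(0, 25, 50, 75, 100), function(m) {
      generate_calibration_series("ftorafur_1a2", seed = seed0 + m,
                                  modulator_conc = m, gamma = gamma,
                                  noise = noise)
    })
  }
  act <- analyze_drug_pair(mk_family(0.005, 300))
  expect_true(act$monotone_increase)
  expect_false(act$overlap)
  # activation slope = S * A * gamma = 8.8 * 12.56 * 0.005
  expect_equal(act$activation_slope, 8.8 * 12.56 * 0.005, tolerance = 0.1)
  null <- analyze_drug_pair(mk_family(0, 300))
  expect_true(null$overlap)
  expect_equal(null$activation_slope, 0, tolerance = 0.05)
  # two families: slope still estimable, overlap test undefined
  two <- analyze_drug_pair(mk_family(0.005, 300)[c(1, 5)])
  expect_equal(two$activation_slope, 8.8 * 12.56 * 0.005, tolerance = 0.1)
  expect_true(is.na(two$overlap))
  expect_error(analyze_drug_pair(list()), "insufficient data")
})
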