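test_that("sweep structure and capacitive hysteresis are built in", {
  cv <- generate_voltammogram(noise = cv_noise_model(noise_sd = 0))
  expect_true(all(cv$potential_mV >= -600 & cv$potential_mV <= 300))
  expect_setequal(unique(cv$segment), c("forward", "reverse"))
  fwd <- cv[cv$segment == "forward", ]
  rev_ <- cv[cv$segment == "reverse", ]
  expect_equal(nrow(fwd), nrow(rev_))
  expect_true(all(diff(fwd$potential_mV) > 0))
  expect_true(all(diff(rev_$potential_mV) < 0))
  # forward and reverse differ by 2 * capacitance_scale * scan_rate everywhere
  m <- merge(fwd, rev_, by = "potential_mV")
  expect_equal(unique(m$current_nA.x - m$current_nA.y), 2 * 25 * 20)
})

test_that("programmed peaks are where they were put", {
  cv <- generate_voltammogram(list(peak_spec(-450, -500, width = 20)),
                              cv_noise_model(noise_sd = 0))
  pm <- extract_peak_current(cv, c(-520, -380), "reverse")
  expect_equal(pm$peak_potential, -450)
  expect_equal(pm$peak_current, -500, tolerance = 1e-3)
  # the peak lives only on its declared segment
  fwd <- extract_peak_current(cv, c(-520, -380), "forward")
  expect_lt(abs(fwd$peak_current), 1)
  expect_error(
    generate_voltammogram(list(peak_spec(400, 10, segment = "forward"))),
    "outside the sweep")
})

test_that("noise is reproducible under a seed", {
  n <- cv_noise_model(noise_sd = 5, seed = 99)
  cv1 <- generate_voltammogram(noise = n)
  cv2 <- generate_voltammogram(noise = n)
  expect_identical(cv1, cv2)
  expect_false(identical(cv1,
    generate_voltammogram(noise = cv_noise_model(noise_sd = 5, seed = 100))))
})

test_that("calibration series encodes the preset amplitude model", {
  # noiseless etoposide, blank suppressed: amplitude = 73.7 * 12.56 * conc
  s <- generate_calibration_series("etoposide_cnt", concentrations = 1,
                                   n_replicates = 1, blank_nA = 0,
                                   noise = cv_noise_model(noise_sd = 0))
  rec <- s[[length(s)]]
  expect_equal(rec$concentration, 1)
  pm <- extract_peak_current(rec$cv, c(150, 290), "forward")
  expect_equal(pm$peak_current, 925.672, tolerance = 0.005)
  expect_equal(pm$peak_potential, 220, tolerance = 2)
  # blanks carry only the blank amplitude
  blank <- s[[1]]
  expect_equal(blank$concentration, 0)
  pm0 <- extract_peak_current(blank$cv, c(150, 290), "forward")
  expect_lt(abs(pm0$peak_current), 1)
  # serum matrix switches to the serum sensitivity
  ss <- generate_calibration_series("etoposide_cnt", concentrations = 1,
                                    n_replicates = 1, blank_nA = 0,
                                    matrix = "serum",
                                    noise = cv_noise_model(noise_sd = 0))
  pms <- extract_peak_current(ss[[length(ss)]]$cv, c(150, 290), "forward")
  expect_equal(pms$peak_current, 9.1 * 12.56, tolerance = 0.05)
  expect_error(generate_calibration_series("etoposide_cnt", matrix = "plasma"),
               "arg")
  expect_error(cyp_preset("nonexistent_drug"), "unknown preset")
})

test_that("default concentrations span the pharmacological range", {
  s <- generate_calibration_series("ftorafur_1a2",
                                   noise = cv_noise_model(noise_sd = 0),
                                   n_replicates = 1)
  concs <- unique(vapply(s, `[[`, numeric(1), "concentration"))
  expect_true(all(concs[concs > 0] >= 1 & concs[concs > 0] <= 10))
  expect_true(0 %in% concs) # blanks always present for LOD estimation
})

test_that("extracted blank scatter tracks the injected noise level", {
  noise_sd <- 5
  s <- generate_calibration_series("ftorafur_1a2", concentrations = numeric(0),
                                   n_replicates = 100, seed = 31,
                                   noise = cv_noise_model(noise_sd = noise_sd))
  blanks <- vapply(s[vapply(s, `[[`, numeric(1), "concentration") == 0],
                   function(rec) {
                     extract_peak_current(rec$cv, c(-375, -285),
                                          "reverse", 20)$peak_current
                   }, numeric(1))
  expect_gte(length(blanks), 100)
  expect_lt(abs(sd(blanks) - noise_sd) / noise_sd, 0.2)
})

test_that("hetero-activation multiplier behaves linearly", {
  expect_equal(effective_sensitivity(100, 50, 0), 100)
  expect_equal(effective_sensitivity(100, 0, 0.005), 100)
  expect_equal(effective_sensitivity(100, 100, 0.005), 150)
  # non-decreasing in modulator concentration for gamma >= 0
  m <- seq(0, 160, by = 20)
  expect_true(all(diff(effective_sensitivity(73.7, m, 0.004)) >= 0))
  expect_error(effective_sensitivity(-1, 0, 0), "invalid parameter")
  expect_error(effective_sensitivity(100, 300, -0.01), "invalid parameter")
})
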