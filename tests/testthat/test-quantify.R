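# Bucket integration, SNR, calibration, normalisation, anomer correction.

test_that("trapezoidal bucket integration is exact and additive", {
  axis <- seq(0, 2, by = 0.001)
  zero <- nmr_spectrum(axis, numeric(length(axis)))
  expect_equal(integrate_bucket(zero, 0.2, 0.8), 0)
  lor <- render_spectrum(data.frame(frequency_Hz = 60, intensity = 1),
                         axis, 0.55, 60)
  expect_equal(integrate_bucket(lor, 0.5, 1.5), 1, tolerance = 0.01)
  # adjacent buckets partition their union exactly
  a <- integrate_bucket(lor, 0.5, 0.9735)
  b <- integrate_bucket(lor, 0.9735, 1.5)
  expect_equal(a + b, integrate_bucket(lor, 0.5, 1.5), tolerance = 1e-12)
  expect_error(integrate_bucket(lor, 1.5, 2.5),
               class = "lfnmr_validation_error")
})

test_that("SNR estimators behave as specified", {
  axis <- seq(0, 10, by = 0.001)
  y <- rep(1, length(axis))
  y[abs(axis - 5.25) < 0.002] <- 30
  sp <- nmr_spectrum(axis, y)
  expect_equal(estimate_snr(sp, 5.25, "flank_mean"), 30)
  clean <- nmr_spectrum(axis, ifelse(abs(axis - 5.25) < 0.002, 30, 0))
  expect_identical(estimate_snr(clean, 5.25), Inf)
  expect_error(estimate_snr(sp, 9.2, "top10_noise"),
               class = "lfnmr_validation_error")
  # extreme-value estimator never exceeds the flank-mean estimator
  for (s in 1:5) {
    set.seed(s)
    yn <- rnorm(length(axis))
    yn[abs(axis - 5.25) < 0.005] <- 50
    spn <- nmr_spectrum(axis, yn)
    expect_lte(estimate_snr(spn, 5.25, "top10_noise"),
               estimate_snr(spn, 5.25, "flank_mean"))
  }
})

test_that("internal-standard ratios follow proton bookkeeping", {
  expect_equal(tsp_normalize(2, 2), 1)
  expect_equal(tsp_normalize(0, 2), 0)
  expect_error(tsp_normalize(1, 0), class = "lfnmr_validation_error")
  # 100 mmol/L total glucose vs 223 umol/L TSP: (0.36*100)/(0.223*9)
  expect_equal(theoretical_slope(0.223) * 100, 17.94, tolerance = 0.005)
  # simulated, presaturation off: ratio matches bookkeeping within 2%
  # (wide tail-capturing windows so the comparison tests the physics,
  # not the protocol's finite integration apertures)
  cfg <- fix_config(noise_sigma = 0, presat = FALSE)
  ser <- generate_calibration_series("glucose", c(50, 100, 200), cfg)
  sp <- ser$clean[[2]]
  ratio <- tsp_normalize(
    integrate_bucket(sp, 5.05, 5.45) -
      integrate_bucket(ser$water, 5.05, 5.45),
    integrate_bucket(sp, -0.2, 0.2))
  tsp_mM <- tsp_final_concentration(ser$recipe) / 1000
  expect_equal(ratio, theoretical_slope(tsp_mM) * 100, tolerance = 0.02)
})

test_that("constant-sum normalisation is scale-invariant with unit row sums", {
  m <- matrix(c(1, 3, 2, 6), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), NULL))
  out <- constant_sum_normalize(m)
  expect_equal(unname(out[1, ]), c(0.25, 0.75))
  expect_equal(out[1, ], out[2, ])        # doubling a row changes nothing
  expect_equal(unname(rowSums(out)), c(1, 1))
  one <- matrix(5, 1, 1)
  expect_equal(constant_sum_normalize(one)[1, 1], 1)
  m[2, ] <- 0
  expect_error(constant_sum_normalize(m), "s2",
               class = "lfnmr_validation_error")
})

test_that("anomer correction applies the 100/36 factor", {
  expect_equal(alpha_to_total_glucose(36), 100)
  expect_equal(round(alpha_to_total_glucose(1), 2), 2.78)
  expect_equal(alpha_to_total_glucose(0), 0)
  expect_error(alpha_to_total_glucose(-1),
               class = "lfnmr_validation_error")
})

test_that("calibration fitting reports LOD/LOQ from SNR and water overlap", {
  conc <- c(1, 5, 8, 10)
  ratios <- 0.08 * conc
  m <- fit_calibration(conc, ratios, snr = c(2, 12, 20, 30),
                       water_overlap = c(0.5, 0.12, 0.09, 0.05))
  expect_equal(m$slope, 0.08, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$r, 1)
  expect_equal(m$lod, 5)       # first SNR >= 3
  expect_equal(m$loq_snr, 5)   # first SNR >= 10
  expect_equal(m$loq, 8)       # raised until overlap < 10%
  expect_error(fit_calibration(c(1, 2), c(1, 2)),
               class = "lfnmr_validation_error")
  expect_error(fit_calibration(c(1, 1, 2), c(1, 1, 2)),
               class = "lfnmr_validation_error")
})

test_that("concentrations are recovered from the calibration line", {
  m <- fit_calibration(c(10, 20, 30), c(1.5, 2.5, 3.5), snr = c(20, 30, 40),
                       water_overlap = c(0, 0, 0))
  expect_equal(quantify_from_calibration(m$intercept, m)$concentration, 0)
  est <- quantify_from_calibration(m$slope * 50 + m$intercept, m)
  expect_equal(est$concentration, 50)
  expect_false(est$below_loq)
  low <- quantify_from_calibration(m$intercept - 1, m)
  expect_equal(low$concentration, 0)
  expect_true(low$clamped)
  bad <- m; bad$slope <- -1
  expect_error(quantify_from_calibration(1, bad),
               class = "lfnmr_validation_error")
})

test_that("quantification is linear above the LOQ", {
  cfg <- fix_config(noise_sigma = 0)
  ser <- generate_calibration_series("glucose", c(100, 200, 400), cfg)
  areas <- vapply(ser$clean, integrate_bucket, numeric(1), 5.17, 5.36)
  w <- integrate_bucket(ser$water, 5.17, 5.36)
  expect_equal((areas[3] - w) / (areas[2] - w), 2, tolerance = 0.01)
})

test_that("LOD and LOQ rise monotonically with the noise level", {
  conc <- c(2, 5, 8, 10, 20, 50)
  out <- lapply(c(5, 20, 80), function(sig) {
    ser <- generate_calibration_series(
      "glucose", conc, fix_config(noise_sigma = sig), seed = 9)
    calibration_from_series(ser)
  })
  lods <- vapply(out, `[[`, numeric(1), "lod")
  loqs <- vapply(out, `[[`, numeric(1), "loq_snr")
  expect_true(all(diff(lods) >= 0))
  expect_true(all(diff(loqs) >= 0))
})

test_that("the default bucket table matches the published layout", {
  bt <- default_bucket_table()
  expect_equal(nrow(bt$buckets), 27)
  expect_true(all(c("citrate", "creatinine", "glucose_bulk",
                    "glucose_c1h", "hippurate") %in% bt$buckets$label))
  cit <- bt$buckets[bt$buckets$label == "citrate", ]
  expect_equal(c(cit$low_ppm, cit$high_ppm), c(2.53, 2.70))
  expect_equal(range(bt$buckets$low_ppm, bt$buckets$high_ppm),
               c(1.03, 8.52))
  # overlapping buckets or bucket/exclusion clashes are rejected
  expect_error(bucket_table(data.frame(low_ppm = c(1, 1.5),
                                       high_ppm = c(1.6, 2),
                                       label = c("a", "b"))),
               class = "lfnmr_validation_error")
  expect_error(bucket_table(data.frame(low_ppm = 4.5, high_ppm = 4.6,
                                       label = "water")),
               class = "lfnmr_validation_error")
})

test_that("feature matrices carry state and creatinine normalisation flags overlap", {
  spec <- fix_small_cohort_spec()
  co <- generate_cohort(spec, fix_config(noise_sigma = 0), seed = 2)
  fm <- build_feature_matrix(co$spectra)
  expect_equal(attr(fm, "state"), "raw")
  fm_tsp <- normalize_features(fm, "tsp")
  expect_equal(attr(fm_tsp, "state"), c("raw", "tsp"))
  expect_error(normalize_features(fm_tsp, "csn"),
               class = "lfnmr_state_error")
  cn <- creatinine_normalize(fm)
  expect_true(attr(cn, "feasible"))
  # 3-HB / creatinine bucket ratio tracks the concentration ratio: both
  # buckets hold 3 protons, so the bucket ratio estimates conc ratio
  truth_ratio <- co$truth$hydroxybutyrate_3 / co$truth$creatinine
  expect_equal(unname(cn[, "hydroxybutyrate_3"]), truth_ratio,
               tolerance = 0.1)
})

test_that("creatinine normalisation warns at low field under high glucose", {
  spec <- cohort_spec(list(d = list(n = 2, metabolites = data.frame(
    metabolite = c("glucose", "creatinine"),
    mean_mM = c(155, 20), sd_mM = c(0, 0)))))
  co60 <- generate_cohort(spec, fix_config(noise_sigma = 0), seed = 1)
  fm60 <- build_feature_matrix(co60$spectra)
  expect_warning(out <- creatinine_normalize(fm60), "overlaps")
  expect_false(attr(out, "feasible"))
  # at 400 MHz the same samples normalise cleanly
  cfg400 <- fix_config(field_MHz = 400, presat_ppm = 4.80,
                       presat_power_dB = 50, noise_sigma = 0)
  co400 <- generate_cohort(spec, cfg400, seed = 1)
  fm400 <- build_feature_matrix(co400$spectra)
  expect_no_warning(out4 <- creatinine_normalize(fm400))
  expect_true(attr(out4, "feasible"))
  expect_error(creatinine_normalize(fm60[, setdiff(colnames(fm60),
                                                   "creatinine")]),
               class = "lfnmr_validation_error")
})
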