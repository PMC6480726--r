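# Exact-diagonalisation spectrum simulator and instrument-effect models.

test_that("an uncoupled spin gives one line at its Larmor frequency", {
  tr <- compute_transitions(fix_single_spin(1.00), 60)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$frequency_Hz, 60, tolerance = 1e-12)
  expect_equal(tr$intensity, 1, tolerance = 1e-9)
})

test_that("AB spin pairs match the closed-form solution", {
  for (delta_over_J in c(1, 0.5, 3)) {
    J <- 10
    want <- ab_closed_form(100, delta_over_J * J, J)
    got <- compute_transitions(fix_ab(100, delta_over_J * J, J), 60)
    expect_equal(got$frequency_Hz, sort(want$frequency_Hz),
                 tolerance = 1e-9)
    expect_equal(got$intensity,
                 want$intensity[order(want$frequency_Hz)],
                 tolerance = 1e-9)
  }
})

test_that("total transition intensity equals the proton count at any field", {
  lib <- metabolite_library()
  for (name in names(lib)) {
    expected <- sum(vapply(lib[[name]]$components, function(comp)
      comp$abundance * sum(vapply(comp$subsystems,
                                  function(s) sum(s$protons), 0)), 0))
    for (field in c(60, 400)) {
      lines <- metabolite_lines(name, field, library = lib)
      expect_equal(sum(lines$intensity), expected, tolerance = 1e-6,
                   info = paste(name, field))
    }
  }
})

test_that("chemical-shift separations scale with field; J splittings do not", {
  cn60 <- compute_transitions(
    spin_system(c("a", "b"), c(3.03, 4.05), c(3, 2)), 60)
  cn400 <- compute_transitions(
    spin_system(c("a", "b"), c(3.03, 4.05), c(3, 2)), 400)
  expect_equal(diff(cn400$frequency_Hz) / diff(cn60$frequency_Hz),
               400 / 60, tolerance = 1e-12)
  # doublet splitting in the weak-coupling regime is J at both fields
  for (field in c(300, 600)) {
    tr <- compute_transitions(
      spin_system(c("CH3", "CH"), c(1.48, 3.78), c(3, 1),
                  matrix(c(0, 7.23, 7.23, 0), 2)), field)
    ch3 <- tr[tr$frequency_Hz < 2 * field, ]
    expect_equal(diff(range(ch3$frequency_Hz[ch3$intensity > 0.1])),
                 7.23, tolerance = 0.05)
  }
})

test_that("weak coupling reproduces binomial multiplet intensities", {
  # ethanol CH3 triplet at 600 MHz: delta-nu/J ~ 200
  tr <- compute_transitions(fix_ethanol(), 600)
  ch3 <- tr[tr$frequency_Hz < 1000, ]
  center <- 1.19 * 600
  bins <- round((ch3$frequency_Hz - center) / 7.07)
  sums <- tapply(ch3$intensity, bins, sum)
  expect_equal(as.numeric(sums[c("-1", "0", "1")]) / 3,
               c(0.25, 0.5, 0.25), tolerance = 0.01)
  # outer-line span converges to the first-order value 2J
  span <- diff(range(ch3$frequency_Hz[ch3$intensity > 0.05]))
  expect_equal(span, 2 * 7.07, tolerance = 0.01 * 14.14)
})

test_that("oversized coupled blocks and invalid couplings are rejected", {
  J <- matrix(c(0, 5, 5, 0), 2)
  expect_error(
    compute_transitions(spin_system(c("a", "b"), c(1, 2), c(5, 4), J), 60),
    class = "lfnmr_size_error")
  badJ <- matrix(c(0, 5, 3, 0), 2)
  expect_error(spin_system(c("a", "b"), c(1, 2), c(1, 1), badJ),
               class = "lfnmr_validation_error")
  # an uncoupled group of 9 equivalent protons needs no joint Hamiltonian
  tsp <- compute_transitions(spin_system("tms", 0, 9), 60)
  expect_equal(tsp$intensity, 9)
})

test_that("presaturation retention hits its anchors and is monotone", {
  expect_equal(presat_attenuation(18, 58, 60), 0.42, tolerance = 1e-12)
  expect_equal(presat_attenuation(60, 50, 400), (36 / 64) * (43 / 57),
               tolerance = 1e-12)
  expect_gt(presat_attenuation(180, 50, 400), 0.99)
  expect_gte(presat_attenuation(1e4, 58, 60), 0.999)
  f <- presat_attenuation(seq(0, 200, by = 1), 58, 60)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(presat_attenuation(-1, 58, 60),
               class = "lfnmr_validation_error")
  # implied beta/alpha retention ratio at the 400 MHz default power
  ratio <- presat_attenuation(60, 50, 400) / presat_attenuation(180, 50, 400)
  expect_equal(ratio, 0.424, tolerance = 0.01)
})

test_that("T1 saturation follows saturation recovery and the Ernst law", {
  expect_equal(t1_saturation_factor(1, 5), 1 - exp(-5), tolerance = 1e-12)
  expect_equal(t1_saturation_factor(6.94, 6), 0.5788, tolerance = 1e-3)
  expect_equal(t1_saturation_factor(1.51, 6), 0.9812, tolerance = 1e-3)
  # slow-relaxing alpha-CH is suppressed below the 1:3 stoichiometry
  ratio <- (1 * t1_saturation_factor(6.94, 6)) /
    (3 * t1_saturation_factor(1.51, 6))
  expect_lt(ratio, 1 / 3)
  # Ernst expression reduces to saturation recovery at 90 degrees
  E <- exp(-2 / 1.5)
  expect_equal(t1_saturation_factor(1.5, 2, 89.999),
               sin(89.999 * pi / 180) * (1 - E) /
                 (1 - E * cos(89.999 * pi / 180)),
               tolerance = 1e-9)
  expect_error(t1_saturation_factor(-1, 5),
               class = "lfnmr_validation_error")
})

test_that("SNR scales with the square root of the scan count", {
  expect_equal(snr_scale(64, 256), 2)
  expect_equal(snr_scale(100, 100), 1)
  expect_equal(snr_scale(64, 128), sqrt(2))
  expect_error(snr_scale(0, 64), class = "lfnmr_validation_error")
})

test_that("rendering conserves area and flags out-of-axis transitions", {
  axis <- seq(0, 3, by = 0.0005)
  empty <- render_spectrum(data.frame(frequency_Hz = numeric(),
                                      intensity = numeric()),
                           axis, 0.55, 60)
  expect_true(all(empty$intensity == 0))
  one <- render_spectrum(data.frame(frequency_Hz = 90, intensity = 2),
                         axis, 0.55, 60)
  expect_equal(sum(diff(axis) * (one$intensity[-1] +
                                   one$intensity[-length(axis)]) / 2),
               2, tolerance = 0.02)
  expect_warning(
    out <- render_spectrum(data.frame(frequency_Hz = 500, intensity = 1),
                           axis, 0.55, 60),
    "outside")
  expect_true(attr(out, "truncated"))
})

test_that("FID synthesis round-trips through the Fourier transform", {
  cfg <- fix_config(sw_ppm = c(0, 4), acq_time_s = 6.4)
  tr <- compute_transitions(fix_ab(100, 10, 10), 60)
  fid <- synthesize_fid(tr, cfg)
  sp <- fourier_transform(fid)
  rendered <- render_spectrum(tr, sp$ppm, cfg$linewidth_Hz, cfg$field_MHz)
  dev <- max(abs(Re(sp$intensity) - rendered$intensity)) /
    max(rendered$intensity)
  expect_lt(dev, 0.02)
  # trivial cases
  fid0 <- synthesize_fid(data.frame(frequency_Hz = numeric(),
                                    intensity = numeric()), cfg)
  expect_true(all(fid0$signal == 0))
  expect_error(
    synthesize_fid(data.frame(frequency_Hz = 1e5, intensity = 1), cfg),
    class = "lfnmr_nyquist_error")
})
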