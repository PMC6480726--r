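# FID preprocessing chain: apodisation, FT, phasing, baseline, referencing.

make_fid <- function(lines_hz, intensities, cfg = fix_config(sw_ppm = c(0, 4))) {
  synthesize_fid(data.frame(frequency_Hz = lines_hz,
                            intensity = intensities), cfg)
}

measure_fwhm <- function(sp, around_ppm) {
  y <- Re(sp$intensity)
  x <- sp$ppm
  win <- which(abs(x - around_ppm) < 0.2)
  peak <- win[which.max(y[win])]
  half <- y[peak] / 2
  left <- peak; while (y[left] > half) left <- left - 1L
  right <- peak; while (y[right] > half) right <- right + 1L
  interp <- function(i, j) x[i] + (half - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
  interp(right - 1L, right) - interp(left, left + 1L)
}

test_that("zero-parameter apodisation is the identity", {
  fid <- make_fid(90, 1)
  for (k in c("exponential", "gaussian", "sine-bell"))
    expect_identical(apodize(fid, k, 0)$signal, fid$signal)
})

test_that("exponential apodisation adds its broadening to the linewidth", {
  cfg <- fix_config(sw_ppm = c(0, 4), linewidth_Hz = 0.55)
  fid <- make_fid(90, 1, cfg)
  sp0 <- fourier_transform(fid)
  sp1 <- fourier_transform(apodize(fid, "exponential", 1))
  expect_equal(measure_fwhm(sp0, 1.5) * 60, 0.55, tolerance = 0.05)
  expect_equal(measure_fwhm(sp1, 1.5) * 60, 1.55, tolerance = 0.05)
})

test_that("gaussian apodisation suppresses far-wing noise", {
  cfg <- fix_config(sw_ppm = c(0, 4))
  fid <- make_fid(90, 1, cfg)
  set.seed(42)
  n <- length(fid$signal)
  fid$signal <- fid$signal + complex(real = rnorm(n, 0, 0.05),
                                     imaginary = rnorm(n, 0, 0.05))
  raw <- fourier_transform(fid)
  apo <- fourier_transform(apodize(fid, "gaussian", 2))
  far <- which(raw$ppm > 2.5)  # signal-free
  expect_lt(sd(Re(apo$intensity[far])), sd(Re(raw$intensity[far])))
})

test_that("the Fourier transform places lines correctly and is linear", {
  fid <- make_fid(60, 1)
  sp <- fourier_transform(fid)
  expect_equal(sp$ppm[which.max(Re(sp$intensity))], 1.00,
               tolerance = 2 * diff(sp$ppm[1:2]))
  f1 <- make_fid(60, 1); f2 <- make_fid(120, 2)
  fsum <- f1; fsum$signal <- f1$signal + f2$signal
  lhs <- fourier_transform(fsum)$intensity
  rhs <- fourier_transform(f1)$intensity + fourier_transform(f2)$intensity
  expect_lt(max(Mod(lhs - rhs)), 1e-10 * max(Mod(rhs)))
})

test_that("known phase errors are recovered by auto-phasing", {
  fid <- make_fid(c(60, 90, 150), c(1, 2, 1))
  sp <- fourier_transform(fid)
  expect_identical(phase_correct(sp, 0, 0)$intensity, sp$intensity)
  rotated <- phase_correct(sp, ph0 = 30)
  # mis-phasing produces negative lobes
  expect_lt(min(Re(rotated$intensity)), -0.02 * max(Re(sp$intensity)))
  fixed <- phase_correct(rotated, auto = TRUE)
  ph <- attr(fixed, "phase")
  expect_equal(ph[1] %% 360, 330, tolerance = 1)
  # corrected spectrum is non-negative up to numerical ripple
  expect_gt(min(Re(fixed$intensity)), -0.01 * max(Re(fixed$intensity)))
})

test_that("auto-phasing a flat spectrum warns and returns the input", {
  flat <- nmr_spectrum(seq(0, 1, 0.01), rep(0 + 0i, 101))
  expect_warning(out <- phase_correct(flat, auto = TRUE), "flat")
  expect_equal(out$intensity, flat$intensity)
})

test_that("baseline correction removes offsets, drifts and curvature", {
  axis <- seq(0, 4, by = 0.001)
  peak <- render_spectrum(data.frame(frequency_Hz = 90, intensity = 1),
                          axis, 0.55, 60)
  # constant offset: removed exactly
  off <- peak; off$intensity <- off$intensity + 5
  fixed <- baseline_correct(off, "constant")
  expect_equal(fixed$intensity, peak$intensity - median(peak$intensity),
               tolerance = 1e-12)
  # pure linear drift: removed within 1e-6 by the polynomial mode
  drift <- nmr_spectrum(axis, 2 + 3 * axis)
  expect_lt(max(abs(baseline_correct(drift, "poly")$intensity)), 1e-6)
  # curved baseline under a peak: ALS residual < 5% of drift amplitude
  curved <- peak
  A <- 0.2 * max(peak$intensity)
  curved$intensity <- curved$intensity + A * sin(axis / 4 * pi)
  fixed <- baseline_correct(curved, "als")
  flank <- which(axis < 1 | axis > 2)
  expect_lt(max(abs(fixed$intensity[flank] - peak$intensity[flank])),
            0.05 * A)
})

test_that("TSP referencing recovers known axis shifts", {
  axis <- seq(-0.5, 2, by = 0.001)
  sp <- render_spectrum(data.frame(frequency_Hz = c(0, 60),
                                   intensity = c(9, 1)), axis, 0.55, 60)
  ref <- reference_to_tsp(sp)
  expect_lt(abs(ref$ppm[which.max(Re(ref$intensity))]), 1e-6)
  shifted <- sp; shifted$ppm <- sp$ppm + 0.02
  rec <- reference_to_tsp(shifted)
  expect_equal(attr(rec, "shift_applied_ppm"), -0.02, tolerance = 1e-3)
  # no TSP peak: explicit error
  bare <- render_spectrum(data.frame(frequency_Hz = 60, intensity = 1),
                          axis, 0.55, 60)
  expect_error(reference_to_tsp(bare), class = "lfnmr_reference_error")
})

test_that("the processing chain is idempotent at its fixed point", {
  axis <- seq(-0.5, 2, by = 0.001)
  sp <- render_spectrum(data.frame(frequency_Hz = c(0, 60),
                                   intensity = c(9, 1)), axis, 0.55, 60)
  once <- reference_to_tsp(baseline_correct(sp, "poly"))
  twice <- reference_to_tsp(baseline_correct(once, "poly"))
  expect_lt(max(abs(once$intensity - twice$intensity)), 1e-9)
  expect_lt(max(abs(once$ppm - twice$ppm)), 1e-6)
})

test_that("the full chain turns a synthetic FID into a quantifiable spectrum", {
  cfg <- fix_config(sw_ppm = c(-1, 5), noise_sigma = 0)
  tr <- rbind(data.frame(frequency_Hz = 0, intensity = 9),
              data.frame(frequency_Hz = 126, intensity = 3))
  fid <- synthesize_fid(tr, cfg)
  # the synthetic FID carries no baseline, so the chain uses the exact
  # constant mode; +/- 0.3 ppm captures 99% of a 0.55 Hz Lorentzian
  sp <- preprocess_fid(fid, baseline_method = "constant")
  expect_equal(integrate_bucket(sp, 1.8, 2.4), 3, tolerance = 0.02)
})
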