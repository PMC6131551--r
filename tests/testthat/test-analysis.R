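# Profile extraction, calibration and Lorentzian fitting.

et <- etalon_spec()
fsr <- free_spectral_range(et)
lay <- reference_layout(et)

test_that("dispersion row is located within one pixel and window size is benign", {
  src <- spectrum_model(shift = 7.41, elastic_amp = 1000, brillouin_amp = 100,
                        fsr = fsr)
  pat <- camera_pattern(et, aperture_mask(), lay, src)
  ex0 <- extract_dispersion_profile(pat, window_rows = 0)
  ex2 <- extract_dispersion_profile(pat, window_rows = 2)
  expect_lte(abs(ex0$dispersion_row - pat$dispersion_row), 1)
  expect_equal(which.max(ex0$profile), which.max(ex2$profile))
  # transposed frame recovered with the axis flag
  ext <- extract_dispersion_profile(t(pat$intensity), axis = "y")
  expect_equal(ext$profile, ex2$profile)
  # featureless frame: no second peak
  expect_error(extract_dispersion_profile(matrix(c(rep(0, 99), 1), 10, 10)),
               class = "bdb_extraction_error")
})

test_that("linear calibration round-trips generated mappings to 1e-6", {
  px <- 1:800
  c0 <- -1.5; c1 <- 34.4 / 800
  prof <- synth_spectrum(spectrum_model(shift = 7.4, fsr = fsr),
                         c0 + c1 * px)
  cal <- calibrate_axis(prof, fsr = fsr)
  expect_lt(abs(cal$coeffs[1] - c0) / abs(c0), 1e-6)
  expect_lt(abs(cal$coeffs[2] - c1) / c1, 1e-6)
  # water anchor: the Brillouin pair averages to the reference by construction
  nu_b <- predict(cal, cal$rayleigh_px)
  expect_equal(nu_b, c(0, fsr), tolerance = 1e-6)
})

test_that("quadratic refinement absorbs a 1% distortion (rms drops >= 10x)", {
  px <- 1:800
  c0 <- -1.5; c1 <- 34.4 / 800
  nu_true <- c0 + c1 * px + 0.01 * c1 * px^2 / 800
  prof <- synth_spectrum(spectrum_model(shift = 7.4, fsr = fsr), nu_true)
  cal_l <- calibrate_axis(prof, fsr = fsr, refine = "linear")
  cal_q <- calibrate_axis(prof, fsr = fsr, refine = "quadratic")
  expect_gt(cal_l$rms_residual / cal_q$rms_residual, 10)
  # refined mapping stays monotonic over the pixel range
  d <- diff(predict(cal_q, px))
  expect_true(all(d > 0))
})

test_that("calibration is invariant under integer pixel shifts", {
  px <- 1:900
  c1 <- 34.4 / 900
  prof <- function(off) synth_spectrum(water_model(),
                                       -2 + c1 * (px - off))
  f1 <- fit_spectrum(prof(0), calibration = calibrate_axis(prof(0), fsr))
  f2 <- fit_spectrum(prof(25), calibration = calibrate_axis(prof(25), fsr))
  expect_lt(abs(f1$shift - f2$shift), 1e-6)
})

test_that("noiseless fits recover shift and width over the physiological grid", {
  f <- default_axis()
  for (shift in c(5, 7.41, 9.5, 12)) {
    for (width in c(0.3, 0.8, 2)) {
      m <- spectrum_model(shift = shift, linewidth = width,
                          instrument_width = 0.3, fsr = fsr)
      ft <- fit_spectrum(synth_spectrum(m, f), freq = f)
      expect_true(ft$converged)
      expect_lt(abs(ft$shift - shift), 1e-4)
      expect_lt(abs(ft$linewidth - (width + 0.3)), 1e-4)
      expect_gt(ft$r_squared, 1 - 1e-10)
    }
  }
})

test_that("water-like spectra return the observed 0.80 GHz width", {
  f <- default_axis()
  ft <- fit_spectrum(synth_spectrum(water_model(), f), freq = f)
  expect_lt(abs(ft$shift - 7.41), 1e-4)
  expect_lt(abs(ft$linewidth - 0.80), 1e-4)
})

test_that("Monte-Carlo: unbiased mean, calibrated errors, S/AS symmetry", {
  f <- default_axis(by = 0.03)
  m <- spectrum_model(shift = 7.80, linewidth = 0.5, instrument_width = 0.3,
                      fsr = fsr, elastic_amp = 4000, brillouin_amp = 400)
  s0 <- synth_spectrum(m, f)
  n_rep <- 300
  res <- vapply(seq_len(n_rep), function(i) {
    sp <- add_noise(s0, noise_model(seed = 1000 + i))
    ft <- fit_spectrum(sp, freq = f, weighting = "shot", read_sigma = 2)
    c(ft$shift, ft$shift_se, ft$offsets, ft$offset_se)
  }, numeric(6))
  expect_lt(abs(mean(res[1, ]) - 7.80), 0.01)
  # reported standard error tracks the empirical scatter within 30%
  expect_lt(abs(mean(res[2, ]) - sd(res[1, ])) / sd(res[1, ]), 0.3)
  # Stokes/anti-Stokes agreement inside 3 combined standard errors (99%-ish)
  dsym <- abs(res[3, ] - res[4, ])
  se_c <- sqrt(res[5, ]^2 + res[6, ]^2)
  expect_gt(mean(dsym < 3 * se_c), 0.9)
})

test_that("estimator scatter shrinks as 1/sqrt(amplitude)", {
  f <- default_axis(by = 0.03)
  sds <- vapply(c(40, 400, 4000), function(amp) {
    m <- spectrum_model(shift = 7.8, linewidth = 0.5, instrument_width = 0.3,
                        fsr = fsr, elastic_amp = 10 * amp,
                        brillouin_amp = amp)
    s0 <- synth_spectrum(m, f)
    sh <- vapply(1:60, function(i) {
      fit_spectrum(add_noise(s0, noise_model(seed = 50 + i)), freq = f)$shift
    }, numeric(1))
    sd(sh)
  }, numeric(1))
  # each decade of amplitude buys roughly sqrt(10) in precision
  expect_gt(sds[1] / sds[2], sqrt(10) / 2)
  expect_gt(sds[2] / sds[3], sqrt(10) / 2)
  expect_true(all(diff(sds) < 0))
})

test_that("saturated Rayleigh samples are excluded but the fit still succeeds", {
  f <- default_axis()
  m <- spectrum_model(shift = 7.41, elastic_amp = 5000, brillouin_amp = 100,
                      fsr = fsr)
  s <- pmin(synth_spectrum(m, f), 3000)
  ft <- fit_spectrum(s, freq = f, saturation = 3000)
  expect_true(ft$saturated)
  expect_true(ft$converged)
  expect_lt(abs(ft$shift - 7.41), 5e-3)
})

test_that("detectability follows the spectrometer contrast (turbidity scenario)", {
  f <- default_axis()
  bril <- 200
  m <- spectrum_model(shift = 7.41, linewidth = 0.5, instrument_width = 0.3,
                      elastic_amp = bril * 1e5, brillouin_amp = bril,
                      fsr = fsr)
  det <- function(contrast) {
    s <- crosstalk_spectrum(m, contrast, f)
    sn <- add_noise(s, noise_model(read_sigma = 0, saturation = Inf,
                                   seed = 7))
    detectability(sn, f)
  }
  d_lo <- det(1e3); d_hi <- det(1e7)
  expect_false(d_lo$detectable)
  expect_true(d_hi$detectable)
  expect_gt(d_hi$snr, 5)
  # no Brillouin signal is never detectable
  s0 <- synth_spectrum(spectrum_model(brillouin_amp = 0), f)
  expect_false(detectability(s0, f)$detectable)
  # noiseless background-free doublet: infinite-SNR sentinel
  dn <- detectability(synth_spectrum(water_model(), f), f)
  expect_true(dn$detectable)
  expect_gt(dn$snr, 100)
})
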