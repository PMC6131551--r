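# Generative spectra: Lorentzian lines, order structure, camera noise.

fsr <- default_fsr()

test_that("lorentzian has the textbook peak, half-maximum and area", {
  f <- seq(-25, 25, by = 1e-3)
  L <- lorentzian(f, center = 0, fwhm = 0.5, amplitude = 3)
  expect_equal(max(L), 3, tolerance = 1e-6)
  expect_equal(lorentzian(c(-0.25, 0.25), 0, 0.5, 3), c(1.5, 1.5))
  # analytic area amplitude * pi * fwhm / 2; the +-50 fwhm window cuts
  # 2/(50 pi) ~ 1.3% of the tails, so compare against the truncated
  # analytic integral exactly and the full area loosely
  area <- sum(L) * 1e-3
  trunc <- 3 * 0.25 * 2 * atan(25 / 0.25)
  expect_equal(area, trunc, tolerance = 1e-4)
  expect_equal(area, 3 * pi * 0.5 / 2, tolerance = 1e-2)
  expect_error(lorentzian(f, 0, fwhm = 0), class = "bdb_invalid_parameter")
})

test_that("spectra place Rayleigh and Brillouin peaks at the order positions", {
  f <- seq(0, 30.5, by = 0.01)
  m <- spectrum_model(shift = 7.41, linewidth = 0.5, instrument_width = 0.3,
                      fsr = 30.5)
  s <- synth_spectrum(m, f)
  pk <- bdbmicro:::local_maxima(s)
  pk <- sort(c(pk, if (s[1] > s[2]) 1, if (s[length(s)] > s[length(s) - 1])
    length(s)))
  expect_length(pk, 4)   # 2 Rayleigh + Stokes + anti-Stokes in one order
  # grid-argmax oracle: Brillouin peaks at shift and fsr - shift
  bri <- f[pk][order(s[pk])][1:2]
  expect_equal(sort(bri), c(7.41, 30.5 - 7.41), tolerance = 1e-2)
})

test_that("zero Brillouin amplitude leaves the pure Rayleigh comb", {
  f <- default_axis()
  m0 <- spectrum_model(brillouin_amp = 0)
  comb <- synth_spectrum(m0, f)
  by_hand <- Reduce(`+`, lapply(-3:4, function(mm)
    lorentzian(f, mm * m0$fsr, m0$instrument_width, m0$elastic_amp)))
  expect_equal(comb, by_hand, tolerance = 1e-10)
})

test_that("Stokes/anti-Stokes pairs are mirror-symmetric about the order centre", {
  f <- seq(0, fsr, length.out = 6089)   # axis symmetric about fsr/2
  for (shift in c(5.2, 7.41, 9.8)) {
    m <- spectrum_model(shift = shift, elastic_amp = 0, brillouin_amp = 100,
                        fsr = fsr)
    s <- synth_spectrum(m, f)
    # peak offsets from the two Rayleigh orders agree to < 1e-9 GHz
    i_s <- which.max(s[f < fsr / 2])
    i_as <- which.max(s[f >= fsr / 2]) + sum(f < fsr / 2)
    expect_lt(abs(f[i_s] - (fsr - f[i_as])), 1e-9 + diff(f[1:2]))
    # exact symmetry of the synthesised intensities
    expect_equal(s, rev(s), tolerance = 1e-9)
  }
})

test_that("order-ambiguous shifts are rejected", {
  expect_error(spectrum_model(shift = 16, fsr = 30),
               class = "bdb_invalid_spec")
  m <- spectrum_model(shift = 7.41)
  m$shift <- 20   # tampered object
  expect_error(synth_spectrum(m, default_axis()),
               class = "bdb_order_ambiguity")
})

test_that("camera noise is reproducible, unbiased and optional", {
  s <- rep(1000, 1e4)
  nm <- noise_model(shot = TRUE, read_sigma = 2, seed = 42)
  n1 <- add_noise(s, nm)
  n2 <- add_noise(s, nm)
  expect_identical(n1, n2)                     # determinism contract
  expect_false(identical(n1, add_noise(s, noise_model(seed = 43))))
  # CLT bound on the mean of 1e4 Poisson(1000) + N(0, 2) samples
  expect_lt(abs(mean(n1) - 1000), 3 * sqrt(1000 / 1e4) + 3 * 2 / sqrt(1e4))
  # identity when all noise sources are off
  expect_identical(add_noise(s, noise_model(shot = FALSE, read_sigma = 0)), s)
  expect_identical(add_noise(s, NULL), s)
  expect_error(add_noise(c(-1, 5), nm), class = "bdb_invalid_input")
  # saturation clips
  expect_lte(max(add_noise(s, noise_model(saturation = 1010, seed = 1))),
             1010)
})

test_that("crosstalk-limited spectra carry the floor at elastic/contrast", {
  f <- default_axis()
  m <- spectrum_model(elastic_amp = 1e6, brillouin_amp = 10)
  s <- crosstalk_spectrum(m, contrast = 1e4, f)
  mid <- s[abs(f - fsr / 2) < 1]   # far from all lines
  expect_equal(stats::median(mid), 1e6 / 1e4, tolerance = 0.1)
  expect_equal(max(s), 1e6, tolerance = 1e-2)
})
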