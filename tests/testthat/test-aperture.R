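# Fraunhofer kernels: closed forms, FFT cross-check, tails, excess loss.

lay <- reference_layout()
lf <- lay$wavelength * lay$focal_length

test_that("circular kernel has its first zero at 1.22 lambda f / D", {
  m <- aperture_mask("circular", 4e-3, 4e-3)
  x <- seq(0, 6e-5, by = 5e-8)
  k <- aperture_kernel(m, lay, x = x, y = 0)
  i0 <- which(diff(sign(diff(k$intensity[1, ]))) == 2)[1] + 1
  expect_equal(x[i0], 1.22 * lf / 4e-3, tolerance = 1e-2)
})

test_that("rhomboid kernel zeros sit at k lambda f / (width/2) on the diagonal", {
  m <- aperture_mask()  # 8 x 4 mm, long diagonal on the dispersion axis
  a <- m$width / 2
  x <- seq(1e-6, 4.5 * lf / a, by = 2e-7)
  k <- aperture_kernel(m, lay, x = x, y = 0)
  zeros <- x[which(diff(sign(diff(k$intensity[1, ]))) == 2) + 1]
  expect_equal(zeros[1:4], (1:4) * lf / a, tolerance = 5e-3)
})

test_that("discrete-transform kernels match the closed forms", {
  for (m in list(aperture_mask("circular", 4e-3, 4e-3),
                 aperture_mask("rectangular", 6e-3, 3e-3))) {
    kf <- aperture_kernel(m, lay, method = "fft")
    ext <- if (m$shape == "circular") 4e-3 else 6e-3
    lim <- 10.5 * lf / ext             # first ~10 lobes
    selx <- abs(kf$x) <= lim
    sely <- abs(kf$y) <= lim
    ka <- aperture_kernel(m, lay, x = kf$x[selx], y = kf$y[sely])
    expect_lt(max(abs(ka$intensity - kf$intensity[sely, selx])), 1e-3)
  }
})

test_that("kernel energy matches the aperture-plane prediction (Parseval)", {
  # for a unit-peak kernel the camera-plane integral is (lambda f)^2 / area
  cases <- list(
    list(m = aperture_mask(), area = 2 * 4e-3 * 2e-3),
    list(m = aperture_mask("circular", 4e-3, 4e-3), area = pi * 2e-3^2))
  for (cs in cases) {
    k <- aperture_kernel(cs$m, lay, method = "fft")
    tot <- sum(k$intensity) * k$camera_step^2
    expect_equal(tot, lf^2 / cs$area, tolerance = 1e-2)
  }
})

test_that("far-tail decay exponents are -3 (circle), -2 (rect), -4 (rhomboid)", {
  expect_equal(tail_exponent(aperture_mask("circular", 4e-3, 4e-3), lay),
               -3, tolerance = 0.15 / 3)
  expect_equal(tail_exponent(aperture_mask("rectangular", 6e-3, 3e-3), lay),
               -2, tolerance = 0.15 / 2)
  expect_equal(tail_exponent(aperture_mask(), lay), -4, tolerance = 0.2 / 4)
})

test_that("aperture sampling errors are caught", {
  m <- aperture_mask()
  coarse <- seq(-1e-3, 1e-3, by = 5e-5)   # 50 um >> Nyquist 13.3 um
  expect_error(aperture_kernel(m, lay, x = coarse, y = 0),
               class = "bdb_aliasing_error")
  expect_error(aperture_kernel(aperture_mask("none"), lay),
               class = "bdb_invalid_spec")
  expect_error(aperture_mask("circular", width = 0, height = 1e-3),
               class = "bdb_invalid_spec")
})

test_that("mask rotation is normalised to [0, pi)", {
  expect_equal(aperture_mask(rotation = pi + 0.3)$rotation, 0.3)
  expect_equal(aperture_mask(rotation = -0.3)$rotation, pi - 0.3)
})

test_that("excess loss is 0 for open/huge apertures and matches the Gaussian overlap", {
  expect_equal(excess_loss(aperture_mask("none"), lay), 0)
  big <- aperture_mask("rectangular", 0.1, 0.1)
  expect_lt(excess_loss(big, lay), 1e-6)
  # independent quadrature oracle for the 8 x 4 mm rhomboid, 2.2 mm beam
  expect_equal(excess_loss(aperture_mask(), lay), 0.836, tolerance = 3e-3)
  # the illumination radius that documents a 2.5 dB loss
  w25 <- solve_beam_radius(aperture_mask(), 2.5)
  expect_equal(w25, 3.32e-3, tolerance = 2e-3)
  lay25 <- optical_layout(beam_radius = w25)
  expect_equal(excess_loss(aperture_mask(), lay25), 2.5, tolerance = 1e-3)
})
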