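# Camera patterns and spectral-contrast metrics.

et <- etalon_spec()
fsr <- free_spectral_range(et)
lay <- reference_layout(et)
mono <- spectrum_model(elastic_amp = 1, brillouin_amp = 0)

test_that("open-pupil dispersion profile equals the Airy transfer function", {
  pat <- camera_pattern(et, aperture_mask("none"), lay, mono)
  prof <- pat$intensity[pat$dispersion_row, ]
  expect_equal(prof, airy_transfer(et, pat$freq_map)$transmission,
               tolerance = 1e-12)
})

test_that("monochromatic patterns show two order peaks one FSR apart", {
  for (mask in list(aperture_mask("none"), aperture_mask(),
                    aperture_mask("circular", 4e-3, 4e-3))) {
    pat <- camera_pattern(et, mask, lay, mono)
    prof <- pat$intensity[pat$dispersion_row, ]
    inwin <- which(pat$freq_map > -2 & pat$freq_map < fsr + 2)
    pk <- inwin[bdbmicro:::local_maxima(prof[inwin])]
    pk <- pk[order(prof[pk], decreasing = TRUE)][1:2]
    sep <- abs(diff(pat$freq_map[pk]))
    expect_equal(sep, fsr, tolerance = 1e-2)
  }
})

test_that("order-peak positions do not depend on the mask", {
  peak_pos <- function(mask) {
    pat <- camera_pattern(et, mask, lay, mono)
    prof <- pat$intensity[pat$dispersion_row, ]
    pat$freq_map[which.max(prof)]
  }
  p_rh <- peak_pos(aperture_mask())
  p_ci <- peak_pos(aperture_mask("circular", 4e-3, 4e-3))
  expect_equal(p_rh, p_ci, tolerance = 1e-6)
})

test_that("idealized delta-kernel contrast at FSR/2 reduces to 1 + F", {
  pat <- camera_pattern(et, aperture_mask("none"), lay, mono)
  ctr <- spectral_contrast(pat, c(fsr / 2 - 1, fsr / 2 + 1))
  # band mean of the Airy floor slightly exceeds the exact minimum
  expect_equal(ctr, 1 + et$F, tolerance = 0.15)
  expect_lt(ctr, 1 + et$F)
})

test_that("contrast is invariant under intensity scaling", {
  pat <- camera_pattern(et, aperture_mask(), lay, mono)
  c1 <- spectral_contrast(pat, c(5, 25))
  pat$intensity <- pat$intensity * 137.5
  expect_equal(spectral_contrast(pat, c(5, 25)), c1, tolerance = 1e-12)
})

test_that("bands touching a spectral line are rejected", {
  src <- spectrum_model(shift = 7.41, elastic_amp = 1, brillouin_amp = 0.1,
                        fsr = fsr)
  pat <- camera_pattern(et, aperture_mask(), lay, src)
  expect_error(spectral_contrast(pat, c(7, 12)), class = "bdb_invalid_band")
  expect_error(spectral_contrast(pat, c(-1, 5)), class = "bdb_invalid_band")
  expect_silent(spectral_contrast(pat, c(9, 21)))
})

test_that("rhomboid mask beats the circular baseline and the identity holds", {
  rh <- aperture_mask()
  ci <- aperture_mask("circular", 4e-3, 4e-3)
  expect_equal(contrast_enhancement(rh, rh, et, lay), 0, tolerance = 1e-9)
  e_ab <- contrast_enhancement(rh, ci, et, lay)
  e_ba <- contrast_enhancement(ci, rh, et, lay)
  expect_equal(e_ab, -e_ba, tolerance = 1e-9)   # antisymmetric
  expect_gt(e_ab, 15)                           # strong suppression
  # enhancement grows as the band moves into the far tails
  lows <- c(4, 6, 8, 10, 12)
  e <- vapply(lows, function(lo)
    contrast_enhancement(rh, ci, et, lay, band = c(lo, lo + 8)), numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("masked contrast exceeds the unmasked etalon-limited contrast", {
  rh <- camera_pattern(et, aperture_mask(), lay, mono)
  un <- camera_pattern(et, aperture_mask("none"), lay, mono)
  for (band in list(c(2.5, 4), c(3, 8), c(5, 25), c(12, 18), c(20, 28))) {
    expect_gt(spectral_contrast(rh, band), spectral_contrast(un, band))
  }
})

test_that("rotating the rhomboid away from reference drops the on-axis contrast", {
  ref <- camera_pattern(et, aperture_mask(), lay, mono)
  rot <- camera_pattern(et, aperture_mask(rotation = pi / 4), lay, mono)
  expect_gt(spectral_contrast(ref, c(5, 25)),
            2 * spectral_contrast(rot, c(5, 25)))
})
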