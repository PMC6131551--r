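# Cell phantoms: geometry, determinism, partial-volume blur, raster scan.

test_that("phantoms are deterministic and respect granule requests", {
  p1 <- small_cell_phantom(seed = 7)
  p2 <- small_cell_phantom(seed = 7)
  expect_identical(p1$labels, p2$labels)
  p3 <- small_cell_phantom(seed = 8)
  expect_false(identical(p1$labels, p3$labels))
  # zero granules requested -> no label-4 voxels
  p0 <- synth_phantom(dim_vox = c(6, 24, 24), n_granules = 0,
                      n_nucleoli = 1, nucleolus_radius_um = 0.8, seed = 1)
  expect_equal(sum(p0$labels == 4L), 0)
  # all labels present are covered by the truth table
  expect_true(all(unique(as.integer(p1$labels)) %in% p1$truth$label))
})

test_that("requested granule volume fraction is realised within 0.5% absolute", {
  ph <- synth_phantom(dim_vox = c(12, 40, 40),
                      granule_volume_fraction = 0.01, seed = 5)
  cyto <- sum(ph$labels %in% c(1L, 4L))
  frac <- sum(ph$labels == 4L) / cyto
  expect_lt(abs(frac - 0.01), 0.005)
})

test_that("impossible granule placement raises a placement error", {
  # cytoplasm shell far too thin for 2 um granules
  expect_error(
    synth_phantom(dim_vox = c(2, 8, 8), n_granules = 5, n_nucleoli = 0,
                  nucleus_scale = 0.98,
                  granule_diameter_um = c(2, 2), seed = 1),
    class = "bdb_placement_error")
})

test_that("periodic Gaussian blur conserves the volume mean", {
  set.seed(3)
  v <- array(runif(10 * 20 * 20), c(10, 20, 20))
  vb <- blur_volume(v, c(1.1, 0.3, 0.3), c(1.0, 0.4, 0.4))
  expect_lt(abs(mean(vb) - mean(v)), 1e-6)
  expect_equal(dim(vb), dim(v))
  # zero-width PSF is the identity
  expect_identical(blur_volume(v, c(0, 0, 0), c(1, 0.4, 0.4)), v)
})

test_that("partial-volume blur attenuates sub-resolution granule contrast", {
  # a granule thinner than the axial PSF cannot keep its full +0.3 GHz step
  tr <- default_truth_table()
  tr$shift_GHz[tr$label == 4] <- tr$shift_GHz[tr$label == 2] + 0.3
  dimv <- c(9, 9, 9)
  lab <- array(2L, dimv)                       # nucleus-filled background
  lab[5, 5, 5] <- 4L                           # one 0.4 x 0.4 x 1 um voxel
  ph <- uniform_phantom(7.8)
  ph$labels <- lab
  ph$truth <- tr
  scan <- phantom_to_spectra(ph, water_model(), apply_psf = TRUE,
                             freq = seq(-2, default_fsr() + 2, by = 0.1))
  delta <- max(scan$shift_true) - tr$shift_GHz[tr$label == 2]
  expect_lt(delta, 0.3)
  expect_gt(delta, 0)
  # with the PSF off, the truth map equals the label truth exactly
  scan0 <- phantom_to_spectra(ph, water_model(), apply_psf = FALSE,
                              freq = seq(-2, default_fsr() + 2, by = 0.1))
  expect_equal(max(scan0$shift_true), tr$shift_GHz[tr$label == 4])
})

test_that("uniform phantoms give identical spectra at every voxel", {
  ph <- uniform_phantom(7.8, dim_vox = c(2, 4, 4))
  scan <- phantom_to_spectra(ph, water_model(), apply_psf = FALSE)
  expect_equal(ncol(scan$spectra), 32)
  expect_true(all(apply(scan$spectra, 1, function(r) diff(range(r)) == 0)))
})
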