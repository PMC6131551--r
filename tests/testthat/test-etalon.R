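# Etalon spectral behaviour: free spectral range and Airy transfer function.

test_that("free spectral range follows c/(2nL cos tilt)", {
  # air-spaced 15 cm cavity: exactly 1 GHz
  expect_equal(free_spectral_range(etalon_spec(thickness = 0.15,
                                               n_etalon = 1)), 0.999308,
               tolerance = 1e-3)
  # the fused-silica 3.371 mm etalon lands near 30.4 GHz
  expect_equal(free_spectral_range(etalon_spec()), 30.44, tolerance = 1e-3)
  # doubling the thickness halves the FSR exactly
  et1 <- etalon_spec(thickness = 2e-3)
  et2 <- etalon_spec(thickness = 4e-3)
  expect_equal(free_spectral_range(et1) / free_spectral_range(et2), 2,
               tolerance = 1e-12)
})

test_that("invalid etalon specifications are rejected", {
  expect_error(etalon_spec(thickness = -1), class = "bdb_invalid_spec")
  expect_error(etalon_spec(R1 = 1.2), class = "bdb_invalid_spec")
  expect_error(etalon_spec(R2 = 0), class = "bdb_invalid_spec")
  expect_error(etalon_spec(n_etalon = 0.5), class = "bdb_invalid_spec")
})

test_that("Airy transfer function peaks at 1 and bottoms at 1/(1+F)", {
  et <- default_etalon()
  fsr <- free_spectral_range(et)
  tf <- airy_transfer(et, c(0, fsr / 2, fsr))
  expect_equal(tf$transmission[1], 1)
  expect_equal(tf$transmission[3], 1, tolerance = 1e-12)
  expect_equal(tf$transmission[2], 1 / (1 + et$F), tolerance = 1e-12)
  # R1 = 99.9%, R2 = 96% gives an etalon-limited contrast near 9.15e3
  expect_equal(1 + et$F, 9.15e3, tolerance = 1e-3)
})

test_that("transfer function is FSR-periodic and unimodal per order", {
  et <- default_etalon()
  fsr <- free_spectral_range(et)
  nu <- seq(-fsr, 2 * fsr, length.out = 4001)
  t1 <- airy_transfer(et, nu)$transmission
  t2 <- airy_transfer(et, nu + fsr)$transmission
  expect_lt(max(abs(t1 - t2)), 1e-12)
  half <- airy_transfer(et, seq(1e-3, fsr / 2, length.out = 500))$transmission
  expect_true(all(diff(half) < 0))   # strictly decreasing on (0, FSR/2)
})
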