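# Brillouin observables <-> longitudinal mechanics.

test_that("water at 532 nm gives the canonical 7.41 GHz shift", {
  expect_equal(shift_from_velocity(1.33, 1482, 532e-9), 7.41,
               tolerance = 1e-3)
  expect_equal(shift_from_velocity(1.33, 0), 0)
})

test_that("shift <-> velocity <-> modulus round trips are exact", {
  for (shift in c(5.5, 7.41, 9.9)) {
    v <- velocity_from_shift(shift, 1.36)
    expect_equal(shift_from_velocity(1.36, v), shift, tolerance = 1e-12)
    mp <- modulus_real_from_shift(shift, 1.36, 1050)
    expect_equal(sqrt(mp / 1050), v, tolerance = 1e-12)
  }
})

test_that("water longitudinal moduli have the expected magnitudes", {
  expect_equal(modulus_real_from_shift(7.41, 1.33, 998) / 1e9, 2.19,
               tolerance = 2e-3)
  expect_equal(modulus_imag_from_linewidth(7.41, 0.5, 1.33, 998) / 1e9,
               0.148, tolerance = 3e-3)
  expect_equal(modulus_imag_from_linewidth(7.41, 0, 1.33, 998), 0)
})

test_that("moduli scale quadratically in shift and linearly in density/width", {
  m1 <- modulus_real_from_shift(4, 1.35, 1000)
  expect_equal(modulus_real_from_shift(8, 1.35, 1000) / m1, 4)
  expect_equal(modulus_real_from_shift(4, 1.35, 2000) / m1, 2)
  i1 <- modulus_imag_from_linewidth(7.4, 0.4, 1.35, 1000)
  expect_equal(modulus_imag_from_linewidth(7.4, 0.8, 1.35, 1000) / i1, 2)
  # at equal shift/density, M'' ratio equals the linewidth ratio
  r <- modulus_imag_from_linewidth(8.1, 1.13, 1.37, 1050) /
    modulus_imag_from_linewidth(8.1, 0.86, 1.37, 1050)
  expect_equal(r, 1.13 / 0.86, tolerance = 1e-12)
})

test_that("q ratio obeys identity, reciprocity and the cytoplasm value", {
  expect_equal(q_ratio(7.8, 7.8), 1)
  expect_equal(q_ratio(7.8 * 1.049, 7.8), 1.049, tolerance = 1e-12)
  expect_equal(q_ratio(8.1, 7.7) * q_ratio(7.7, 8.1), 1, tolerance = 1e-12)
  expect_error(q_ratio(7.8, 0), class = "bdb_invalid_input")
  expect_equal(q_ratio(7.8, 7.8, volume_correction = 1.02), 1.02)
})

test_that("relative index and velocity sensitivities add (finite differences)", {
  n0 <- 1.36; v0 <- 1550
  b0 <- shift_from_velocity(n0, v0)
  dn <- 0.015
  expect_equal(shift_from_velocity(n0 * (1 + dn), v0) / b0 - 1, dn,
               tolerance = 1e-9)
  dv <- 0.01
  both <- shift_from_velocity(n0 * (1 + dn), v0 * (1 + dv)) / b0 - 1
  # first order in the perturbations; the dn*dv cross term is 1.5e-4
  expect_equal(both, dn + dv, tolerance = 0.01)
})

test_that("confocal resolution reproduces the instrument's 0.3 x 1.1 um figures", {
  r <- confocal_resolution(532e-9, na = 1, n_imm = 1.518)
  expect_equal(round(unname(r["lateral_um"]), 1), 0.3)
  expect_equal(round(unname(r["axial_um"]), 1), 1.1)
})

test_that("the shipped materials table is readable and consistent", {
  mat <- brillouin_materials()
  w <- mat[mat$material == "water", ]
  expect_equal(shift_from_velocity(w$n, w$velocity_m_s), 7.41,
               tolerance = 1e-3)
})
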