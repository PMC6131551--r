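# Conversions between Brillouin observables and longitudinal mechanics.
#
# Backscattering geometry at ordinary frequencies: nu_B = 2 n V / lambda.
# The acoustic velocity is V = sqrt(M'/rho), so
#   M'  = rho (lambda nu_B / (2 n))^2
#   M'' = rho (lambda / (2 n))^2 nu_B dnu_B      (hypersonic damping relation)
# with dnu_B the Brillouin FWHM.

#' Brillouin shift from acoustic velocity
#'
#' Backscattering relation `nu_B = 2 n V / lambda`. For water
#' (`n = 1.33`, `V = 1482 m/s`) at 532 nm this gives 7.41 GHz.
#'
#' @param n refractive index (>= 1).
#' @param velocity acoustic velocity (m/s).
#' @param wavelength laser wavelength (m).
#' @return Brillouin shift (GHz).
#' @examples
#' shift_from_velocity(1.33, 1482) # 7.41
#' @export
shift_from_velocity <- function(n, velocity, wavelength = 532e-9) {
  if (any(wavelength <= 0))
    bdb_stop("'wavelength' must be > 0", "bdb_invalid_input")
  2 * n * velocity / wavelength / 1e9
}

#' Acoustic velocity from Brillouin shift
#'
#' Inverse of [shift_from_velocity()].
#'
#' @param shift Brillouin shift (GHz).
#' @inheritParams shift_from_velocity
#' @return acoustic velocity (m/s).
#' @export
velocity_from_shift <- function(shift, n, wavelength = 532e-9) {
  shift * 1e9 * wavelength / (2 * n)
}

#' Storage (real) longitudinal modulus from the Brillouin shift
#'
#' `M' = rho V^2 = rho (lambda nu_B / (2 n))^2`. A measure of high-frequency
#' stiffness; quadratic in the shift, linear in density.
#'
#' @param shift Brillouin shift (GHz).
#' @param n refractive index.
#' @param rho mass density (kg/m^3).
#' @param wavelength laser wavelength (m).
#' @return M' in Pa.
#' @examples
#' modulus_real_from_shift(7.41, 1.33, 998) / 1e9 # ~2.19 GPa (water)
#' @export
modulus_real_from_shift <- function(shift, n, rho, wavelength = 532e-9) {
  v <- velocity_from_shift(shift, n, wavelength)
  rho * v^2
}

#' Loss (imaginary) longitudinal modulus from the Brillouin linewidth
#'
#' Standard hypersonic-damping relation
#' `M'' = rho (lambda / (2 n))^2 nu_B dnu_B`, proportional to the linewidth
#' at fixed shift; `dnu_B = 0` is the lossless limit. The linewidth tracks
#' viscosity and hence the condensation state of the material.
#'
#' @param shift Brillouin shift nu_B (GHz).
#' @param linewidth Brillouin FWHM dnu_B (GHz).
#' @inheritParams modulus_real_from_shift
#' @return M'' in Pa.
#' @export
modulus_imag_from_linewidth <- function(shift, linewidth, n, rho,
                                        wavelength = 532e-9) {
  rho * (wavelength / (2 * n))^2 * (shift * 1e9) * (linewidth * 1e9)
}

#' Fixed-to-living frequency ratio q
#'
#' `q = nu_fixed / nu_living`, the per-compartment ratio quantifying the
#' stiffening effect of chemical fixation. An optional user-supplied
#' volume-correction factor multiplies the plain ratio.
#'
#' @param shift_fixed Brillouin shift of the fixed state (GHz).
#' @param shift_living Brillouin shift of the living state (GHz), > 0.
#' @param volume_correction optional multiplicative correction (default 1).
#' @return dimensionless ratio.
#' @examples
#' q_ratio(7.8 * 1.049, 7.8) # 1.049
#' @export
q_ratio <- function(shift_fixed, shift_living, volume_correction = 1) {
  if (any(shift_living <= 0))
    bdb_stop("'shift_living' must be > 0", "bdb_invalid_input")
  volume_correction * shift_fixed / shift_living
}

#' Theoretical confocal resolution
#'
#' Gaussian-equivalent confocal FWHM: lateral `0.51 lambda / NA`, axial
#' `1.4 n_imm lambda / NA^2`. With an oil objective stopped to NA = 1 at
#' 532 nm this gives ~0.27 um lateral and ~1.13 um axial (0.3 x 0.3 x 1.1
#' um^3 at one significant digit).
#'
#' @param wavelength laser wavelength (m).
#' @param na numerical aperture.
#' @param n_imm immersion refractive index (oil 1.518).
#' @return named numeric `c(lateral_um, axial_um)`.
#' @export
confocal_resolution <- function(wavelength = 532e-9, na = 1, n_imm = 1.518) {
  c(lateral_um = 0.51 * wavelength / na * 1e6,
    axial_um = 1.4 * n_imm * wavelength / na^2 * 1e6)
}

#' Reference material constants
#'
#' Small lookup table of refractive index, density and acoustic velocity for
#' water and typical HeLa compartments (index ranges reported for HeLa cells;
#' midpoints tabulated). Shipped as CSV in `inst/extdata/materials.csv`.
#'
#' @return data frame with columns `material`, `n`, `rho_kg_m3`,
#'   `velocity_m_s`.
#' @export
brillouin_materials <- function() {
  path <- system.file("extdata", "materials.csv", package = "bdbmicro",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
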