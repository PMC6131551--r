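# VIPA etalon description and its frequency-domain transfer function.

# speed of light (m/s)
.c0 <- 299792458

#' Describe a VIPA etalon
#'
#' A VIPA (virtually imaged phased array) is a solid Fabry-Perot etalon with
#' an anti-reflection coated entrance window, used as an angular-dispersion
#' spectrometer. Its spectral behaviour is governed by the two surface
#' reflectivities and the optical thickness.
#'
#' Defaults describe a fused-silica etalon of 3.371 mm thickness with
#' `R1 = 99.9%` and `R2 = 96%` surface reflectivities, giving a free spectral
#' range near 30.4 GHz at 532 nm.
#'
#' @param R1 entrance-surface reflectivity, fraction in (0, 1).
#' @param R2 exit-surface reflectivity, fraction in (0, 1).
#' @param thickness optical path length L of the etalon (m), > 0.
#' @param n_etalon refractive index of the etalon material, >= 1.
#' @param tilt internal propagation angle (rad).
#'
#' @return An object of class `etalon_spec` with derived fields
#'   `R` (effective reflectivity, `sqrt(R1*R2)`) and `F`
#'   (finesse coefficient, `4R/(1-R)^2`).
#' @examples
#' et <- etalon_spec()
#' free_spectral_range(et)
#' @export
etalon_spec <- function(R1 = 0.999, R2 = 0.96, thickness = 3.371e-3,
                        n_etalon = 1.4607, tilt = 0) {
  chk_num(R1, "R1", 0, 1, strict = TRUE)
  chk_num(R2, "R2", 0, 1, strict = TRUE)
  if (!is.numeric(thickness) || length(thickness) != 1L ||
      !is.finite(thickness) || thickness <= 0)
    bdb_stop("'thickness' must be a positive length in metres",
             "bdb_invalid_spec")
  chk_num(n_etalon, "n_etalon", 1, Inf)
  chk_num(tilt, "tilt", -pi / 2, pi / 2, strict = TRUE)
  R <- sqrt(R1 * R2)
  structure(list(R1 = R1, R2 = R2, thickness = thickness,
                 n_etalon = n_etalon, tilt = tilt,
                 R = R, F = 4 * R / (1 - R)^2),
            class = "etalon_spec")
}

#' @export
print.etalon_spec <- function(x, ...) {
  cat("<etalon_spec>\n")
  cat(sprintf("  R1 = %.4f, R2 = %.4f  (effective R = %.5f, F = %.0f)\n",
              x$R1, x$R2, x$R, x$F))
  cat(sprintf("  thickness = %.4f mm, n = %.4f, tilt = %.3g rad\n",
              x$thickness * 1e3, x$n_etalon, x$tilt))
  cat(sprintf("  FSR = %.3f GHz, etalon-limited contrast 1+F = %.3g\n",
              free_spectral_range(x), 1 + x$F))
  invisible(x)
}

#' Free spectral range of an etalon
#'
#' Frequency spacing between consecutive interference orders,
#' `FSR = c / (2 n L cos(tilt))`.
#'
#' @param etalon an [etalon_spec()].
#' @return FSR in GHz.
#' @examples
#' free_spectral_range(etalon_spec(thickness = 0.15, n_etalon = 1)) # 1 GHz
#' @export
free_spectral_range <- function(etalon) {
  stopifnot(inherits(etalon, "etalon_spec"))
  .c0 / (2 * etalon$n_etalon * etalon$thickness * cos(etalon$tilt)) / 1e9
}

#' Airy intensity transfer function of an etalon
#'
#' `T(nu) = 1 / (1 + F sin^2(pi nu / FSR))` with the finesse coefficient
#' `F = 4R/(1-R)^2`, `R = sqrt(R1 R2)`. Peak transmission is 1 on resonance;
#' the inter-order minimum is `1/(1+F)`, which bounds the spectral contrast
#' of an ideal single-stage spectrometer.
#'
#' @param etalon an [etalon_spec()].
#' @param freq frequency-offset axis (GHz), finite.
#' @return An object of class `transfer_function`: a data frame with columns
#'   `freq` (GHz) and `transmission` (peak-normalised intensity).
#' @export
airy_transfer <- function(etalon, freq) {
  stopifnot(inherits(etalon, "etalon_spec"))
  if (!is.numeric(freq) || any(!is.finite(freq)))
    bdb_stop("'freq' must be finite numeric", "bdb_invalid_spec")
  fsr <- free_spectral_range(etalon)
  tr <- 1 / (1 + etalon$F * sin(pi * freq / fsr)^2)
  structure(data.frame(freq = freq, transmission = tr),
            class = c("transfer_function", "data.frame"),
            fsr = fsr, finesse_coefficient = etalon$F)
}

# scalar/vector version used internally by the pattern builder
airy_transmission <- function(etalon, freq, fsr = free_spectral_range(etalon)) {
  1 / (1 + etalon$F * sin(pi * freq / fsr)^2)
}
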