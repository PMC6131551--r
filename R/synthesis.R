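# Generative Brillouin spectra: Lorentzian lines, order combs, camera noise.

#' Lorentzian line profile
#'
#' `L(nu) = amplitude * (fwhm/2)^2 / ((nu - center)^2 + (fwhm/2)^2)`;
#' peak value equals `amplitude` at `center`, half maximum at
#' `center +- fwhm/2`, area `amplitude * pi * fwhm / 2`.
#'
#' @param freq frequency axis (GHz).
#' @param center line centre (GHz).
#' @param fwhm full width at half maximum (GHz), > 0.
#' @param amplitude peak amplitude.
#' @return intensity at `freq`.
#' @export
lorentzian <- function(freq, center, fwhm, amplitude = 1) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0)
    bdb_stop("'fwhm' must be > 0", "bdb_invalid_parameter")
  g <- fwhm / 2
  amplitude * g^2 / ((freq - center)^2 + g^2)
}

#' Generative Brillouin spectrum parameters
#'
#' Describes a single-component Brillouin spectrum: elastic Rayleigh lines at
#' every interference order `m * fsr`, a Stokes line at `m * fsr + shift` and
#' an anti-Stokes line at `(m + 1) * fsr - shift` (two Brillouin peaks between
#' consecutive Rayleigh orders).
#'
#' The spectrometer line shape is approximated as Lorentzian, so Lorentzian
#' widths add under convolution: the *observed* Brillouin FWHM is
#' `linewidth + instrument_width`, and the Rayleigh FWHM is
#' `instrument_width` (the elastic line is spectrally narrow).
#'
#' @param shift Brillouin shift nu_B (GHz), in `(0, fsr/2)`.
#' @param linewidth material Brillouin FWHM (GHz), > 0.
#' @param elastic_amp Rayleigh peak amplitude (counts), >= 0.
#' @param brillouin_amp Stokes/anti-Stokes peak amplitude (counts), >= 0.
#' @param fsr free spectral range (GHz). Default: the 3.371 mm fused-silica
#'   etalon of [etalon_spec()].
#' @param instrument_width spectrometer line FWHM (GHz), >= 0.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(shift = 7.41, linewidth = 0.5,
                           elastic_amp = 1000, brillouin_amp = 100,
                           fsr = free_spectral_range(etalon_spec()),
                           instrument_width = 0.3) {
  chk_num(fsr, "fsr", 0, Inf, strict = TRUE)
  chk_num(shift, "shift", 0, fsr / 2, strict = TRUE)
  chk_num(linewidth, "linewidth", 0, Inf, strict = TRUE)
  chk_num(elastic_amp, "elastic_amp", 0, Inf)
  chk_num(brillouin_amp, "brillouin_amp", 0, Inf)
  chk_num(instrument_width, "instrument_width", 0, Inf)
  structure(list(shift = shift, linewidth = linewidth,
                 elastic_amp = elastic_amp, brillouin_amp = brillouin_amp,
                 fsr = fsr, instrument_width = instrument_width),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf(
    "<spectrum_model> shift %.3f GHz, linewidth %.3f (+ %.3f instr.) GHz, FSR %.3f GHz\n",
    x$shift, x$linewidth, x$instrument_width, x$fsr))
  invisible(x)
}

#' Synthesise a Brillouin spectrum on a frequency axis
#'
#' Renders the line spectrum of a [spectrum_model()] as a sum of Lorentzians,
#' including all interference orders whose wings reach the requested window.
#' Frequencies are offsets from the lower Rayleigh order, increasing
#' left-to-right.
#'
#' @param model a [spectrum_model()].
#' @param freq frequency axis (GHz).
#' @return numeric intensity vector (same length as `freq`).
#' @examples
#' f <- seq(-2, 33, by = 0.02)
#' s <- synth_spectrum(spectrum_model(), f)
#' @export
synth_spectrum <- function(model, freq) {
  stopifnot(inherits(model, "spectrum_model"))
  if (!is.numeric(freq) || any(!is.finite(freq)))
    bdb_stop("'freq' must be finite numeric", "bdb_invalid_spec")
  if (model$shift >= model$fsr / 2)
    bdb_stop("shift >= FSR/2: order-ambiguous spectrum", "bdb_order_ambiguity")
  fsr <- model$fsr
  w_b <- model$linewidth + model$instrument_width
  w_r <- model$instrument_width
  if (model$elastic_amp > 0 && w_r <= 0)
    bdb_stop("elastic lines need instrument_width > 0 (Rayleigh FWHM)",
             "bdb_invalid_parameter")
  m_lo <- floor(min(freq) / fsr) - 2L
  m_hi <- ceiling(max(freq) / fsr) + 2L
  out <- numeric(length(freq))
  # Stokes above and anti-Stokes below every order m: for a window covering
  # [0, fsr] this places the pair symmetrically between consecutive Rayleigh
  # peaks (anti-Stokes of order m+1 sits at (m+1) fsr - shift), and the
  # included order range maps onto itself under reflection, so the mirror
  # symmetry of the synthesised spectrum is exact.
  for (m in m_lo:m_hi) {
    if (model$elastic_amp > 0)
      out <- out + lorentzian(freq, m * fsr, w_r, model$elastic_amp)
    if (model$brillouin_amp > 0) {
      out <- out + lorentzian(freq, m * fsr + model$shift, w_b,
                              model$brillouin_amp)
      out <- out + lorentzian(freq, m * fsr - model$shift, w_b,
                              model$brillouin_amp)
    }
  }
  out
}

#' Synthesise a spectrum limited by spectrometer crosstalk
#'
#' Scenario generator for detectability studies in turbid media: the
#' Brillouin doublet is rendered as Lorentzians, while the (much stronger)
#' elastic lines are rendered as narrow Gaussian cores plus a flat crosstalk
#' floor at `elastic_amp / contrast`. This reflects how a real spectrometer
#' behaves: near its core the elastic line has the instrument width, but its
#' far wings are set by the instrument's spectral contrast, not by a
#' Lorentzian tail (a Lorentzian of instrument width would bound the
#' contrast at ~1e3-1e4 regardless of the spectrometer).
#'
#' @param model a [spectrum_model()]; `elastic_amp / brillouin_amp` sets the
#'   elastic-to-Brillouin ratio.
#' @param contrast spectral contrast of the instrument (peak / background),
#'   e.g. `1e3` for a standard single-stage spectrometer, `1e7` for the
#'   background-deflected one.
#' @param freq frequency axis (GHz).
#' @return intensity vector.
#' @export
crosstalk_spectrum <- function(model, contrast, freq) {
  stopifnot(inherits(model, "spectrum_model"))
  chk_num(contrast, "contrast", 1, Inf)
  fsr <- model$fsr
  iw <- if (model$instrument_width > 0) model$instrument_width else 0.3
  sg <- iw / (2 * sqrt(2 * log(2)))
  m_lo <- floor(min(freq) / fsr) - 1L
  m_hi <- ceiling(max(freq) / fsr) + 1L
  out <- rep(model$elastic_amp / contrast, length(freq))
  w_b <- model$linewidth + model$instrument_width
  for (m in m_lo:m_hi) {
    out <- out + model$elastic_amp * exp(-(freq - m * fsr)^2 / (2 * sg^2))
    if (model$brillouin_amp > 0) {
      out <- out + lorentzian(freq, m * fsr + model$shift, w_b,
                              model$brillouin_amp)
      out <- out + lorentzian(freq, m * fsr - model$shift, w_b,
                              model$brillouin_amp)
    }
  }
  out
}

#' Camera noise model
#'
#' Photon shot noise (Poisson on counts), additive Gaussian read noise, and
#' full-well clipping, applied in that order. Identical seeds give identical
#' realisations.
#'
#' @param shot logical, apply Poisson shot noise.
#' @param read_sigma Gaussian read-noise SD (counts), >= 0.
#' @param saturation full-well clip level (counts), > 0.
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shot = TRUE, read_sigma = 2, saturation = 65535,
                        seed = 1L) {
  chk_num(read_sigma, "read_sigma", 0, Inf)
  if (!is.numeric(saturation) || length(saturation) != 1L ||
      is.na(saturation) || saturation <= 0)
    bdb_stop("'saturation' must be > 0 (Inf disables clipping)",
             "bdb_invalid_spec")
  structure(list(shot = isTRUE(shot), read_sigma = read_sigma,
                 saturation = saturation, seed = as.integer(seed)),
            class = "noise_model")
}

#' Apply camera noise to a spectrum
#'
#' @param spectrum nonnegative numeric vector of expected counts.
#' @param noise a [noise_model()]; `NULL` returns the input unchanged.
#' @return noisy counts, clipped at `noise$saturation`.
#' @export
add_noise <- function(spectrum, noise) {
  if (is.null(noise)) return(spectrum)
  stopifnot(inherits(noise, "noise_model"))
  if (any(spectrum < 0))
    bdb_stop("input spectrum must be nonnegative", "bdb_invalid_input")
  out <- with_seed(noise$seed, {
    s <- spectrum
    if (noise$shot) s <- stats::rpois(length(s), s)
    if (noise$read_sigma > 0)
      s <- s + stats::rnorm(length(s), 0, noise$read_sigma)
    s
  })
  pmin(out, noise$saturation)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
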