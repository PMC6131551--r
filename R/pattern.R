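# Camera-plane interference patterns and spectral-contrast metrics.

#' Simulate the camera-plane interference pattern
#'
#' Builds the 2D camera image produced by a line spectrum dispersed by the
#' etalon and diffracted by the pupil mask.
#'
#' Two background models are available, reflecting two physically distinct
#' contributions to the inter-order background:
#'
#' * `"airy"` — the dispersion-axis radiance of each spectral line is the
#'   full etalon angular response (the Airy transfer function, including its
#'   inter-order floor `1/(1+F)`), convolved with the mask kernel. With an
#'   open pupil (`shape = "none"`) the dispersion profile equals
#'   [airy_transfer()] exactly. This is the idealised-etalon bound for an
#'   unmasked spectrometer.
#' * `"comb"` — each spectral line contributes a discrete order comb of
#'   diffraction kernels: the inter-order background is then set by the
#'   kernel tails alone. This models the masked instrument, where the light
#'   that would form the on-axis floor has been deflected off the dispersion
#'   axis and the residual background is aperture diffraction of the order
#'   peaks (the background-deflection mechanism).
#'
#' The default is `"airy"` for an open pupil and `"comb"` when a mask is
#' present.
#'
#' @param etalon an [etalon_spec()].
#' @param mask an [aperture_mask()] (may be `shape = "none"`).
#' @param layout an [optical_layout()] with angular dispersion set (see
#'   [reference_layout()]).
#' @param source a [spectrum_model()]; its `shift`, `elastic_amp`,
#'   `brillouin_amp` define the line spectrum. Use `brillouin_amp = 0` for a
#'   monochromatic (elastic-only) source.
#' @param x,y camera coordinates (m); defaults cover `[-0.35, 1.35]` FSR
#'   spans along x and a narrow strip in y.
#' @param line_profile `"comb"`, `"airy"` or `"auto"` (default; see Details).
#' @return An object of class `interference_pattern`: `intensity` matrix
#'   `[y, x]`, `x_axis`, `y_axis` (m), `dispersion_row`, `freq_map` (GHz per
#'   camera x), plus the generating configuration.
#' @export
camera_pattern <- function(etalon, mask, layout, source,
                           x = NULL, y = NULL,
                           line_profile = c("auto", "comb", "airy")) {
  stopifnot(inherits(etalon, "etalon_spec"),
            inherits(mask, "aperture_mask"),
            inherits(layout, "optical_layout"),
            inherits(source, "spectrum_model"))
  line_profile <- match.arg(line_profile)
  if (line_profile == "auto")
    line_profile <- if (mask$shape == "none") "airy" else "comb"
  fsr <- free_spectral_range(etalon)
  scl <- dispersion_scale(layout)             # m per GHz
  if (is.null(x)) x <- seq(-0.35 * fsr, 1.35 * fsr, by = 2e-6 / scl) * scl
  if (is.null(y)) y <- seq(-32, 32, by = 2) * 1e-6
  if (any(diff(x) <= 0))
    bdb_stop("freq_map must be strictly monotonic (x not sorted)",
             "bdb_config_error")
  freq_map <- x / scl                          # GHz offset
  if (source$shift >= fsr / 2)
    bdb_stop("source line outside the unambiguous half-FSR window",
             "bdb_config_error")

  # base line set within one FSR (frequency offset, amplitude)
  lines <- rbind(c(0, source$elastic_amp),
                 if (source$brillouin_amp > 0)
                   rbind(c(source$shift, source$brillouin_amp),
                         c(-source$shift, source$brillouin_amp)))

  dispersion_row <- which.min(abs(y))
  ny <- length(y); nx <- length(x)
  intensity <- matrix(0, ny, nx)

  if (line_profile == "airy") {
    prof <- numeric(nx)
    for (i in seq_len(nrow(lines)))
      prof <- prof + lines[i, 2] *
        airy_transmission(etalon, freq_map - lines[i, 1], fsr)
    if (mask$shape == "none") {
      intensity[dispersion_row, ] <- prof
    } else {
      ker <- aperture_kernel(mask, layout, x = x - mean(range(x)), y = y)
      kmat <- ker$intensity
      kmat <- kmat / (sum(kmat[dispersion_row, ]))   # row-energy normalised
      for (j in seq_len(ny))
        intensity[j, ] <- conv_same(prof, kmat[j, ])
    }
  } else {
    # discrete order comb: kernel replicas at every line position
    m_lo <- floor(min(freq_map) / fsr) - 1
    m_hi <- ceiling(max(freq_map) / fsr) + 1
    if (mask$shape == "none")
      bdb_stop("comb profile with an open pupil is a sum of deltas; use line_profile = 'airy'",
               "bdb_config_error")
    for (m in m_lo:m_hi) {
      for (i in seq_len(nrow(lines))) {
        nu0 <- m * fsr + lines[i, 1]
        if (nu0 < min(freq_map) - 2 * fsr || nu0 > max(freq_map) + 2 * fsr)
          next
        ker <- aperture_kernel(mask, layout, x = x - nu0 * scl, y = y)
        intensity <- intensity + lines[i, 2] * ker$intensity
      }
    }
  }

  structure(list(intensity = intensity, x_axis = x, y_axis = y,
                 dispersion_row = dispersion_row, freq_map = freq_map,
                 fsr = fsr, etalon = etalon, mask = mask, layout = layout,
                 source = source, line_profile = line_profile),
            class = "interference_pattern")
}

# linear convolution truncated to the length of a ('same'), kernel k centred
conv_same <- function(a, k) {
  n <- length(a); m <- length(k)
  full <- stats::convolve(a, rev(k), type = "open")
  start <- (m + 1) %/% 2
  full[start:(start + n - 1)]
}

#' @export
print.interference_pattern <- function(x, ...) {
  cat(sprintf("<interference_pattern> %d x %d px, FSR %.3f GHz, mask %s (%s profile)\n",
              nrow(x$intensity), ncol(x$intensity), x$fsr, x$mask$shape,
              x$line_profile))
  invisible(x)
}

# dispersion-row profile of a pattern
dispersion_profile <- function(pattern) {
  pattern$intensity[pattern$dispersion_row, ]
}

#' Spectral contrast of an interference pattern
#'
#' Ratio of the order-peak intensity to the mean intensity along the
#' dispersion axis within a frequency band strictly between order peaks.
#' This is the figure of merit that limits detection of weak Brillouin peaks
#' next to strong elastic lines.
#'
#' @param pattern an [camera_pattern()] result.
#' @param band numeric length-2, frequency interval in GHz (offsets from the
#'   lower Rayleigh order), e.g. `c(5, 25)`.
#' @param guard half-width (GHz) of the exclusion zone around spectral lines
#'   used to detect band/peak overlap.
#' @return dimensionless contrast (> 1 for any physical pattern).
#' @export
spectral_contrast <- function(pattern, band, guard = 1) {
  stopifnot(inherits(pattern, "interference_pattern"))
  if (length(band) != 2L || band[1] >= band[2])
    bdb_stop("'band' must be an increasing frequency interval",
             "bdb_invalid_band")
  fsr <- pattern$fsr
  src <- pattern$source
  lines <- c(0, fsr, if (src$brillouin_amp > 0) c(src$shift, fsr - src$shift))
  if (any(lines > band[1] - guard & lines < band[2] + guard))
    bdb_stop("band overlaps a spectral line", "bdb_invalid_band")
  if (band[1] <= 0 || band[2] >= fsr)
    bdb_stop("band must lie strictly between the two order peaks",
             "bdb_invalid_band")
  prof <- dispersion_profile(pattern)
  sel <- pattern$freq_map >= band[1] & pattern$freq_map <= band[2]
  if (!any(sel))
    bdb_stop("band contains no camera samples", "bdb_invalid_band")
  max(prof) / mean(prof[sel])
}

#' Contrast enhancement between two masks (dB)
#'
#' `10 log10(contrast_a / contrast_b)` for the same etalon, layout, source
#' and band; antisymmetric under swapping the masks. Positive values mean
#' `mask_a` suppresses the inter-order background better.
#'
#' @param mask_a,mask_b [aperture_mask()] objects.
#' @param etalon an [etalon_spec()].
#' @param layout an [optical_layout()].
#' @param band frequency band (GHz), as in [spectral_contrast()].
#' @param source a [spectrum_model()]; default monochromatic.
#' @return enhancement in dB.
#' @export
contrast_enhancement <- function(mask_a, mask_b, etalon = etalon_spec(),
                                 layout = reference_layout(etalon),
                                 band = c(5, 25), source = NULL) {
  if (is.null(source))
    source <- spectrum_model(elastic_amp = 1, brillouin_amp = 0)
  ca <- spectral_contrast(camera_pattern(etalon, mask_a, layout, source), band)
  cb <- spectral_contrast(camera_pattern(etalon, mask_b, layout, source), band)
  10 * log10(ca / cb)
}

#' Band-averaged pointwise background suppression (dB)
#'
#' Pointwise ratio of the dispersion-axis backgrounds of two masks, averaged
#' over a frequency band. Both profiles are first averaged over one
#' diffraction-lobe period (so the metric tracks the intensity envelopes
#' rather than the zero crossings of either pattern), converted to dB
#' pointwise, and then averaged across the band. For a rhomboid (tail
#' envelope `~u^-4`) against a circular aperture (`~8/(pi v^3)`) the
#' pointwise envelope ratio grows linearly with the frequency offset.
#'
#' @inheritParams contrast_enhancement
#' @return mean suppression over the band, dB (positive when `mask_a` has
#'   the lower background).
#' @export
band_suppression <- function(mask_a, mask_b, etalon = etalon_spec(),
                             layout = reference_layout(etalon),
                             band = c(5, 25), source = NULL) {
  if (is.null(source))
    source <- spectrum_model(elastic_amp = 1, brillouin_amp = 0)
  pa <- camera_pattern(etalon, mask_a, layout, source)
  pb <- camera_pattern(etalon, mask_b, layout, source)
  prof_a <- dispersion_profile(pa); prof_b <- dispersion_profile(pb)
  # smoothing window: one lobe period of the coarser-lobed mask
  lf <- layout$wavelength * layout$focal_length
  ext <- function(m) if (m$shape == "rhomboidal") m$width / 2 else
    min(m$width, m$height)
  period <- lf / min(ext(mask_a), ext(mask_b))
  dx <- pa$x_axis[2] - pa$x_axis[1]
  k <- max(3L, as.integer(round(period / dx)))
  if (k %% 2 == 0) k <- k + 1L
  sm <- function(p) stats::filter(p, rep(1 / k, k), sides = 2)
  sa <- sm(prof_a); sb <- sm(prof_b)
  sel <- pa$freq_map >= band[1] & pa$freq_map <= band[2] &
    !is.na(sa) & !is.na(sb)
  mean(10 * log10(sb[sel] / sa[sel]))
}
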