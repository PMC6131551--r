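# Diffraction masks, optical layout, Fraunhofer kernels and excess loss.

#' Describe a pupil diffraction mask
#'
#' The mask sits in the spectrometer pupil (before the Fourier lens); its
#' Fraunhofer diffraction pattern is the point-spread kernel that every
#' spectral line is convolved with on the camera. A rhomboidal aperture
#' (default 8 mm x 4 mm) redirects the high-energy diffraction tails away
#' from the dispersion axis, which is the contrast-enhancement mechanism.
#'
#' @param shape one of `"rhomboidal"`, `"circular"`, `"rectangular"`,
#'   `"none"`. The rhomboid is `|x|/(width/2) + |y|/(height/2) <= 1` in its
#'   local frame; for `"circular"` the limiting diameter is `min(width,
#'   height)` (pass one value to both for a circle).
#' @param width full extent along the local x axis (m).
#' @param height full extent along the local y axis (m).
#' @param rotation angle of the mask local frame, counter-clockwise from the
#'   dispersion axis (rad); normalised to `[0, pi)`. The reference rotation
#'   (0) puts the long rhomboid diagonal along the dispersion axis.
#' @return An object of class `aperture_mask`.
#' @examples
#' aperture_mask()                          # reference rhomboid, 8 x 4 mm
#' aperture_mask("circular", 4e-3, 4e-3)    # standard circular baseline
#' @export
aperture_mask <- function(shape = c("rhomboidal", "circular", "rectangular",
                                    "none"),
                          width = 8e-3, height = 4e-3, rotation = 0) {
  shape <- match.arg(shape)
  if (shape != "none") {
    if (!is.numeric(width) || width <= 0 || !is.numeric(height) || height <= 0)
      bdb_stop("mask 'width' and 'height' must be > 0",
               "bdb_invalid_spec")
  }
  rotation <- rotation %% pi
  structure(list(shape = shape, width = width, height = height,
                 rotation = rotation),
            class = "aperture_mask")
}

#' @export
print.aperture_mask <- function(x, ...) {
  if (x$shape == "none") {
    cat("<aperture_mask> open (no mask)\n")
  } else {
    cat(sprintf("<aperture_mask> %s, %.1f x %.1f mm, rotation %.1f deg\n",
                x$shape, x$width * 1e3, x$height * 1e3,
                x$rotation * 180 / pi))
  }
  invisible(x)
}

#' Describe the spectrometer imaging layout
#'
#' Geometry linking the pupil plane to the camera plane. `angular_dispersion`
#' (rad/GHz) sets how etalon output angle varies with frequency; together
#' with the focal length it fixes the camera-plane span of one free spectral
#' range. The default (`NULL`) is resolved by [reference_layout()].
#'
#' @param wavelength laser wavelength (m). Default 532 nm.
#' @param focal_length Fourier-lens focal length (m). Default 200 mm
#'   (documented reference value; not a measured quantity).
#' @param beam_radius 1/e^2 intensity radius of the illumination at the mask
#'   plane (m). Default 2.2 mm. Affects [excess_loss()] only.
#' @param pixel_pitch camera sampling (m). Default 2 um.
#' @param grid_shape simulation grid (pixels), `c(ny, nx)`.
#' @param angular_dispersion d(theta)/d(nu) of the etalon output (rad/GHz),
#'   or `NULL` to be filled in by [reference_layout()].
#' @return An object of class `optical_layout`.
#' @export
optical_layout <- function(wavelength = 532e-9, focal_length = 0.2,
                           beam_radius = 2.2e-3, pixel_pitch = 2e-6,
                           grid_shape = c(256, 2048),
                           angular_dispersion = NULL) {
  for (nm in c("wavelength", "focal_length", "beam_radius", "pixel_pitch")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bdb_stop(sprintf("'%s' must be a positive scalar", nm),
               "bdb_invalid_spec")
  }
  if (!is.null(angular_dispersion))
    chk_num(angular_dispersion, "angular_dispersion", 0, Inf, strict = TRUE)
  structure(list(wavelength = wavelength, focal_length = focal_length,
                 beam_radius = beam_radius, pixel_pitch = pixel_pitch,
                 grid_shape = as.integer(grid_shape),
                 angular_dispersion = angular_dispersion),
            class = "optical_layout")
}

#' Reference layout for contrast computations
#'
#' The published system does not state its focal length, beam radius or
#' angular dispersion. The package fixes a documented reference: 200 mm
#' Fourier lens, 2.2 mm beam radius, and angular dispersion chosen so that
#' one free spectral range of the given etalon spans exactly `fsr_span`
#' (default 1.0 mm) on the camera. All quoted contrast figures refer to this
#' layout.
#'
#' @param etalon an [etalon_spec()].
#' @param fsr_span camera-plane extent of one FSR (m).
#' @param ... passed to [optical_layout()].
#' @return An `optical_layout` with `angular_dispersion` filled in.
#' @export
reference_layout <- function(etalon = etalon_spec(), fsr_span = 1e-3, ...) {
  lay <- optical_layout(...)
  fsr <- free_spectral_range(etalon)
  lay$angular_dispersion <- fsr_span / (lay$focal_length * fsr)
  lay
}

# camera-plane distance per GHz (m/GHz)
dispersion_scale <- function(layout) {
  if (is.null(layout$angular_dispersion))
    bdb_stop("layout has no angular_dispersion; use reference_layout()",
             "bdb_config_error")
  layout$focal_length * layout$angular_dispersion
}

# mask transmission indicator in the camera/mask global frame
mask_transmission <- function(mask, x, y) {
  if (mask$shape == "none") return(rep(1, length(x)))
  ct <- cos(mask$rotation); st <- sin(mask$rotation)
  # rotate global coords into the mask local frame
  xl <- ct * x + st * y
  yl <- -st * x + ct * y
  a <- mask$width / 2; b <- mask$height / 2
  switch(mask$shape,
    circular    = as.numeric((xl / a)^2 + (yl / b)^2 <= 1),
    rectangular = as.numeric(abs(xl) <= a & abs(yl) <= b),
    rhomboidal  = as.numeric(abs(xl) / a + abs(yl) / b <= 1)
  )
}

# normalised Fraunhofer *amplitude* at camera coords (x, y), closed forms.
# fx, fy are spatial frequencies xl/(lambda f) in the mask local frame.
fraunhofer_amplitude <- function(mask, layout, x, y) {
  ct <- cos(mask$rotation); st <- sin(mask$rotation)
  lf <- layout$wavelength * layout$focal_length
  fx <- (ct * x + st * y) / lf
  fy <- (-st * x + ct * y) / lf
  a <- mask$width / 2; b <- mask$height / 2
  if (mask$shape == "circular") {
    r <- min(a, b)                      # limiting radius
    v <- 2 * pi * r * sqrt(fx^2 + fy^2) # = pi D rho / (lambda f)
    amp <- ifelse(v == 0, 1, 2 * besselJ(v, 1) / v)
  } else if (mask$shape == "rectangular") {
    sx <- pi * mask$width * fx
    sy <- pi * mask$height * fy
    amp <- ifelse(sx == 0, 1, sin(sx) / sx) * ifelse(sy == 0, 1, sin(sy) / sy)
  } else if (mask$shape == "rhomboidal") {
    # FT of |x|/a + |y|/b <= 1: amplitude = 2 (cos q - cos p) / (p^2 - q^2),
    # p = 2 pi a fx, q = 2 pi b fy (normalised to 1 at the origin).
    p <- 2 * pi * a * fx
    q <- 2 * pi * b * fy
    d <- p^2 - q^2
    amp <- numeric(length(d))
    deg <- abs(d) < 1e-9
    amp[!deg] <- 2 * (cos(q[!deg]) - cos(p[!deg])) / d[!deg]
    # p ~ +-q limit -> sin(p)/p
    pd <- p[deg]
    amp[deg] <- ifelse(abs(pd) < 1e-12, 1, sin(pd) / pd)
  } else {
    bdb_stop("no diffraction kernel for an open aperture",
             "bdb_invalid_spec")
  }
  amp
}

#' Diffraction point-spread kernel of a mask
#'
#' Camera-plane intensity point-spread kernel: the squared modulus of the
#' Fraunhofer transform of the aperture transmission under uniform
#' illumination, normalised to unit peak. Closed forms are used for the
#' circular (`[2 J1(v)/v]^2`), rectangular (`sinc^2 sinc^2`) and rhomboidal
#' apertures at any rotation; `method = "fft"` computes the kernel from a
#' discrete Fourier transform of the sampled aperture instead (cross-check
#' path, and the route for arbitrary numerical transmissions).
#'
#' @param mask an [aperture_mask()] with `shape != "none"`.
#' @param layout an [optical_layout()].
#' @param x,y camera coordinates (m) at which to evaluate the kernel.
#'   Defaults derive from `layout$grid_shape` and `pixel_pitch`, centred on 0.
#' @param method `"analytic"` (closed form, default) or `"fft"`.
#' @param n_aperture,pad_factor sampling of the aperture plane for the FFT
#'   path: `n_aperture` samples across a window `pad_factor` times the mask
#'   extent (zero padding).
#' @return An object of class `aperture_kernel`: list with `x`, `y` (m) and
#'   `intensity` (matrix `[y, x]`, unit peak).
#' @export
aperture_kernel <- function(mask, layout, x = NULL, y = NULL,
                            method = c("analytic", "fft"),
                            n_aperture = 2048, pad_factor = 2) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "aperture_mask"), inherits(layout, "optical_layout"))
  if (mask$shape == "none")
    bdb_stop("aperture_kernel() needs a mask; shape = 'none' is the open pupil",
             "bdb_invalid_spec")
  if (mask$width <= 0 || mask$height <= 0)
    bdb_stop("zero-area aperture", "bdb_invalid_spec")
  if (method == "fft" && is.null(x) && is.null(y)) {
    # native FFT grid: exact sample positions, no interpolation error
    k <- kernel_fft(mask, layout, n_aperture, pad_factor)
    return(structure(list(x = k$x, y = k$y, intensity = k$intensity,
                          camera_step = k$camera_step,
                          mask = mask, layout = layout, method = method),
                     class = "aperture_kernel"))
  }
  if (is.null(x))
    x <- (seq_len(layout$grid_shape[2]) - 1 -
            (layout$grid_shape[2] - 1) / 2) * layout$pixel_pitch
  if (is.null(y))
    y <- (seq_len(layout$grid_shape[1]) - 1 -
            (layout$grid_shape[1] - 1) / 2) * layout$pixel_pitch
  # Nyquist: camera sampling must resolve the fastest diffraction fringe
  ext <- max(mask$width, mask$height)
  lim <- layout$wavelength * layout$focal_length / (2 * ext)
  dx <- if (length(x) > 1) min(diff(sort(x))) else lim
  dy <- if (length(y) > 1) min(diff(sort(y))) else lim
  if (dx > lim || dy > lim)
    bdb_stop(sprintf(
      "camera sampling (%.3g m) undersamples the diffraction pattern (Nyquist %.3g m)",
      max(dx, dy), lim), "bdb_aliasing_error")

  if (method == "analytic") {
    g <- expand.grid(x = x, y = y)
    amp <- fraunhofer_amplitude(mask, layout, g$x, g$y)
    intensity <- matrix(amp^2, nrow = length(y), ncol = length(x),
                        byrow = TRUE)
  } else {
    k <- kernel_fft(mask, layout, n_aperture, pad_factor)
    intensity <- interp_bilinear(k$x, k$y, k$intensity, x, y)
  }
  structure(list(x = x, y = y, intensity = intensity,
                 mask = mask, layout = layout, method = method),
            class = "aperture_kernel")
}

# numeric Fraunhofer kernel on its natural FFT grid; anti-aliased aperture
# sampling (4x4 subpixel area coverage).
kernel_fft <- function(mask, layout, n_aperture = 2048, pad_factor = 2) {
  ext <- 1.2 * max(mask$width, mask$height)
  S <- pad_factor * ext                 # aperture-plane window
  n <- n_aperture
  d <- S / n
  u <- (seq_len(n) - 1 - n / 2) * d
  ss <- 4                               # subpixel supersampling
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  tr <- matrix(0, n, n)
  for (oy in off) for (ox in off) {
    g <- expand.grid(x = u + ox * d, y = u + oy * d)
    tr <- tr + matrix(mask_transmission(mask, g$x, g$y), n, n, byrow = TRUE)
  }
  tr <- tr / ss^2
  fld <- stats::fft(tr)
  fld <- fftshift2(fld)
  intensity <- Mod(fld)^2
  intensity <- intensity / max(intensity)
  # camera coordinates: spatial frequency k/(n d) maps to x = lambda f k/(n d)
  lf <- layout$wavelength * layout$focal_length
  ax <- (seq_len(n) - 1 - n / 2) * lf / (n * d)
  list(x = ax, y = ax, intensity = intensity,
       aperture_energy = sum(tr^2) * d^2,
       camera_step = lf / (n * d))
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}

interp_bilinear <- function(xs, ys, z, xo, yo) {
  fx <- findInterval(xo, xs, all.inside = TRUE)
  fy <- findInterval(yo, ys, all.inside = TRUE)
  tx <- pmin(pmax((xo - xs[fx]) / (xs[fx + 1] - xs[fx]), 0), 1)
  ty <- pmin(pmax((yo - ys[fy]) / (ys[fy + 1] - ys[fy]), 0), 1)
  out <- matrix(0, length(yo), length(xo))
  for (j in seq_along(yo)) {
    r1 <- z[fy[j], fx] * (1 - tx) + z[fy[j], fx + 1] * tx
    r2 <- z[fy[j] + 1, fx] * (1 - tx) + z[fy[j] + 1, fx + 1] * tx
    out[j, ] <- r1 * (1 - ty[j]) + r2 * ty[j]
  }
  out
}

#' Far-tail decay exponent of a diffraction kernel
#'
#' Least-squares slope of `log(intensity envelope)` versus `log(distance)`
#' along a camera-plane direction, fitted on the lobe maxima of the far
#' diffraction tail. Expected values: -3 for a circular aperture (Airy,
#' envelope `8/(pi v^3)`), -2 for a rectangular aperture along an edge
#' normal, -4 for a rhomboid along a diagonal (`(sin u / u)^4`).
#'
#' @param mask an [aperture_mask()].
#' @param layout an [optical_layout()].
#' @param direction camera-plane direction (length-2 vector, need not be
#'   normalised). Default: the dispersion axis.
#' @param u_range dimensionless range of the lobe variable
#'   `u = pi * ext * r / (lambda f)` over which the envelope is fitted
#'   (`ext` = limiting half-extent of the mask along the direction).
#' @return fitted slope (dimensionless).
#' @export
tail_exponent <- function(mask, layout, direction = c(1, 0),
                          u_range = c(15, 120)) {
  stopifnot(mask$shape != "none")
  d <- direction / sqrt(sum(direction^2))
  ext <- switch(mask$shape,
                circular = min(mask$width, mask$height),
                rectangular = mask$width,
                rhomboidal = mask$width / 2)
  lf <- layout$wavelength * layout$focal_length
  u <- seq(u_range[1], u_range[2], length.out = 30000)
  r <- u * lf / (pi * ext)
  I <- fraunhofer_amplitude(mask, layout, r * d[1], r * d[2])^2
  pk <- local_maxima(I)
  if (length(pk) < 5)
    bdb_stop("too few lobes in the requested range", "bdb_invalid_spec")
  unname(stats::coef(stats::lm(log(I[pk]) ~ log(u[pk])))[2])
}

#' Excess illumination loss of a mask
#'
#' Fraction of a Gaussian beam (1/e^2 intensity radius `layout$beam_radius`,
#' centred on the mask) blocked by the aperture, in dB:
#' `-10 log10(transmitted power fraction)`. Always evaluated with Gaussian
#' illumination regardless of the kernel illumination convention.
#'
#' @param mask an [aperture_mask()].
#' @param layout an [optical_layout()] (only `beam_radius` is used).
#' @param n quadrature grid size per axis.
#' @return loss in dB (>= 0); 0 for an open aperture.
#' @examples
#' excess_loss(aperture_mask(), reference_layout())
#' @export
excess_loss <- function(mask, layout, n = 1501) {
  stopifnot(inherits(mask, "aperture_mask"), inherits(layout, "optical_layout"))
  if (mask$shape == "none") return(0)
  w <- layout$beam_radius
  # integrate over the mask bounding square (rotation-safe)
  half <- max(mask$width, mask$height) / 2
  xs <- seq(-half, half, length.out = n)
  d <- xs[2] - xs[1]
  g <- expand.grid(x = xs, y = xs)
  t2 <- mask_transmission(mask, g$x, g$y)
  inten <- exp(-2 * (g$x^2 + g$y^2) / w^2)
  transmitted <- sum(t2 * inten) * d^2
  total <- pi * w^2 / 2
  frac <- min(transmitted / total, 1)
  -10 * log10(frac)
}

#' Beam radius documenting a target excess loss
#'
#' Solves for the Gaussian 1/e^2 beam radius at which [excess_loss()] of the
#' given mask equals `target_db`. Used to document which illumination radius
#' reproduces a quoted loss figure; the returned radius is a solving value,
#' not a measured one.
#'
#' @param mask an [aperture_mask()].
#' @param target_db target loss (dB).
#' @param interval search interval for the radius (m).
#' @return beam radius (m).
#' @export
solve_beam_radius <- function(mask, target_db, interval = c(5e-4, 2e-2)) {
  f <- function(w)
    excess_loss(mask, optical_layout(beam_radius = w)) - target_db
  stats::uniroot(f, interval, tol = 1e-7)$root
}
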