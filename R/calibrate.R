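# Dispersion-profile extraction and pixel -> GHz calibration.

#' Extract the 1D dispersion-axis spectrum from a camera frame
#'
#' Locates the dispersion axis as the intensity-weighted centroid row of the
#' two brightest spots (the Rayleigh order peaks) and sums columns over
#' `+- window_rows` about it.
#'
#' @param pattern an [camera_pattern()] result, or a plain numeric matrix
#'   `[rows, cols]` of camera counts.
#' @param window_rows half-width of the summation window (rows).
#' @param axis `"x"` if the dispersion axis runs along columns (default),
#'   `"y"` if the frame is transposed.
#' @return list with `profile` (numeric), `pixel` (column index),
#'   `dispersion_row` (located row).
#' @export
extract_dispersion_profile <- function(pattern, window_rows = 2,
                                       axis = c("x", "y")) {
  axis <- match.arg(axis)
  img <- if (inherits(pattern, "interference_pattern")) pattern$intensity
         else as.matrix(pattern)
  if (axis == "y") img <- t(img)
  # two brightest, well-separated spots
  p1 <- which(img == max(img), arr.ind = TRUE)[1, ]
  guard_c <- max(3L, round(ncol(img) / 20))
  masked <- img
  c_lo <- max(1L, p1[2] - guard_c); c_hi <- min(ncol(img), p1[2] + guard_c)
  masked[, c_lo:c_hi] <- -Inf
  p2 <- which(masked == max(masked), arr.ind = TRUE)[1, ]
  if (!is.finite(masked[p2[1], p2[2]]) || img[p2[1], p2[2]] <= 0)
    bdb_stop("fewer than 2 detectable order peaks", "bdb_extraction_error")
  # centroid row around each spot
  centroid <- function(p) {
    r <- max(1L, p[1] - 3L):min(nrow(img), p[1] + 3L)
    wts <- img[r, p[2]]
    sum(r * wts) / sum(wts)
  }
  row <- round((centroid(p1) + centroid(p2)) / 2)
  rows <- max(1L, row - window_rows):min(nrow(img), row + window_rows)
  prof <- colSums(img[rows, , drop = FALSE])
  list(profile = prof, pixel = seq_len(ncol(img)), dispersion_row = row)
}

# sub-pixel peak centres: local maxima of a median-filtered profile, refined
# by a Lorentzian fit on a +-halfwin window.
find_peaks <- function(profile, n = 4, min_sep = 5, halfwin = 6) {
  sm <- stats::runmed(profile, 5)
  n_p <- length(profile)
  cand <- local_maxima(sm)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (all(abs(p - keep) >= min_sep)) keep <- c(keep, p)
    if (length(keep) >= n) break
  }
  vapply(keep, function(p) {
    i <- max(1L, p - halfwin):min(n_p, p + halfwin)
    refine_peak_lorentz(i, profile[i], p)
  }, numeric(1))
}

refine_peak_lorentz <- function(x, y, p0) {
  df <- data.frame(x = x, y = y)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ b + a * (g / 2)^2 / ((x - c)^2 + (g / 2)^2),
    data = df,
    start = list(b = min(y), a = max(y) - min(y), c = p0, g = 3),
    lower = c(-Inf, 0, min(x), 0.3),
    upper = c(Inf, Inf, max(x), diff(range(x)) * 2),
    control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
  if (inherits(fit, "try-error")) return(as.numeric(p0))
  stats::coef(fit)[["c"]]
}

# Joint fit of n Lorentzians + quadratic background in pixel space; returns
# refined centres. The smooth background terms absorb the wings of
# out-of-window interference orders, which would otherwise bias the centres
# at the 1e-5 pixel level.
refine_peaks_joint <- function(profile, centers0) {
  np <- length(centers0)
  px <- seq_along(profile)
  x0 <- mean(px); xs <- (px - x0) / length(px)
  h0 <- stats::approx(px, profile, centers0)$y
  par0 <- c(min(profile), 0, 0, as.vector(rbind(h0, centers0, rep(4, np))))
  model <- function(p) {
    y <- p[1] + p[2] * xs + p[3] * xs^2
    for (i in seq_len(np)) {
      a <- p[3 * i + 1]; c0 <- p[3 * i + 2]; g <- p[3 * i + 3]
      y <- y + a * (g / 2)^2 / ((px - c0)^2 + (g / 2)^2)
    }
    y
  }
  res <- try(minpack.lm::nls.lm(
    par = par0, fn = function(p) profile - model(p),
    lower = c(-Inf, -Inf, -Inf, rep(c(0, 1, 0.2), np)),
    upper = c(Inf, Inf, Inf, rep(c(Inf, length(px), length(px)), np)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)), silent = TRUE)
  if (inherits(res, "try-error")) return(centers0)
  res$par[3 * seq_len(np) + 2]
}

#' Calibrate the pixel-to-frequency mapping
#'
#' Anchors a linear pixel -> GHz mapping on the two Rayleigh order peaks
#' (which are one free spectral range apart by construction). With a water
#' reference profile, `refine = "quadratic"` adds a curvature term using the
#' known Stokes/anti-Stokes positions (`water_shift_ref` and
#' `fsr - water_shift_ref`) as two further anchors, fitted by least squares;
#' if the refined mapping is non-monotonic over the pixel range it falls
#' back to linear with a warning.
#'
#' @param profile numeric spectrum vs pixel (a water reference), or the list
#'   returned by [extract_dispersion_profile()].
#' @param fsr free spectral range (GHz).
#' @param water_shift_ref reference Brillouin shift of water (GHz); 7.4 GHz
#'   in backscattering at 532 nm.
#' @param refine `"linear"` or `"quadratic"`.
#' @return An object of class `calibration_model`: coefficients `coeffs`
#'   (`c0, c1, c2`, GHz per pixel powers), `fsr_anchor`, `water_anchor`,
#'   `rms_residual` (GHz), `pixel_range`.
#' @export
calibrate_axis <- function(profile, fsr, water_shift_ref = 7.4,
                           refine = c("linear", "quadratic")) {
  refine <- match.arg(refine)
  if (is.list(profile)) profile <- profile$profile
  px_axis <- seq_along(profile)
  # preferred route: the full four-peak comb fit in pixel space gives
  # sub-millipixel Rayleigh/Brillouin centres (far-order wings are part of
  # the fitted model). Falls back to per-peak refinement when the profile
  # has no Brillouin pair.
  anchors <- tryCatch({
    ft <- fit_spectrum(profile, freq = px_axis)
    if (!isTRUE(ft$converged)) bdb_stop("no convergence", "bdb_fit_error")
    list(ray = sort(c(ft$parameters[["c_r1"]], ft$parameters[["c_r2"]])),
         bri = sort(c(ft$parameters[["c_s"]], ft$parameters[["c_as"]])))
  }, bdb_error = function(e) {
    pk <- sort(find_peaks(profile, n = 2))
    if (length(pk) < 2)
      bdb_stop("calibration peaks not found", "bdb_calibration_error")
    pk <- sort(refine_peaks_joint(profile, pk))
    list(ray = pk, bri = numeric(0))
  })
  ray <- anchors$ray
  bri <- anchors$bri
  c1_lin <- fsr / (ray[2] - ray[1])
  c0_lin <- -c1_lin * ray[1]
  coeffs <- c(c0_lin, c1_lin, 0)
  rms <- if (length(bri) >= 2) {
    pred <- c0_lin + c1_lin * bri
    sqrt(mean((pred - c(water_shift_ref, fsr - water_shift_ref))^2))
  } else NA_real_
  if (refine == "quadratic") {
    if (length(bri) < 2)
      bdb_stop("quadratic refinement needs the water Brillouin pair",
               "bdb_calibration_error")
    px <- c(ray[1], bri[1], bri[2], ray[2])
    nu <- c(0, water_shift_ref, fsr - water_shift_ref, fsr)
    fitq <- stats::lm(nu ~ px + I(px^2))
    cq <- unname(stats::coef(fitq))
    # monotonic over the pixel range?
    pr <- range(seq_along(profile))
    dmin <- min(cq[2] + 2 * cq[3] * pr)
    if (dmin <= 0) {
      bdb_warn("refined mapping non-monotonic; falling back to linear",
               "bdb_calibration_warning")
    } else {
      coeffs <- cq
      rms <- sqrt(mean(stats::residuals(fitq)^2))
    }
  }
  structure(list(coeffs = coeffs, fsr_anchor = fsr,
                 water_anchor = water_shift_ref, rms_residual = rms,
                 pixel_range = c(1L, length(profile)),
                 rayleigh_px = ray),
            class = "calibration_model")
}

#' Evaluate a calibration mapping
#'
#' @param object a `calibration_model`.
#' @param pixel pixel coordinates.
#' @param ... unused.
#' @return frequency offsets (GHz).
#' @export
predict.calibration_model <- function(object, pixel, ...) {
  cf <- object$coeffs
  cf[1] + cf[2] * pixel + cf[3] * pixel^2
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> nu = %.4g + %.4g px + %.3g px^2 (rms %.2g GHz)\n",
    x$coeffs[1], x$coeffs[2], x$coeffs[3], x$rms_residual))
  invisible(x)
}
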