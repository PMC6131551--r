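# Simultaneous Lorentzian fitting of Brillouin spectra.

#' Fit a calibrated Brillouin spectrum
#'
#' Simultaneous least-squares fit (Levenberg-Marquardt) of two Rayleigh and
#' two Brillouin (Stokes/anti-Stokes) Lorentzians plus a constant background.
#' To keep the model exact on windows wider than one order, each fitted peak
#' is replicated at `m * spacing` for `m = -2..2`, where the order spacing is
#' itself tied to the two Rayleigh centres; replicas share amplitude and
#' width with their base peak.
#'
#' The reported Brillouin shift is the arithmetic mean of the Stokes offset
#' from the lower Rayleigh peak and the anti-Stokes offset from the upper
#' one; the reported linewidth is the mean FWHM of the two Brillouin peaks.
#' Standard errors come from the parameter covariance (delta method for the
#' means).
#'
#' @param spectrum numeric counts, or a data frame with columns
#'   `freq`/`pixel` and `counts`.
#' @param freq frequency axis (GHz) when `spectrum` is a bare vector and no
#'   calibration is supplied.
#' @param calibration optional [calibrate_axis()] result mapping pixel to
#'   GHz; required when the input axis is in pixels.
#' @param init optional named list of starting values
#'   (`c_r1, c_r2, c_s, c_as, f_r, f_s, f_as, a_r, a_s, a_as, bg`);
#'   defaults come from median-filtered peak detection.
#' @param saturation optional clip level; samples at or above it are
#'   excluded from the residuals and a `saturated` flag is set.
#' @param snr_min detection threshold: fits with SNR below it raise a
#'   below-detection error (`check_detectable = TRUE`) or only flag it.
#' @param fix_rayleigh optional numeric length-2: hold the two Rayleigh
#'   centres at these frequencies (GHz), as when the order positions are
#'   known from a calibration reference. Used together with
#'   `exclude_elastic_GHz` for crosstalk-limited spectra whose elastic cores
#'   saturate or are not Lorentzian.
#' @param exclude_elastic_GHz optional half-width (GHz): samples within this
#'   distance of either Rayleigh centre are excluded from the residuals.
#' @param weighting `"none"` (ordinary least squares, default) or `"shot"`
#'   (residuals weighted by `1/sqrt(counts + read_sigma^2 + 1)`, the
#'   inverse shot-noise SD, which calibrates the reported standard errors
#'   for photon-noise-limited spectra).
#' @param read_sigma read-noise SD (counts) used by the `"shot"` weighting.
#' @param check_detectable raise `bdb_below_detection` when the Brillouin
#'   peaks are not detectable (see [detectability()]).
#' @return An object of class `fit_result`: `shift`, `shift_se`, `linewidth`,
#'   `linewidth_se` (GHz), `offsets` (Stokes/anti-Stokes, with SEs),
#'   `amplitudes`, `background`, `r_squared`, `snr`, `converged`,
#'   `saturated`, and the fitted `parameters`.
#' @export
fit_spectrum <- function(spectrum, freq = NULL, calibration = NULL,
                         init = NULL, saturation = NULL, snr_min = 5,
                         check_detectable = FALSE, fix_rayleigh = NULL,
                         exclude_elastic_GHz = NULL,
                         weighting = c("none", "shot"), read_sigma = 0) {
  weighting <- match.arg(weighting)
  if (is.data.frame(spectrum)) {
    counts <- spectrum$counts
    if (!is.null(spectrum$freq)) freq <- spectrum$freq
    else if (!is.null(spectrum$pixel) && !is.null(calibration))
      freq <- predict(calibration, spectrum$pixel)
    else bdb_stop("spectrum data frame needs 'freq', or 'pixel' plus a calibration",
                  "bdb_invalid_input")
  } else {
    counts <- as.numeric(spectrum)
    if (is.null(freq)) {
      if (is.null(calibration))
        bdb_stop("supply 'freq' or a calibration", "bdb_invalid_input")
      freq <- predict(calibration, seq_along(counts))
    }
  }
  # reject structurally negative input; small negatives at the read-noise
  # scale are expected after background subtraction and are kept
  if (any(counts < 0) && min(counts) < -0.05 * max(abs(counts)))
    bdb_stop("spectrum must be nonnegative", "bdb_invalid_input")
  use <- rep(TRUE, length(counts))
  saturated <- FALSE
  if (!is.null(saturation)) {
    use <- counts < saturation
    saturated <- any(!use)
  }

  if (check_detectable) {
    det <- detectability(counts, freq, k = snr_min)
    if (!det$detectable)
      bdb_stop(sprintf("Brillouin peaks below detection (snr = %.2g < %g)",
                       det$snr, snr_min), "bdb_below_detection")
  }

  if (is.null(init)) {
    init <- if (is.null(fix_rayleigh)) init_from_peaks(freq, counts)
            else init_between_rayleigh(freq, counts, fix_rayleigh)
  }
  if (!is.null(fix_rayleigh)) {
    init$c_r1 <- fix_rayleigh[1]
    init$c_r2 <- fix_rayleigh[2]
  }
  p0 <- c(init$c_r1, init$c_r2, init$c_s, init$c_as,
          init$f_r, init$f_s, init$f_as,
          init$a_r, init$a_s, init$a_as, init$bg)
  names(p0) <- c("c_r1", "c_r2", "c_s", "c_as", "f_r", "f_s", "f_as",
                 "a_r", "a_s", "a_as", "bg")
  if (!is.null(exclude_elastic_GHz)) {
    rc <- if (!is.null(fix_rayleigh)) fix_rayleigh
          else c(init$c_r1, init$c_r2)
    sp0 <- rc[2] - rc[1]
    for (m in -2:3)
      use <- use & (abs(freq - (rc[1] + m * sp0)) > exclude_elastic_GHz)
  }
  fr <- freq[use]; cn <- counts[use]
  wts <- if (weighting == "shot")
    1 / sqrt(pmax(cn, 0) + read_sigma^2 + 1) else rep(1, length(cn))
  span <- diff(range(freq))

  model <- function(p) fit_model_eval(p, fr)
  lower <- c(rep(min(freq) - span, 4), rep(1e-4, 3), rep(0, 3), -Inf)
  upper <- c(rep(max(freq) + span, 4), rep(span, 3), rep(Inf, 3), Inf)
  if (!is.null(fix_rayleigh)) {
    lower[1:2] <- fix_rayleigh
    upper[1:2] <- fix_rayleigh
  }
  res <- try(minpack.lm::nls.lm(
    par = p0, fn = function(p) wts * (cn - model(p)),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15)), silent = TRUE)
  converged <- !inherits(res, "try-error") && res$info %in% 1:4
  if (inherits(res, "try-error")) {
    return(structure(list(converged = FALSE,
                          diagnostics = as.character(res)),
                     class = "fit_result"))
  }
  p <- res$par
  fitted <- model(p)
  rss <- sum((cn - fitted)^2)
  tss <- sum((cn - mean(cn))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  dof <- max(length(cn) - length(p), 1)
  sigma2 <- sum((wts * (cn - fitted))^2) / dof
  covm <- try(sigma2 * solve(res$hessian), silent = TRUE)
  if (inherits(covm, "try-error") || any(!is.finite(diag(covm))))
    covm <- matrix(NA_real_, length(p), length(p),
                   dimnames = list(names(p0), names(p0)))
  dimnames(covm) <- list(names(p0), names(p0))

  off_s <- p[["c_s"]] - p[["c_r1"]]
  off_as <- p[["c_r2"]] - p[["c_as"]]
  shift <- (off_s + off_as) / 2
  lw <- (p[["f_s"]] + p[["f_as"]]) / 2
  se_of <- function(w) {    # delta method for a linear combination w'p
    v <- drop(t(w) %*% covm %*% w)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }
  wn <- stats::setNames(numeric(length(p)), names(p0))
  w_shift <- wn; w_shift[c("c_s", "c_r2")] <- 0.5
  w_shift[c("c_r1", "c_as")] <- -0.5
  w_lw <- wn; w_lw[c("f_s", "f_as")] <- 0.5
  w_os <- wn; w_os["c_s"] <- 1; w_os["c_r1"] <- -1
  w_oas <- wn; w_oas["c_r2"] <- 1; w_oas["c_as"] <- -1

  sigma_res <- sqrt(sigma2)
  snr <- if (sigma_res > 0) min(p[["a_s"]], p[["a_as"]]) / sigma_res else Inf

  structure(list(
    shift = shift, shift_se = se_of(w_shift),
    linewidth = lw, linewidth_se = se_of(w_lw),
    offsets = c(stokes = off_s, anti_stokes = off_as),
    offset_se = c(stokes = se_of(w_os), anti_stokes = se_of(w_oas)),
    amplitudes = c(rayleigh = p[["a_r"]], stokes = p[["a_s"]],
                   anti_stokes = p[["a_as"]]),
    background = p[["bg"]], r_squared = r2, snr = snr,
    converged = converged, saturated = saturated,
    parameters = p, covariance = covm, sigma = sigma_res),
    class = "fit_result")
}

# Model: three order combs with common spacing sp = c_r2 - c_r1. The
# Rayleigh comb anchored at c_r1 contains c_r2 as its m = +1 member, so the
# two Rayleigh centres are independent parameters without double counting.
# Replicas (m = -4..4) share amplitude and width with their base peak, so
# the model family contains the generative order structure exactly.
fit_model_eval <- function(p, freq) {
  sp <- p[["c_r2"]] - p[["c_r1"]]
  y <- rep(p[["bg"]], length(freq))
  lor <- function(c0, g, a) a * (g / 2)^2 / ((freq - c0)^2 + (g / 2)^2)
  for (m in -4:4) {
    y <- y + lor(p[["c_r1"]] + m * sp, p[["f_r"]], p[["a_r"]]) +
      lor(p[["c_s"]] + m * sp, p[["f_s"]], p[["a_s"]]) +
      lor(p[["c_as"]] + m * sp, p[["f_as"]], p[["a_as"]])
  }
  y
}

#' @export
print.fit_result <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<fit_result> NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("<fit_result> shift %.4f +- %.2g GHz, linewidth %.4f +- %.2g GHz\n",
              x$shift, x$shift_se, x$linewidth, x$linewidth_se))
  cat(sprintf("  r^2 = %.6f, snr = %.3g%s\n", x$r_squared, x$snr,
              if (x$saturated) ", saturated samples excluded" else ""))
  invisible(x)
}

#' @export
as.data.frame.fit_result <- function(x, ...) {
  data.frame(shift = x$shift, shift_se = x$shift_se,
             linewidth = x$linewidth, linewidth_se = x$linewidth_se,
             r_squared = x$r_squared, snr = x$snr,
             converged = x$converged)
}

# plateau-tolerant local maxima (median filtering flattens peak tops)
local_maxima <- function(v) {
  s <- sign(diff(v))
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  # carry the last nonzero slope forward through plateaus
  idx <- cummax(ifelse(nz, seq_along(s), 0L))
  s_f <- ifelse(idx > 0, s[pmax(idx, 1L)], 0)
  which(diff(s_f) == -2) + 1L
}

# starting values from median-filtered local maxima: Rayleigh = two tallest,
# Brillouin = two tallest between them
init_from_peaks <- function(freq, counts) {
  ord <- order(freq)
  f <- freq[ord]; y <- counts[ord]
  sm <- stats::runmed(y, 5)
  cand <- local_maxima(sm)
  if (length(cand) < 4)
    bdb_stop("fewer than 4 candidate peaks for initialization",
             "bdb_fit_error")
  tall <- cand[order(sm[cand], decreasing = TRUE)]
  # two tallest with decent separation = Rayleigh
  r1 <- tall[1]
  r2 <- tall[which(abs(f[tall] - f[r1]) > 0.2 * diff(range(f)))[1]]
  ray <- sort(c(r1, r2))
  # keep Brillouin candidates away from the Rayleigh shoulders
  guard <- 0.08 * abs(f[ray[2]] - f[ray[1]])
  inner <- cand[f[cand] > f[ray[1]] + guard & f[cand] < f[ray[2]] - guard]
  if (length(inner) < 2)
    bdb_stop("Brillouin peaks not found between the Rayleigh peaks",
             "bdb_fit_error")
  inn_tall <- inner[order(sm[inner], decreasing = TRUE)]
  b1 <- inn_tall[1]
  # second Brillouin candidate must be a distinct peak, not a noise maximum
  # riding on the first one
  b2 <- inn_tall[which(abs(f[inn_tall] - f[b1]) >
                         0.1 * diff(range(f)))[1]]
  if (is.na(b2))
    bdb_stop("Brillouin peaks not found between the Rayleigh peaks",
             "bdb_fit_error")
  bri <- sort(c(b1, b2))
  bg0 <- stats::quantile(y, 0.05, names = FALSE)
  span <- diff(range(f))
  list(c_r1 = f[ray[1]], c_r2 = f[ray[2]], c_s = f[bri[1]], c_as = f[bri[2]],
       f_r = span / 80, f_s = span / 40, f_as = span / 40,
       a_r = max(sm[ray] - bg0), a_s = sm[bri[1]] - bg0,
       a_as = sm[bri[2]] - bg0, bg = bg0)
}

# starting values when the Rayleigh centres are known (fix_rayleigh):
# Brillouin candidates are the two tallest maxima between them
init_between_rayleigh <- function(freq, counts, rayleigh) {
  ord <- order(freq)
  f <- freq[ord]; y <- counts[ord]
  sm <- stats::runmed(y, 5)
  guard <- 0.08 * (rayleigh[2] - rayleigh[1])
  cand <- local_maxima(sm)
  inner <- cand[f[cand] > rayleigh[1] + guard &
                  f[cand] < rayleigh[2] - guard]
  if (length(inner) < 2)
    bdb_stop("Brillouin peaks not found between the Rayleigh peaks",
             "bdb_fit_error")
  inn_tall <- inner[order(sm[inner], decreasing = TRUE)]
  b1 <- inn_tall[1]
  b2 <- inn_tall[which(abs(f[inn_tall] - f[b1]) >
                         0.1 * (rayleigh[2] - rayleigh[1]))[1]]
  if (is.na(b2))
    bdb_stop("Brillouin peaks not found between the Rayleigh peaks",
             "bdb_fit_error")
  bri <- sort(c(b1, b2))
  bg0 <- stats::quantile(y, 0.05, names = FALSE)
  span <- rayleigh[2] - rayleigh[1]
  list(c_r1 = rayleigh[1], c_r2 = rayleigh[2],
       c_s = f[bri[1]], c_as = f[bri[2]],
       f_r = span / 80, f_s = span / 40, f_as = span / 40,
       a_r = max(y) - bg0, a_s = sm[bri[1]] - bg0, a_as = sm[bri[2]] - bg0,
       bg = bg0)
}

#' Detectability of the Brillouin peaks in a spectrum
#'
#' Declares the Brillouin doublet detectable when the prominence of the
#' tallest interior peak (between the Rayleigh peaks, Rayleigh shoulders
#' excluded) exceeds `k` times the background noise SD. The profile is first
#' smoothed with a moving average matched to the expected Brillouin width
#' (`match_width` GHz), so that single-sample noise spikes do not count as
#' peaks; the noise SD is the median absolute deviation of the residual
#' between the raw and smoothed interior samples. Returns an `Inf` SNR
#' sentinel for noiseless, background-free spectra.
#'
#' @param spectrum numeric counts.
#' @param freq frequency axis (GHz).
#' @param k prominence threshold in units of background sigma (default 5, a
#'   conservative documented constant).
#' @param match_width smoothing width (GHz) matched to the Brillouin FWHM.
#' @return list with `detectable` (logical) and `snr` (prominence / sigma).
#' @export
detectability <- function(spectrum, freq, k = 5, match_width = 0.5) {
  y <- as.numeric(spectrum)
  df <- stats::median(diff(sort(freq)))
  w <- max(3L, round(match_width / df))
  if (w %% 2 == 0) w <- w + 1L
  sm <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  cand <- local_maxima(sm)
  if (length(cand) < 2) return(list(detectable = FALSE, snr = 0))
  tall <- cand[order(sm[cand], decreasing = TRUE)]
  r1 <- tall[1]
  r2cand <- tall[which(abs(freq[tall] - freq[r1]) >
                         0.2 * diff(range(freq)))[1]]
  if (is.na(r2cand)) return(list(detectable = FALSE, snr = 0))
  ray <- sort(c(r1, r2cand))
  inner <- seq(ray[1], ray[2])
  # exclude Rayleigh shoulders (10% of the order span on each side)
  guard <- ceiling(0.1 * length(inner))
  core <- inner[(guard + 1):(length(inner) - guard)]
  if (length(core) < 9) return(list(detectable = FALSE, snr = 0))
  yc <- y[core]; smc <- sm[core]
  pk <- local_maxima(smc)
  if (length(pk) < 1) return(list(detectable = FALSE, snr = 0))
  base <- stats::median(smc)
  prom <- max(smc[pk] - base)
  sig <- stats::mad(yc - smc)
  if (sig == 0) {
    snr <- if (prom > 0) Inf else 0
  } else snr <- prom / sig
  list(detectable = is.infinite(snr) || snr > k, snr = snr)
}
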