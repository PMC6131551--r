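# Synthetic cell phantoms: labelled 3D volumes with per-compartment
# Brillouin ground truth, raster-scanned into per-voxel spectra.

#' Compartment legend used by all phantoms
#'
#' @return named integer vector mapping compartment names to label codes:
#'   medium 0, cytoplasm 1, nucleus 2, nucleolus 3, stress_granule 4.
#' @export
phantom_legend <- function() {
  c(medium = 0L, cytoplasm = 1L, nucleus = 2L, nucleolus = 3L,
    stress_granule = 4L)
}

#' Default per-compartment Brillouin ground truth
#'
#' Shifts and observed linewidths chosen inside the ranges typical of HeLa
#' cells at 532 nm: compartment shifts between 7.4 and 8.1 GHz and observed
#' FWHM between 0.8 and 1.2 GHz. The stress-granule linewidth defaults to
#' 0.86 GHz (granules without mutant-protein recruitment); pass
#' `mutant_granules = TRUE` for the stiff/viscous variant (8.1 GHz,
#' 1.13 GHz).
#'
#' @param mutant_granules logical.
#' @return data frame with columns `label`, `compartment`, `shift_GHz`,
#'   `linewidth_GHz` (observed FWHM).
#' @export
default_truth_table <- function(mutant_granules = FALSE) {
  leg <- phantom_legend()
  data.frame(
    label = unname(leg),
    compartment = names(leg),
    shift_GHz = c(7.40, 7.80, 7.95, 8.10,
                  if (mutant_granules) 8.10 else 7.90),
    linewidth_GHz = c(0.80, 0.95, 1.00, 1.05,
                      if (mutant_granules) 1.13 else 0.86)
  )
}

#' Generate a synthetic single-cell phantom
#'
#' Builds a labelled 3D volume (axis order z, y, x; 0-based voxel indexing in
#' all tables) emulating a raster-scanned adherent cell: an ellipsoidal cell
#' in medium, an ellipsoidal nucleus with 1-3 spherical nucleoli, and 0-10
#' spherical stress granules (diameter 0.5-2 um) placed fully inside the
#' cytoplasm. All geometry is deterministic under `seed`.
#'
#' @param dim_vox volume size in voxels, `c(nz, ny, nx)`.
#' @param voxel_size voxel pitch in um, `c(z, y, x)`; default the scan steps
#'   `c(1.0, 0.4, 0.4)`.
#' @param cell_radius_um cell semi-axes in um, `c(z, y, x)`; default fills
#'   ~75% of the field.
#' @param nucleus_scale nucleus semi-axes as a fraction of the cell's.
#' @param n_nucleoli number of nucleoli (0-3).
#' @param nucleolus_radius_um nucleolus radius (um).
#' @param n_granules number of stress granules (0-10); ignored when
#'   `granule_volume_fraction` is given.
#' @param granule_diameter_um length-2 range of granule diameters (um).
#' @param granule_volume_fraction optional target granule volume as a
#'   fraction of the cytoplasm volume; granules are added until the realised
#'   fraction reaches the target.
#' @param truth truth table as from [default_truth_table()].
#' @param psf_fwhm optical PSF FWHM in um, `c(z, y, x)`; default the
#'   confocal resolution `c(1.1, 0.3, 0.3)`.
#' @param seed integer seed.
#' @return An object of class `cell_phantom`: `labels` (3D integer array),
#'   `voxel_size`, `psf_fwhm`, `truth`, `legend`, `seed`.
#' @export
synth_phantom <- function(dim_vox = c(12, 40, 40),
                          voxel_size = c(1.0, 0.4, 0.4),
                          cell_radius_um = NULL,
                          nucleus_scale = 0.55,
                          n_nucleoli = 2,
                          nucleolus_radius_um = 1.2,
                          n_granules = 5,
                          granule_diameter_um = c(0.5, 2.0),
                          granule_volume_fraction = NULL,
                          truth = default_truth_table(),
                          psf_fwhm = c(1.1, 0.3, 0.3),
                          seed = 1L) {
  stopifnot(length(dim_vox) == 3L, all(dim_vox >= 2),
            all(voxel_size > 0), all(psf_fwhm >= 0))
  need <- c("label", "compartment", "shift_GHz", "linewidth_GHz")
  if (!all(need %in% names(truth)))
    bdb_stop("truth table must have columns label, compartment, shift_GHz, linewidth_GHz",
             "bdb_invalid_spec")
  if (n_nucleoli < 0 || n_nucleoli > 3)
    bdb_stop("n_nucleoli must be in 0..3", "bdb_invalid_spec")
  if (is.null(granule_volume_fraction) &&
      (n_granules < 0 || n_granules > 10))
    bdb_stop("n_granules must be in 0..10", "bdb_invalid_spec")

  ext <- dim_vox * voxel_size                 # physical extent (um), z,y,x
  if (is.null(cell_radius_um)) cell_radius_um <- 0.375 * ext

  with_seed(seed, {
    # physical voxel-centre coordinates
    cz <- (seq_len(dim_vox[1]) - 0.5) * voxel_size[1]
    cy <- (seq_len(dim_vox[2]) - 0.5) * voxel_size[2]
    cx <- (seq_len(dim_vox[3]) - 0.5) * voxel_size[3]
    ctr <- ext / 2
    Z <- array(rep(cz, times = dim_vox[2] * dim_vox[3]), dim = dim_vox)
    Y <- array(rep(rep(cy, each = dim_vox[1]), times = dim_vox[3]),
               dim = dim_vox)
    X <- array(rep(cx, each = dim_vox[1] * dim_vox[2]), dim = dim_vox)

    inside_ellipsoid <- function(c0, r)
      ((Z - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
        ((X - c0[3]) / r[3])^2 <= 1

    labels <- array(0L, dim = dim_vox)
    cell <- inside_ellipsoid(ctr, cell_radius_um)
    labels[cell] <- 1L

    nuc_r <- nucleus_scale * cell_radius_um
    # nucleus offset kept small enough to stay inside the cell
    off <- stats::runif(3, -0.15, 0.15) * cell_radius_um * (1 - nucleus_scale)
    nuc_c <- ctr + off
    nuc <- inside_ellipsoid(nuc_c, nuc_r)
    labels[nuc & cell] <- 2L

    if (n_nucleoli > 0) {
      for (i in seq_len(n_nucleoli)) {
        placed <- FALSE
        for (try in seq_len(200)) {
          u <- stats::runif(3, -0.6, 0.6)
          c0 <- nuc_c + u * nuc_r
          sph <- inside_ellipsoid(c0, rep(nucleolus_radius_um, 3))
          if (any(sph) && all(labels[sph] %in% c(2L, 3L))) {
            labels[sph] <- 3L
            placed <- TRUE
            break
          }
        }
        if (!placed)
          bdb_warn("could not place a nucleolus; skipped",
                   "bdb_placement_warning")
      }
    }

    cyto_n <- sum(labels == 1L)
    # candidate granule centres are drawn from cytoplasm voxel centres, so
    # placement succeeds whenever any cytoplasm pocket can hold the sphere
    place_granule <- function(diam) {
      r <- diam / 2
      cyto <- which(labels == 1L)
      if (!length(cyto)) return(FALSE)
      for (try in seq_len(400)) {
        i <- cyto[sample.int(length(cyto), 1)]
        c0 <- c(Z[i], Y[i], X[i])
        sph <- inside_ellipsoid(c0, rep(r, 3))
        if (any(sph) && all(labels[sph] == 1L)) {
          labels[sph] <<- 4L
          return(TRUE)
        }
      }
      FALSE
    }

    if (!is.null(granule_volume_fraction)) {
      chk_num(granule_volume_fraction, "granule_volume_fraction", 0, 0.2)
      target <- granule_volume_fraction * cyto_n
      guard <- 0L
      while (sum(labels == 4L) < target && guard < 1000L) {
        diam <- stats::runif(1, granule_diameter_um[1], granule_diameter_um[2])
        if (!place_granule(diam))
          bdb_stop("granule placement impossible (cytoplasm too thin)",
                   "bdb_placement_error")
        guard <- guard + 1L
      }
    } else if (n_granules > 0) {
      diams <- stats::runif(n_granules, granule_diameter_um[1],
                            granule_diameter_um[2])
      for (d in diams)
        if (!place_granule(d))
          bdb_stop("granule placement impossible (cytoplasm too thin)",
                   "bdb_placement_error")
    }

    present <- sort(unique(as.integer(labels)))
    if (!all(present %in% truth$label))
      bdb_stop("truth table does not cover all labels present",
               "bdb_invalid_spec")

    structure(list(labels = labels,
                   voxel_size = voxel_size, psf_fwhm = psf_fwhm,
                   truth = truth, legend = phantom_legend(), seed = seed),
              class = "cell_phantom")
  })
}

#' @export
print.cell_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<cell_phantom> %d x %d x %d voxels (z,y,x), voxel %s um\n",
              d[1], d[2], d[3], paste(x$voxel_size, collapse = " x ")))
  tab <- table(factor(x$labels, levels = x$truth$label,
                      labels = x$truth$compartment))
  print(tab)
  invisible(x)
}

#' Separable Gaussian blur of a 3D volume
#'
#' Convolution with a Gaussian of the given FWHM per axis, applied
#' separably with *periodic* (wrap-around) boundaries, which conserves the
#' volume mean exactly for the normalised kernel.
#'
#' @param vol 3D numeric array (z, y, x).
#' @param fwhm_um blur FWHM per axis (um), `c(z, y, x)`; 0 skips the axis.
#' @param voxel_size voxel pitch (um), `c(z, y, x)`.
#' @return blurred array, same dim.
#' @export
blur_volume <- function(vol, fwhm_um, voxel_size) {
  stopifnot(length(dim(vol)) == 3L)
  out <- vol
  for (ax in 1:3) {
    s <- fwhm_um[ax] / (2 * sqrt(2 * log(2))) / voxel_size[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    out <- apply_axis_conv(out, ax, k)
  }
  out
}

# periodic 1D convolution along axis ax of a 3D array
apply_axis_conv <- function(a, ax, k) {
  d <- dim(a)
  n <- d[ax]
  r <- (length(k) - 1L) / 2L
  idx <- outer(seq_len(n), seq(-r, r), function(i, o) ((i + o - 1L) %% n) + 1L)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)                    # rows = axis of interest
  res <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    res <- res + k[j] * m[idx[, j], , drop = FALSE]
  out <- array(res, dim = d[perm])
  aperm(out, order(perm))
}

#' Raster-scan a phantom into per-voxel spectra
#'
#' Computes per-voxel ground-truth shift and linewidth maps (the label truth
#' blurred by the optical PSF — the partial-volume model is a Gaussian blur
#' of the parameter maps, keeping each voxel's spectrum single-component),
#' then synthesises one spectrum per voxel and optionally applies camera
#' noise.
#'
#' The truth table stores *observed* linewidths; the material `linewidth`
#' passed to the generator is the observed value minus
#' `model_defaults$instrument_width` (floored at 0.01 GHz).
#'
#' @param phantom a [cell_phantom()][synth_phantom()].
#' @param model_defaults a [spectrum_model()] supplying amplitudes, FSR and
#'   instrument width (its shift/linewidth are overridden per voxel).
#' @param noise a [noise_model()] or `NULL` (noiseless). Per-voxel noise
#'   seeds derive deterministically from `noise$seed`.
#' @param freq frequency axis (GHz); default `seq(-2, fsr + 2, by = 0.02)`.
#' @param apply_psf logical; `FALSE` skips the partial-volume blur.
#' @return list with `freq`, `spectra` (matrix `[n_freq, n_voxels]`, voxels
#'   in array order), `shift_true`, `width_true` (3D arrays, GHz), and
#'   `phantom`.
#' @export
phantom_to_spectra <- function(phantom, model_defaults = spectrum_model(),
                               noise = NULL, freq = NULL,
                               apply_psf = TRUE) {
  stopifnot(inherits(phantom, "cell_phantom"),
            inherits(model_defaults, "spectrum_model"))
  fsr <- model_defaults$fsr
  if (is.null(freq)) freq <- seq(-2, fsr + 2, by = 0.02)
  tr <- phantom$truth
  shift_lut <- stats::setNames(tr$shift_GHz, tr$label)
  width_lut <- stats::setNames(tr$linewidth_GHz, tr$label)
  key <- as.character(phantom$labels)
  shift_map <- array(unname(shift_lut[key]), dim = dim(phantom$labels))
  width_map <- array(unname(width_lut[key]), dim = dim(phantom$labels))
  if (apply_psf && any(phantom$psf_fwhm > 0)) {
    shift_map <- blur_volume(shift_map, phantom$psf_fwhm, phantom$voxel_size)
    width_map <- blur_volume(width_map, phantom$psf_fwhm, phantom$voxel_size)
  }
  nv <- length(shift_map)
  spectra <- matrix(0, nrow = length(freq), ncol = nv)
  iw <- model_defaults$instrument_width
  for (i in seq_len(nv)) {
    m <- model_defaults
    m$shift <- shift_map[i]
    m$linewidth <- max(width_map[i] - iw, 0.01)
    spectra[, i] <- synth_spectrum(m, freq)
  }
  if (!is.null(noise)) {
    for (i in seq_len(nv)) {
      ni <- noise
      ni$seed <- (noise$seed + 97L * i) %% .Machine$integer.max
      spectra[, i] <- add_noise(spectra[, i], ni)
    }
  }
  list(freq = freq, spectra = spectra, shift_true = shift_map,
       width_true = width_map, phantom = phantom)
}
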