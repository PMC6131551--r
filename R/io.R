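# Readers and writers for the package's on-disk formats: 32-bit float TIFF
# with JSON sidecars for images/volumes, CSV for spectra and fit tables.

#' Write an interference pattern (or kernel) to TIFF + JSON sidecar
#'
#' Intensity is written as a single-page 32-bit float TIFF (scaled to the
#' unit range required by the TIFF writer; the scale factor is recorded in
#' the sidecar), axes and frequency mapping in `<path>.json`.
#'
#' @param pattern an `interference_pattern` or `aperture_kernel`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  img <- pattern$intensity
  scale <- max(img)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(img / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(scale = scale,
               x_axis_m = as.numeric(pattern$x_axis %||% pattern$x),
               y_axis_m = as.numeric(pattern$y_axis %||% pattern$y),
               dispersion_row = pattern$dispersion_row,
               freq_map_GHz = as.numeric(pattern$freq_map),
               fsr_GHz = pattern$fsr)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an interference pattern written by [write_pattern()]
#'
#' @param path TIFF path (expects `<path>.json` sidecar).
#' @return an `interference_pattern`-like list.
#' @export
read_pattern <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(intensity = img * meta$scale, x_axis = meta$x_axis_m,
                 y_axis = meta$y_axis_m,
                 dispersion_row = meta$dispersion_row,
                 freq_map = meta$freq_map_GHz, fsr = meta$fsr_GHz),
            class = "interference_pattern")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a 1D spectrum as CSV
#'
#' Two-column CSV, `freq_GHz` (or `pixel`) and `counts`.
#'
#' @param freq frequency axis (GHz) or pixel index.
#' @param counts intensity values.
#' @param path output path.
#' @param axis column name for the abscissa, `"freq_GHz"` or `"pixel"`.
#' @return `path` invisibly (write); data frame with `freq`/`pixel` and
#'   `counts` (read).
#' @export
write_spectrum_csv <- function(freq, counts, path, axis = "freq_GHz") {
  d <- data.frame(a = freq, counts = counts)
  names(d)[1] <- axis
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  names(d)[1] <- if (names(d)[1] == "pixel") "pixel" else "freq"
  d
}

#' Write a 3D volume as multi-page TIFF + JSON metadata
#'
#' Pages are z slices; each page is the `[y, x]` plane. Float volumes are
#' scaled into the unit range (scale recorded in the sidecar); integer label
#' volumes are written as 8-bit.
#'
#' @param vol 3D array (z, y, x).
#' @param path output TIFF path.
#' @param voxel_size voxel pitch (um), recorded in the sidecar.
#' @param labels logical: write as uint8 labels.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, voxel_size = c(1.0, 0.4, 0.4),
                              labels = FALSE) {
  d <- dim(vol)
  pages <- lapply(seq_len(d[1]), function(i) {
    pl <- matrix(vol[i, , ], d[2], d[3])
    pl
  })
  if (labels) {
    pages <- lapply(pages, function(p) p / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    scale <- 255; offset <- 0
  } else {
    offset <- min(vol, na.rm = TRUE)
    scale <- max(vol - offset, na.rm = TRUE)
    if (!is.finite(scale) || scale <= 0) scale <- 1
    pages <- lapply(pages, function(p) {
      p <- (p - offset) / scale
      p[!is.finite(p)] <- 0
      p
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  meta <- list(scale = scale, offset = offset, dim_zyx = d,
               voxel_size_um = voxel_size,
               axes = "zyx", indexing = "0-based", labels = labels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF path.
#' @return list with `volume` (3D array, z, y, x) and `voxel_size`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim_zyx)
  off <- meta$offset %||% 0
  vol <- array(0, d)
  for (i in seq_len(d[1])) vol[i, , ] <- pages[[i]] * meta$scale + off
  if (isTRUE(meta$labels)) vol <- array(as.integer(round(vol)), d)
  list(volume = vol, voxel_size = meta$voxel_size_um)
}

#' Write a fit table to CSV
#'
#' One row per voxel: `x, y, z, shift, shift_se, linewidth, linewidth_se,
#' r_squared, snr, converged`.
#'
#' @param fits data frame from [fit_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fits_csv
#' @export
read_fits_csv <- function(path) utils::read.csv(path)

#' Write compartment statistics to tidy CSV
#'
#' @param stats a [compartment_statistics()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(stats$per_cell, path, row.names = FALSE)
  invisible(path)
}
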