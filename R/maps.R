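# Assembling per-voxel fits into Brillouin maps and registering label masks.

#' Reconstruct Brillouin maps from a fit table
#'
#' Places per-voxel fit results onto the scan grid. Rows must carry 0-based
#' integer grid coordinates `z, y, x`. Voxels that are missing, failed to
#' converge, or fall below the SNR threshold are marked invalid and excluded
#' from every downstream statistic.
#'
#' @param fit_table data frame with columns `z, y, x, shift, linewidth`,
#'   optionally `shift_se, linewidth_se, r_squared, snr, converged`.
#' @param grid_dim grid size `c(nz, ny, nx)`.
#' @param voxel_size voxel pitch (um), `c(z, y, x)`.
#' @param snr_min validity threshold on `snr` (ignored if absent).
#' @return An object of class `brillouin_map`: `shift_map`, `width_map`,
#'   `r2_map`, `snr_map` (3D arrays), `valid_mask` (logical array),
#'   `voxel_size`.
#' @export
reconstruct_maps <- function(fit_table, grid_dim,
                             voxel_size = c(1.0, 0.4, 0.4), snr_min = 5) {
  need <- c("z", "y", "x", "shift", "linewidth")
  if (!all(need %in% names(fit_table)))
    bdb_stop("fit table needs columns z, y, x, shift, linewidth",
             "bdb_invalid_input")
  idx <- cbind(fit_table$z, fit_table$y, fit_table$x)
  if (any(idx < 0) || any(t(t(idx) >= grid_dim)))
    bdb_stop("grid coordinates out of range", "bdb_invalid_input")
  lin <- idx[, 1] + grid_dim[1] * (idx[, 2] + grid_dim[2] * idx[, 3]) + 1
  if (anyDuplicated(lin))
    bdb_stop("duplicate grid coordinates in fit table", "bdb_conflict_error")
  n <- prod(grid_dim)
  mk <- function(v, fill = NA_real_) {
    a <- array(fill, grid_dim); a[lin] <- v; a
  }
  shift_map <- mk(fit_table$shift)
  width_map <- mk(fit_table$linewidth)
  r2_map <- mk(if (!is.null(fit_table$r_squared)) fit_table$r_squared
               else rep(NA_real_, nrow(fit_table)))
  snr_map <- mk(if (!is.null(fit_table$snr)) fit_table$snr
                else rep(Inf, nrow(fit_table)))
  valid <- array(FALSE, grid_dim)
  ok <- rep(TRUE, nrow(fit_table))
  if (!is.null(fit_table$converged)) ok <- ok & fit_table$converged
  if (!is.null(fit_table$snr)) ok <- ok & (fit_table$snr >= snr_min)
  valid[lin] <- ok
  if (length(lin) < n)
    bdb_warn(sprintf("%d grid voxels have no fit; marked invalid",
                     n - length(lin)), "bdb_gap_warning")
  structure(list(shift_map = shift_map, width_map = width_map,
                 r2_map = r2_map, snr_map = snr_map, valid_mask = valid,
                 voxel_size = voxel_size),
            class = "brillouin_map")
}

#' @export
print.brillouin_map <- function(x, ...) {
  d <- dim(x$shift_map)
  cat(sprintf("<brillouin_map> %d x %d x %d voxels, %d valid (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Resample a fine-grid label mask onto the Brillouin scan grid
#'
#' Nearest-neighbour (default) or majority-vote resampling from a
#' fluorescence-resolution label volume (e.g. 0.1 um pitch) onto the coarser
#' Brillouin grid (0.4 / 1.0 um). Both grids are assumed to share the origin
#' of their first voxel's corner; physical extents must overlap.
#'
#' @param fine_labels 3D integer array (z, y, x) of compartment labels.
#' @param fine_voxel voxel pitch of `fine_labels` (um), `c(z, y, x)`.
#' @param grid_dim target grid `c(nz, ny, nx)`.
#' @param voxel_size target voxel pitch (um).
#' @param method `"nearest"` or `"majority"`.
#' @param legend named label legend; default [phantom_legend()].
#' @return An object of class `label_mask`: `labels` (3D array on the target
#'   grid), `legend`.
#' @export
register_mask <- function(fine_labels, fine_voxel, grid_dim,
                          voxel_size = c(1.0, 0.4, 0.4),
                          method = c("nearest", "majority"),
                          legend = phantom_legend()) {
  method <- match.arg(method)
  fd <- dim(fine_labels)
  if (any(fd * fine_voxel < 0.5 * voxel_size) ||
      all((grid_dim * voxel_size) < fine_voxel))
    bdb_stop("grid extents are disjoint", "bdb_registration_error")
  out <- array(0L, grid_dim)
  # centres of target voxels in physical coordinates
  ctr <- lapply(1:3, function(ax)
    (seq_len(grid_dim[ax]) - 0.5) * voxel_size[ax])
  near_idx <- lapply(1:3, function(ax)
    pmin(pmax(ceiling(ctr[[ax]] / fine_voxel[ax]), 1L), fd[ax]))
  if (method == "nearest") {
    for (k in seq_len(grid_dim[3]))
      for (j in seq_len(grid_dim[2]))
        out[, j, k] <- fine_labels[cbind(near_idx[[1]], near_idx[[2]][j],
                                         near_idx[[3]][k])]
  } else {
    # majority vote over the fine voxels covered by each coarse voxel
    rng <- lapply(1:3, function(ax) {
      lo <- pmin(pmax(floor((seq_len(grid_dim[ax]) - 1) * voxel_size[ax] /
                              fine_voxel[ax]) + 1L, 1L), fd[ax])
      hi <- pmin(pmax(ceiling(seq_len(grid_dim[ax]) * voxel_size[ax] /
                                fine_voxel[ax]), 1L), fd[ax])
      cbind(lo, hi)
    })
    for (k in seq_len(grid_dim[3]))
      for (j in seq_len(grid_dim[2]))
        for (i in seq_len(grid_dim[1])) {
          sub <- fine_labels[rng[[1]][i, 1]:rng[[1]][i, 2],
                             rng[[2]][j, 1]:rng[[2]][j, 2],
                             rng[[3]][k, 1]:rng[[3]][k, 2]]
          tb <- table(sub)
          out[i, j, k] <- as.integer(names(tb)[which.max(tb)])
        }
  }
  structure(list(labels = out, legend = legend), class = "label_mask")
}
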