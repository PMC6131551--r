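# Compartment statistics and group comparisons. The statistical unit is the
# cell: voxel values are first averaged per (cell, compartment), and group
# summaries and tests operate on those cell means.

#' Per-compartment statistics of a Brillouin map
#'
#' Computes, for each (cell, compartment), the number of valid voxels and
#' the mean / SD / median / quartiles / Tukey whiskers of the Brillouin
#' shift, and compartment summaries across cells (mean of cell means, SD,
#' number of cells). Quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7); whiskers extend to the most extreme points
#' within 1.5 IQR of the quartiles.
#'
#' @param map a [reconstruct_maps()] result (or a list of them, one per
#'   cell).
#' @param mask a [register_mask()] result, a `cell_phantom` (its truth
#'   labels), or a plain integer array aligned to the map grid. For a list
#'   of maps, a list of masks of the same length.
#' @param cell_ids optional cell identifiers (default `seq_along`).
#' @param value `"shift"` (default) or `"linewidth"`.
#' @return An object of class `compartment_stats`: list with `per_cell` and
#'   `per_compartment` data frames.
#' @export
compartment_statistics <- function(map, mask, cell_ids = NULL,
                                   value = c("shift", "linewidth")) {
  value <- match.arg(value)
  maps <- if (inherits(map, "brillouin_map")) list(map) else map
  masks <- if (!is.list(mask) || inherits(mask, "label_mask") ||
               inherits(mask, "cell_phantom")) list(mask) else mask
  if (length(masks) == 1L && length(maps) > 1L)
    masks <- rep(masks, length(maps))
  stopifnot(length(maps) == length(masks))
  if (is.null(cell_ids)) cell_ids <- seq_along(maps)
  legend <- phantom_legend()

  rows <- list()
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    lab <- mask_labels(masks[[i]])
    if (!all(dim(lab) == dim(m$shift_map)))
      bdb_stop("mask and map shapes differ", "bdb_invalid_input")
    vals <- if (value == "shift") m$shift_map else m$width_map
    for (lb in sort(unique(as.integer(lab)))) {
      sel <- lab == lb & m$valid_mask
      v <- vals[sel]
      v <- v[is.finite(v)]
      if (length(v) < 1L) {
        bdb_warn(sprintf("cell %s: compartment %d empty; omitted",
                         cell_ids[i], lb), "bdb_empty_compartment")
        next
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      wl <- min(v[v >= q[1] - 1.5 * iqr])
      wh <- max(v[v <= q[3] + 1.5 * iqr])
      nm <- names(legend)[match(lb, legend)]
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell_ids[i], label = lb,
        compartment = if (is.na(nm)) as.character(lb) else nm,
        n_voxels = length(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_lo = wl, whisker_hi = wh)
    }
  }
  per_cell <- do.call(rbind, rows)
  agg <- split(per_cell, per_cell$compartment)
  per_comp <- do.call(rbind, lapply(agg, function(d) data.frame(
    compartment = d$compartment[1], label = d$label[1],
    n_cells = nrow(d), mean = mean(d$mean),
    sd = if (nrow(d) > 1) stats::sd(d$mean) else 0)))
  rownames(per_comp) <- NULL
  structure(list(per_cell = per_cell, per_compartment = per_comp,
                 value = value),
            class = "compartment_stats")
}

mask_labels <- function(mask) {
  if (inherits(mask, "label_mask")) mask$labels
  else if (inherits(mask, "cell_phantom")) mask$labels
  else mask
}

#' @export
print.compartment_stats <- function(x, ...) {
  cat(sprintf("<compartment_stats> (%s)\n", x$value))
  print(x$per_compartment, row.names = FALSE)
  invisible(x)
}

#' Two-sample comparison of compartment cell means
#'
#' Two-sided two-sample t test on the per-cell mean shifts of one
#' compartment between two groups of cells. Pooled-variance Student form by
#' default; `welch = TRUE` drops the equal-variance assumption. When both
#' groups are degenerate (zero variance) with equal means the contract is
#' `t = 0, p = 1`.
#'
#' @param stats_a,stats_b [compartment_statistics()] results.
#' @param compartment compartment name (or label code).
#' @param welch logical.
#' @return An object of class `group_comparison`: `t_statistic`, `p_value`,
#'   `n` (per group), `effect` (difference of means a - b, GHz).
#' @export
compare_groups <- function(stats_a, stats_b, compartment = "cytoplasm",
                           welch = FALSE) {
  va <- cell_means(stats_a, compartment)
  vb <- cell_means(stats_b, compartment)
  if (length(va) < 2 || length(vb) < 2)
    bdb_stop("need >= 2 cells per group", "bdb_invalid_input")
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    eq <- isTRUE(all.equal(mean(va), mean(vb)))
    res <- list(statistic = if (eq) 0 else Inf * sign(mean(va) - mean(vb)),
                p.value = if (eq) 1 else 0)
  } else {
    res <- stats::t.test(va, vb, var.equal = !welch)
  }
  structure(list(t_statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 n = c(a = length(va), b = length(vb)),
                 effect = mean(va) - mean(vb),
                 compartment = compartment,
                 method = if (welch) "welch" else "student"),
            class = "group_comparison")
}

cell_means <- function(stats, compartment) {
  d <- stats$per_cell
  sel <- if (is.numeric(compartment)) d$label == compartment
         else d$compartment == compartment
  d$mean[sel]
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (%s t test): t = %.3f, p = %.3g, effect = %+.4f GHz (N = %d vs %d cells)\n",
    x$compartment, x$method, x$t_statistic, x$p_value, x$effect,
    x$n["a"], x$n["b"]))
  invisible(x)
}

#' Box-and-whisker summary
#'
#' Median, quartiles (linear-interpolation convention), Tukey whiskers at
#' the most extreme points within 1.5 IQR, and the outliers beyond them.
#'
#' @param values numeric vector (>= 1 value), or a `compartment_stats`
#'   object (summarised per compartment over cell means).
#' @return data frame with columns `n, median, q1, q3, whisker_lo,
#'   whisker_hi` and a list column `outliers`; one row per group.
#' @export
boxplot_summary <- function(values) {
  if (inherits(values, "compartment_stats")) {
    d <- values$per_cell
    out <- do.call(rbind, lapply(split(d$mean, d$compartment),
                                 boxplot_summary))
    out$compartment <- rownames(out)
    rownames(out) <- NULL
    return(out[, c("compartment", setdiff(names(out), "compartment"))])
  }
  v <- values[is.finite(values)]
  if (length(v) < 1L)
    bdb_stop("no values to summarise", "bdb_invalid_input")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  wl <- min(v[v >= q[1] - 1.5 * iqr])
  wh <- max(v[v <= q[3] + 1.5 * iqr])
  res <- data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
                    whisker_lo = wl, whisker_hi = wh)
  res$outliers <- list(v[v < wl | v > wh])
  res
}
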