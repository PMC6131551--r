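# Run configuration: YAML schema validation, deterministic seed fan-out,
# and the umbrella pipeline that ties the stages into reproducible runs.

# schema: known keys and defaults per section. Unknown keys are rejected by
# name so typos fail loudly.
config_schema <- function() {
  list(
    seed = 1L,
    output_dir = "bdb_run",
    log_level = "info",
    etalon = list(R1 = 0.999, R2 = 0.96, thickness_mm = 3.371,
                  n = 1.4607, tilt_deg = 0),
    mask = list(shape = "rhomboidal", width_mm = 8, height_mm = 4,
                rotation_deg = 0),
    layout = list(wavelength_nm = 532, focal_length_mm = 200,
                  beam_radius_mm = 2.2, pixel_pitch_um = 2,
                  fsr_span_mm = 1.0),
    phantom = list(nz = 6L, ny = 24L, nx = 24L, n_granules = 2L,
                   n_nucleoli = 1L, nucleolus_radius_um = 0.8,
                   granule_diameter_um = c(0.5, 1.2),
                   mutant_granules = FALSE, apply_psf = TRUE),
    spectrum = list(fsr_GHz = NA_real_, instrument_width_GHz = 0.3,
                    elastic_amp = 1000, brillouin_amp = 100,
                    freq_step_GHz = 0.02),
    noise = list(enabled = FALSE, shot = TRUE, read_sigma = 2,
                 saturation = 65535),
    fit = list(snr_min = 5)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration, validates every key against the
#' package schema (unknown keys are rejected with the offending name),
#' fills defaults, and attaches a provenance block (config hash and package
#' version).
#'
#' @param path file path, or `NULL` for an all-defaults configuration.
#' @return An object of class `run_config` (nested named list with a
#'   `provenance` attribute).
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
          else if (grepl("\\.json$", path))
            jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  schema <- config_schema()
  merged <- merge_config(schema, user, "")
  merged$seed <- as.integer(merged$seed)
  hash <- unname(substr(tools::md5sum(
    files = {
      tf <- tempfile()
      writeLines(jsonlite::toJSON(merged, auto_unbox = TRUE, digits = NA), tf)
      tf
    }), 1, 12))
  attr(merged, "provenance") <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("bdbmicro")))
  class(merged) <- "run_config"
  merged
}

merge_config <- function(schema, user, prefix) {
  extra <- setdiff(names(user), names(schema))
  if (length(extra))
    bdb_stop(sprintf("unknown configuration key%s: %s",
                     if (length(extra) > 1) "s" else "",
                     paste0(prefix, extra, collapse = ", ")),
             "bdb_config_error")
  out <- schema
  for (k in names(user)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      if (!is.list(user[[k]]))
        bdb_stop(sprintf("configuration key '%s%s' must be a section",
                         prefix, k), "bdb_config_error")
      out[[k]] <- merge_config(schema[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

#' Save a configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Deterministic per-stage child seeds
#'
#' Stages draw their randomness from child seeds derived from the single
#' global seed as `(seed * 7919 + stage_index) mod (2^31 - 1)`, so any stage
#' can be re-run in isolation with the same realisation.
#'
#' @param seed global integer seed.
#' @param stage stage index (1 = phantom, 2 = noise, 3 = fit, ...), or a
#'   stage name among `c("phantom", "noise", "fit", "cohort")`.
#' @return integer child seed.
#' @export
stage_seed <- function(seed, stage) {
  if (is.character(stage))
    stage <- match(stage, c("phantom", "noise", "fit", "cohort"))
  as.integer((as.numeric(seed) * 7919 + stage) %% (2^31 - 1))
}

#' Run the synthesis-to-statistics pipeline from a configuration
#'
#' Executes phantom synthesis, raster-scan spectrum generation, per-voxel
#' fitting, map reconstruction and compartment statistics, writing every
#' artifact under `config$output_dir` together with a manifest JSON listing
#' files and their MD5 checksums. Identical (config, seed) pairs produce
#' identical checksums.
#'
#' @param config a [load_config()] result (or `NULL` for defaults).
#' @param seed optional override of `config$seed`.
#' @param output_dir optional override of `config$output_dir`.
#' @return the manifest, invisibly (list with `artifacts`, `checksums`,
#'   `provenance`; on stage failure, `failed` records the stage and error
#'   and the manifest is partial).
#' @export
run_pipeline <- function(config = NULL, seed = NULL, output_dir = NULL) {
  if (is.null(config)) config <- load_config(NULL)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir <- output_dir %||% config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  manifest_path <- file.path(dir, "manifest.json")
  fail <- NULL

  res <- tryCatch({
    cfg <- config
    fsr <- if (is.na(cfg$spectrum$fsr_GHz)) {
      et <- etalon_spec(cfg$etalon$R1, cfg$etalon$R2,
                        cfg$etalon$thickness_mm * 1e-3, cfg$etalon$n,
                        cfg$etalon$tilt_deg * pi / 180)
      free_spectral_range(et)
    } else cfg$spectrum$fsr_GHz

    phantom <- synth_phantom(
      dim_vox = c(cfg$phantom$nz, cfg$phantom$ny, cfg$phantom$nx),
      n_granules = cfg$phantom$n_granules,
      n_nucleoli = cfg$phantom$n_nucleoli,
      nucleolus_radius_um = cfg$phantom$nucleolus_radius_um,
      granule_diameter_um = cfg$phantom$granule_diameter_um,
      truth = default_truth_table(cfg$phantom$mutant_granules),
      seed = stage_seed(cfg$seed, "phantom"))
    p_lab <- file.path(dir, "phantom_labels.tif")
    write_volume_tiff(phantom$labels, p_lab, phantom$voxel_size,
                      labels = TRUE)
    p_truth <- file.path(dir, "phantom_truth.csv")
    utils::write.csv(phantom$truth, p_truth, row.names = FALSE)
    artifacts <- c(artifacts, p_lab, paste0(p_lab, ".json"), p_truth)

    model <- spectrum_model(fsr = fsr,
                            instrument_width = cfg$spectrum$instrument_width_GHz,
                            elastic_amp = cfg$spectrum$elastic_amp,
                            brillouin_amp = cfg$spectrum$brillouin_amp)
    noise <- if (isTRUE(cfg$noise$enabled))
      noise_model(cfg$noise$shot, cfg$noise$read_sigma,
                  cfg$noise$saturation, seed = stage_seed(cfg$seed, "noise"))
    freq <- seq(-2, fsr + 2, by = cfg$spectrum$freq_step_GHz)
    scan <- phantom_to_spectra(phantom, model, noise = noise, freq = freq,
                               apply_psf = cfg$phantom$apply_psf)

    fits <- fit_scan(scan)
    p_fits <- file.path(dir, "fits.csv")
    write_fits_csv(fits, p_fits)
    artifacts <- c(artifacts, p_fits)

    map <- reconstruct_maps(fits, dim(phantom$labels),
                            voxel_size = phantom$voxel_size,
                            snr_min = cfg$fit$snr_min)
    p_shift <- file.path(dir, "shift_map.tif")
    p_width <- file.path(dir, "width_map.tif")
    write_volume_tiff(map$shift_map, p_shift, phantom$voxel_size)
    write_volume_tiff(map$width_map, p_width, phantom$voxel_size)
    artifacts <- c(artifacts, p_shift, paste0(p_shift, ".json"),
                   p_width, paste0(p_width, ".json"))

    st <- compartment_statistics(map, phantom)
    p_stats <- file.path(dir, "stats.csv")
    write_stats_csv(st, p_stats)
    artifacts <- c(artifacts, p_stats)
    TRUE
  }, bdb_error = function(e) {
    fail <<- list(stage = "pipeline", message = conditionMessage(e))
    FALSE
  })

  checks <- unname(tools::md5sum(artifacts))
  manifest <- list(
    artifacts = basename(artifacts),
    checksums = as.list(stats::setNames(checks, basename(artifacts))),
    seed = config$seed,
    provenance = attr(config, "provenance"),
    failed = fail)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!res) bdb_warn("pipeline stage failed; manifest is partial",
                     "bdb_stage_failure")
  invisible(manifest)
}
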