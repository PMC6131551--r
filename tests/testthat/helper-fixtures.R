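# Shared fixtures: default optics, water-like spectra, tiny phantoms.

default_etalon <- function() etalon_spec()
default_fsr <- function() free_spectral_range(etalon_spec())

water_model <- function(fsr = default_fsr(), ...) {
  spectrum_model(shift = 7.41, linewidth = 0.5, instrument_width = 0.3,
                 fsr = fsr, ...)
}

default_axis <- function(fsr = default_fsr(), by = 0.02) {
  seq(-2, fsr + 2, by = by)
}

# single-compartment phantom: every voxel is cytoplasm with the given truth
uniform_phantom <- function(shift, linewidth = 0.95, dim_vox = c(2, 8, 8),
                            seed = 1) {
  tr <- default_truth_table()
  tr$shift_GHz[tr$label == 1] <- shift
  tr$linewidth_GHz[tr$label == 1] <- linewidth
  synth_phantom(dim_vox = dim_vox,
                cell_radius_um = c(1e4, 1e4, 1e4),   # cell >> field
                nucleus_scale = 1e-6, n_nucleoli = 0, n_granules = 0,
                truth = tr, seed = seed)
}

# small cell phantom that reliably fits nucleus + granules
small_cell_phantom <- function(seed = 1, n_granules = 2, mutant = FALSE,
                               dim_vox = c(6, 24, 24)) {
  synth_phantom(dim_vox = dim_vox, n_granules = n_granules,
                n_nucleoli = 1, nucleolus_radius_um = 0.8,
                granule_diameter_um = c(0.8, 1.2),
                truth = default_truth_table(mutant), seed = seed)
}
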