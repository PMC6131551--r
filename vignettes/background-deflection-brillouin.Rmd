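---
title: "Simulating background-deflection Brillouin microscopy"
author: "bdbmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating background-deflection Brillouin microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdbmicro)
```

## The measurement being simulated

Brillouin microscopy maps the mechanics of living matter without contact or
labels. Light scattered inelastically off spontaneous GHz acoustic waves is
shifted in frequency by

$$\nu_B = \frac{2 n V}{\lambda}, \qquad V = \sqrt{M'/\rho},$$

so the Brillouin shift $\nu_B$ encodes the acoustic velocity $V$ and hence
the real (storage) part $M'$ of the longitudinal modulus, while the linewidth
$\Delta\nu_B$ (FWHM) tracks the imaginary (loss) part
$M'' = \rho\,(\lambda/2n)^2\,\nu_B\,\Delta\nu_B$ and therefore viscosity.
For water at 532 nm ($n = 1.33$, $V = 1482$ m/s) the shift is 7.41 GHz and
$M' \approx 2.19$ GPa — numbers `shift_from_velocity()` and
`modulus_real_from_shift()` reproduce directly.

The spectrometer is a single-stage VIPA (virtually imaged phased array): a
tilted solid etalon whose angular dispersion maps frequency to camera
position. Its Airy intensity transfer function
$T(\nu) = [1 + F\sin^2(\pi\nu/\mathrm{FSR})]^{-1}$ is periodic in the free
spectral range and bounds the contrast of an ideal single stage at
$1 + F = 4R/(1-R)^2 + 1 \approx 9.1\times 10^3$ for the modelled
reflectivities ($R_1 = 99.9\%$, $R_2 = 96\%$). The package computes the FSR
from the etalon's physical description — 3.371 mm of fused silica gives
30.44 GHz at 532 nm — rather than assuming a round number.

The elastic (Rayleigh) line in cells and turbid media is many orders of
magnitude stronger than the Brillouin doublet. The instrument concept
simulated here enhances contrast by reshaping the spectrometer pupil: a
rhomboidal aperture (8 mm x 4 mm, long diagonal along the dispersion axis)
replaces the usual circular stop. Its Fraunhofer diffraction pattern decays
as $(\sin u/u)^4 \sim u^{-4}$ along the diagonal, much faster than the Airy
pattern's $\sim v^{-3}$, and its bright diffraction tails leave the
dispersion axis at the edge-normal angles. The elastic background along the
axis is thereby deflected away from where the Brillouin peaks sit.

## The optical model and its deliberate simplifications

`camera_pattern()` builds the camera image as a line spectrum mapped onto
the dispersion axis and convolved with the pupil's intensity point-spread
kernel. Two background models are exposed, because two physically distinct
mechanisms set the inter-order background:

* **Open pupil (`"airy"` profile).** Each spectral line contributes the full
  etalon angular response, including the inter-order floor $1/(1+F)$. The
  dispersion profile of a monochromatic source then *equals* the Airy
  transfer function, and the spectral contrast reduces to $1 + F$ — the
  ideal-etalon bound for an unmasked single-stage instrument.
* **Masked pupil (`"comb"` profile).** The light that would form the
  on-axis floor is deflected off the dispersion axis, so each line
  contributes a comb of diffraction kernels and the residual background is
  set by the kernel tails alone. This is the deflection mechanism, and it is
  why a masked instrument can beat the Airy floor.

A full virtual-source-array field propagation is deliberately out of scope:
the convolution construction captures the quantity of interest (the
dispersion-axis background) at a fraction of the cost, but it does not model
polarization, aberrations, or the finite etalon aperture.

Because the published system's focal length, beam radius and angular
dispersion are not stated, all contrast figures refer to a documented
**reference layout** (`reference_layout()`): a 200 mm Fourier lens, 2.2 mm
illumination radius, and angular dispersion chosen so one FSR spans 1.0 mm
on the camera. Under this layout the rhomboid-vs-circular (4 mm diameter,
chosen to match the rhomboid's limiting dimension) background suppression
averaged over the 5-25 GHz band is about 21.5 dB as computed by
`band_suppression()` — the pointwise, lobe-averaged form whose closed-form
counterpart is the envelope ratio $8v/\pi \cdot (3\pi/8)/3 \propto v$. The
plain ratio of band-mean contrasts (`contrast_enhancement()`) is slightly
lower (~19.9 dB) because band means weight the near tail more heavily.
Absolute contrast values of real instruments additionally depend on camera
dynamic range and the exact geometry, so the package asserts orderings and
suppression bounds, not absolute $10^3$ / $10^7$ contrasts.

Excess illumination loss of the mask is always evaluated with a Gaussian
beam. At the reference 2.2 mm radius the 8 x 4 mm rhomboid costs 0.84 dB; a
~2.5 dB loss corresponds to a 3.32 mm beam radius (`solve_beam_radius()`
documents this solving radius rather than presenting it as a measurement).

Numerics: the closed forms (circular $[2J_1(v)/v]^2$, rectangular
$\mathrm{sinc}^2\mathrm{sinc}^2$, rhomboid
$[2(\cos q - \cos p)/(p^2 - q^2)]^2$) are the default kernel path at any
rotation and are grid-free. The discrete-transform path samples the aperture
on a 2048-point grid with 2x zero padding and 4x4 sub-pixel edge coverage;
it agrees with the closed forms to better than $10^{-3}$ of the peak over
the first ten lobes and conserves energy to 1%, and it is the route for
arbitrary numerical pupil transmissions.

## Synthetic spectra and the instrument line shape

`synth_spectrum()` renders Rayleigh lines at every order $m \cdot$FSR and a
Stokes/anti-Stokes pair at $m\cdot\mathrm{FSR} \pm \nu_B$, all as
Lorentzians. The spectrometer line shape is approximated as Lorentzian too,
so convolution adds widths: the *observed* Brillouin FWHM is
`linewidth + instrument_width` (default instrument width 0.3 GHz; a Voigt
option is out of scope). Whether published cell linewidths are
instrument-deconvolved is generally unstated, so the package treats tabled
linewidths as observed values throughout — phantoms store observed widths
and the synthesis stage subtracts the instrument width before generating.

One modelling caveat is inherent to a Lorentzian elastic line: its wings at
7 GHz are only $\sim 4\times10^{-4}$ of the peak, so an elastic line
$10^5$ stronger than the Brillouin signal would bury the doublet regardless
of spectrometer contrast. Real elastic lines are narrow (laser-limited) near
the core while their far wings are set by the instrument's crosstalk floor.
`crosstalk_spectrum()` models exactly that: Gaussian elastic cores plus a
flat floor at `elastic_amp / contrast`. With an elastic-to-Brillouin ratio
of $10^5$, fitting is refused (peak prominence below $5\sigma$ of the shot
noise) at a $10^{-3}$ floor and succeeds at $10^{-7}$ — the simulated
counterpart of measuring a turbid sample with the standard versus the
deflected spectrometer.

Camera noise (`noise_model()`) is Poisson shot noise, Gaussian read noise,
and full-well clipping, in that order, bit-reproducible under a seed. Fixed
pattern noise, drift and Raman/fluorescence backgrounds are not modelled.

## Cell phantoms

`synth_phantom()` builds a labelled volume (axis order z, y, x; 0-based
coordinates in tables) emulating a raster-scanned adherent cell at the scan
steps 0.4 um transverse / 1.0 um axial: an ellipsoidal cell in medium, an
offset ellipsoidal nucleus, 1-3 spherical nucleoli, and 0-10 spherical
stress granules (0.5-2 um diameter) placed wholly in cytoplasm. Granule
centres are drawn from cytoplasm voxel centres so placement fails only when
no pocket can hold the sphere, which raises a classed error.

Default ground truth places compartments inside the ranges typical of HeLa
cells at 532 nm — medium 7.40 GHz / 0.80 GHz, cytoplasm 7.80 / 0.95,
nucleus 7.95 / 1.00, nucleolus 8.10 / 1.05, stress granules 7.90 / 0.86
(control) or 8.10 / 1.13 (mutant-protein-bearing, the stiffer and more
viscous variant). The two granule linewidths are the published observed
values; granule shifts are not printed in the source data and were fixed
once inside the stated 7.4-8.1 GHz range.

Partial-volume mixing is modelled as a Gaussian blur **of the parameter
maps** (PSF FWHM 0.3 x 0.3 x 1.1 um, the theoretical confocal resolution
$0.51\lambda/\mathrm{NA}$ lateral and $1.4 n\lambda/\mathrm{NA}^2$ axial),
not as a mixture of spectra. This keeps each voxel's spectrum
single-component and the fit well-posed; it is a simplification, and it
means the phantoms cannot exhibit genuinely two-phase voxels. The blur uses
periodic boundaries, which conserves the volume mean exactly. Consequently,
passing tests demonstrate parameter recovery under single-component
partial-volume attenuation — not two-component spectral unmixing, which real
granule boundaries may require.

## Fitting

`fit_spectrum()` performs a simultaneous Levenberg-Marquardt fit
(minpack.lm) of two Rayleigh and two Brillouin Lorentzians plus a constant
background. Each peak is replicated at multiples of the order spacing
(itself tied to the two Rayleigh centres), so the model family contains the
generative comb exactly and noiseless round trips recover parameters to
$10^{-4}$ GHz across shifts 5-12 GHz and widths 0.3-2 GHz. Initialisation is
deterministic: local maxima of a 5-sample median-filtered profile, Rayleigh
= two tallest, Brillouin = two tallest between them with a guard zone of 8%
of the order spacing around the Rayleigh shoulders.

Conventions and constants:

* $\nu_B$ = mean of the Stokes offset from the lower Rayleigh peak and the
  anti-Stokes offset from the upper one; $\Delta\nu_B$ = mean FWHM of the
  pair. (The averaging convention of published analyses is unstated; this
  symmetric mean is the documented choice.)
* Standard errors from the parameter covariance via the delta method. With
  `weighting = "shot"` residuals are scaled by the inverse shot-noise SD and
  the reported errors track Monte-Carlo scatter to a few percent; unweighted
  errors are conservative for photon-limited data by up to ~30%.
* Detection threshold $k = 5$ (peak prominence over background sigma,
  estimated with a moving average matched to a 0.5 GHz linewidth).
* Saturated samples are excluded from the residuals; for crosstalk-limited
  spectra the Rayleigh centres can be fixed from calibration
  (`fix_rayleigh`) with the elastic cores masked (`exclude_elastic_GHz`).
* Background: constant per spectrum. A sloped background is intentionally
  not fitted; the crosstalk floor of the simulated instrument is flat.

`calibrate_axis()` anchors a linear pixel-to-GHz mapping on the two
Rayleigh peaks (one FSR apart by construction) using the same comb fit in
pixel space, which recovers generated linear mappings to $10^{-6}$ relative.
A quadratic refinement uses the water Stokes/anti-Stokes pair (7.4 GHz in
backscattering) as two further anchors and falls back to linear, with a
warning, if the refined mapping is non-monotonic.

## Maps and statistics

`reconstruct_maps()` places fits on the scan grid and invalidates missing,
non-converged or low-SNR voxels; invalid voxels are excluded from every
statistic. `register_mask()` resamples finer fluorescence-resolution label
masks by nearest neighbour (majority vote optional). No fluorescence
segmentation is implemented — masks come from phantom truth or are
user-supplied.

The **cell is the statistical unit**: `compartment_statistics()` averages
voxels per (cell, compartment) and summarises across cells, and
`compare_groups()` runs a two-sided pooled-variance Student t test on cell
means (Welch behind a flag), so refining the scan grid does not manufacture
significance. Quantiles use the linear-interpolation convention (type 7)
with Tukey 1.5 IQR whiskers. Over 1000 null cohorts of 25 cells per group
the empirical type-I error at $\alpha = 0.05$ stays within [0.03, 0.07].

The fixation ratio $q = \nu_\mathrm{fixed}/\nu_\mathrm{living}$ is the
plain per-compartment ratio; a published "normalisation to cellular volume
variations" is not specified anywhere we could implement it from, so
`q_ratio()` exposes an optional user-supplied volume-correction factor
instead.

## Problem sizes and reproducibility

The test-suite and acceptance runs use deliberately small study sizes chosen
to exercise every code path at full fidelity: phantoms of $2\times8\times8$
to $6\times24\times24$ voxels, 0.02-0.03 GHz frequency sampling, 300-500
Monte-Carlo noise realisations, and 1000-cohort null calibrations. All
generators are pure functions of (parameters, seed); `run_pipeline()` fans a
single global seed out to per-stage child seeds
(`(seed * 7919 + stage) mod (2^31 - 1)`) and writes a manifest with MD5
checksums, so identical (config, seed) pairs give bit-identical artifacts.

## Known limitations

* The optical model is intensity-convolutional; coherent effects between
  the etalon field and the mask diffraction are not represented, and the
  absolute contrast of a real instrument (camera dynamic range, stray
  light) is outside the model.
* The Lorentzian instrument approximation overestimates far-line wings;
  crosstalk-limited scenarios must use `crosstalk_spectrum()`.
* Phantom spectra are single-component per voxel (see above).
* Compartment truth values are plausible constants, not fitted to any
  dataset; conclusions about real cells require real calibrated spectra.
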