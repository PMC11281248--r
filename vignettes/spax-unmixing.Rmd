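---
title: "Blind spectral photoacoustic unmixing for collagen tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blind spectral photoacoustic unmixing for collagen tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaxr)
```

## The problem

Spectral photoacoustic imaging (sPAI) acquires one photoacoustic frame per
optical wavelength — here the NIR-I window, 680–970 nm in 5 nm steps
(59 frames) — co-registered with a B-mode ultrasound image. Each pixel's
signal across wavelengths is, to first order, a non-negative mixture of
chromophore absorption spectra (hemoglobins, water, fat, collagen) weighted
by their local concentrations. Resolving that mixture is what lets sPAI
track collagen III deposition, the hallmark of hepatic fibrosis, without
biopsies.

Two obstacles dominate. First, *spectral coloring*: light fluence decays
with depth at a wavelength-dependent rate, so the same tissue shows
different apparent spectra at different depths. Second, collagen is a weak
NIR absorber next to blood, so naive unmixing buries it. The superpixel
photoacoustic unmixing (SPAX) approach addresses both with fluence
correction before a blind, data-driven factorization, and superpixel
subsampling so that small or weak structures are not swamped by large
homogeneous regions.

## The forward model and its inverse

The simulator and the correction share one analytic model. The
initial-pressure signal at wavelength $\lambda$ and pixel $(z, x)$ is

$$ p(\lambda, z, x) \;=\; \Gamma\,\Phi_0\,
   e^{-\mu_\mathrm{eff}(\lambda)\, d(z, x)}
   \sum_k c_k(z, x)\, \varepsilon_k(\lambda) \;+\;
   \mathcal N(0, \sigma^2), $$

with $\Gamma$ a Grüneisen-like efficiency, $\Phi_0$ the fluence at the
skinline, $d$ the depth in mm below the per-column skinline (no source above
it), $c_k \ge 0$ the concentration maps and $\varepsilon_k$ the chromophore
spectra. The depth-exponential fluence is an analytic stand-in for a full
light-transport simulation; `muEff` is pluggable per wavelength, so a more
elaborate fluence model can be substituted without touching anything else.
The default $\mu_\mathrm{eff}$ is a fixed blend of the library blood and
water spectra rescaled to a 0.15 mm$^{-1}$ peak — a soft-tissue-like value
that makes attenuation spectrally non-flat, so decoloring is a real
correction rather than a scalar gain.

`correctFluence()` divides every sub-skin voxel by
$\Phi(\lambda, z) = \Phi_0 e^{-\mu_\mathrm{eff}\lambda\, d}$, capping the
gain (default 50×) so barely-illuminated deep voxels cannot dominate the
factorization. On noiseless simulated data with the true attenuation this
inverts the forward model to floating-point precision; the package's tests
assert that, and also that *disabling* the correction collapses collagen
recovery on an attenuating phantom — the quantitative case for decoloring.

## The unmixing chain

1. **Skinline** — per column, the first row above a global Otsu threshold of
   the B-mode image, median-smoothed across columns (window 5). Otsu was
   chosen because it is parameter-free and easily testable; depth for
   attenuation is measured from this line, not the transducer face, since
   the skinline is the tissue/background watershed.
2. **Superpixels** — SLIC-style clustering of ROI pixels on
   (wavelength-mean intensity, position) with a compactness weight, seeds on
   a regular grid, connectivity enforced afterwards. Clustering uses the
   wavelength-mean image rather than per-wavelength features so a single
   coherent segmentation applies to all frames. Subsampling to ~200
   superpixels averages noise down by an order of magnitude and rebalances
   the data matrix before factorization.
3. **SVD denoising and rank selection** — the superpixel spectra matrix is
   truncated to the smallest rank reaching 99% of squared-singular-value
   energy; that rank doubles as the default NNMF component count, tying the
   hyperparameter to the data's effective dimensionality.
4. **NNMF** — deterministic NNDSVD initialization, multiplicative
   (Frobenius) updates, then alternating exact-NNLS refinement sweeps until
   the relative reconstruction error stalls; the error trace is recorded and
   is non-increasing by construction. Determinism was a hard requirement
   (reproducible science, testability), hence NNDSVD rather than random
   restarts. Endmember rows are normalized to unit maximum with the scale
   absorbed into the abundances, so abundances are relative concentrations.
5. **Abundance projection** — per-pixel non-negative least squares onto the
   endmember rows, solved exactly by enumerating active supports (vectorized
   across pixels; exact because K is small). Negative voxels produced by
   noise or correction are clipped to zero, with the count logged, since the
   factorization requires non-negativity.
6. **Identification** — every endmember is correlated with every library
   spectrum; collagen comparisons are band-restricted to 880–970 nm, where
   collagen absorbs strongly (peak near 930 nm) and blood/water interference
   is low. Assignment is greedy one-to-one by descending correlation so two
   components can never both claim one chromophore; ties break by name
   order; leftovers are "unknown".

## Quantification

- **Collagen reference correlation**: Pearson correlation, on the
  880–970 nm band, between a measured spectrum and the library collagen III
  reference. The default entry point is the ROI-mean spectrum of the
  corrected stack; the collagen-assigned endmember is the alternative. Both
  are exposed because either reading is defensible; the ROI-mean matches the
  idea of comparing each animal's whole-liver spectrum to the reference.
- **Percent area**: share of ROI pixels whose collagen abundance exceeds a
  threshold. For a single acquisition the default is Otsu's threshold of the
  map itself. For a longitudinal series this default is wrong in an
  instructive way: any per-map adaptive threshold (Otsu, or a fraction of
  the map maximum) re-normalizes each timepoint, and thus *cancels* a
  uniform intensity increase by construction. `longitudinalMetrics()`
  therefore fixes the threshold once — Otsu of the baseline map — and holds
  it across the series. Abundance units are comparable across runs because
  endmember rows are unit-maximum and corrected stacks share physical units.
- **SO2**: HbO2/(HbO2+Hb) per pixel, masked (not zeroed) where total
  hemoglobin vanishes. The hemoglobin abundances come from supervised NNLS
  fitting of the library HbO2/Hb spectra on the corrected stack — the
  standard oximetry route — rather than from the blind factorization: at 99%
  SVD energy the blind rank is typically 2 on liver-like data (collagen +
  one blood component), which cannot resolve an oxygenation ratio. The
  percent-SO2 entering the collagen/SO2 ratio is 100 × mean SO2 over valid
  ROI pixels by default; an SO2-positive-area mode is provided as a
  configuration flag because either reading of "percent SO2" is plausible.
- **B-mode features**: echointensity is the ROI mean gray level;
  heterogeneity is the ROI mean of the local (5×5 window, border-clipped,
  ROI-restricted) *population* gray-level variance. Variance rather than
  standard deviation is the default because reported heterogeneity
  magnitudes in liver studies (hundreds of squared gray levels) are
  consistent with variance units; a global-variance mode exists for
  sensitivity analysis. Population (n) rather than sample (n−1) variance is
  fixed and documented for reproducibility.

## The synthetic phantom

`liverPhantom()` emulates the study conditions: a 128 × 256 px section at
0.1 mm/px (≈100 µm axial resolution), skinline at 8 px, a perfused hepatic
background carrying HbO2/Hb with a smooth SO2 field in roughly [0.3, 0.8],
and collagen III as six randomly placed deposits plus a septum-like diagonal
band with peak concentration 1.5 — chosen so fibrotic collagen signal is
comparable to blood within the 880–970 nm band, which is the regime the
method must handle. Total hemoglobin is locally reduced where collagen
accumulates (hypoperfused fibrotic tissue). Additive Gaussian noise defaults
to 2% of the noiseless peak. B-mode targets default to a mean of 103.4 and
local variance of 135, typical healthy-liver baseline echogenicity and
heterogeneity readings. `simulateProgression()` scales only the collagen map
(defaults 1, 1.5, 2, 3 for a baseline / 5 / 10 / 13-week series); all other
structure is fixed and only the noise realization differs between
timepoints. All randomness flows from one integer seed.

What the phantom does *not* emulate: acoustic reconstruction artifacts,
speckle in the photoacoustic channel, scattering heterogeneity, 3-D
out-of-plane signal, motion, and the biological coupling between fibrosis
and echotexture (B-mode statistics stay at their targets across simulated
timepoints). Passing recovery tests on this phantom therefore shows the
algorithm chain is correct and self-consistent, not that in vivo accuracy
matches; in vivo correlations will sit far below the phantom's near-perfect
values.

## Numerical choices and degenerate inputs

- Spectra live strictly inside 680–970 nm; resampling is linear and refuses
  extrapolation. Band restriction uses a closed interval (both 880 and
  970 nm retained).
- A constant spectrum has no defined Pearson correlation: error, not 0.
- NNLS uses QR on the support design rather than normal equations (avoids
  squaring the condition number); support updates require a relative
  residual improvement of 1e−12, which keeps exact interpolants ahead of
  near-degenerate rivals while staying deterministic.
- Coordinates are 0-based with half-open ranges for rectangle ROIs; row 0 is
  the shallowest row. Skinline columns with no supra-threshold pixel are
  assigned the image depth and counted in a warning.
- Otsu thresholding of a constant map returns the constant, so "above
  threshold" selects nothing.
- The gamma-speckle variance in the B-mode simulator is inflated by
  n/(n−1) for the 5×5 analysis window so the windowed population-variance
  estimator is centred on the target.

## Problem sizes

The shipped tests and the acceptance script run: the full 128 × 256 × 59
recovery phantom with 200 superpixels (single-stack pipeline ≈ 5 s on one
CPU); a 4-animal × 4-timepoint progression at the same size (≈ 40 s); and
64 × 96 phantoms for the faster unit checks. These sizes were chosen to
match the acquisition geometry while keeping a full study re-runnable in
about a minute.

## Known limitations

- The blind rank from 99% SVD energy merges HbO2 and Hb when their spatial
  patterns are spectrally entangled; SO2 therefore uses the supervised
  route. Forcing `K = 3` does not reliably split them on realistic data.
- The analytic fluence model is 1-D in depth per column; lateral fluence
  structure is not modelled (a pluggable `muEff`/correction interface is the
  extension point for Monte Carlo fluence maps).
- The reference library is a constructed, literature-shaped stand-in (the
  package and its tests are self-consistent by design); absolute
  quantification against real chromophore extinction data is out of scope.
- Greedy one-to-one assignment can relabel components when two endmembers
  correlate almost equally with one reference; the full correlation table is
  available from `assignComponents()` for inspection.
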