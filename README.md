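# spaxr

Blind spectral unmixing of multispectral photoacoustic (sPAI) image stacks
for tracking collagen during liver-fibrosis progression, with first-order
B-mode ultrasound features alongside.

## The problem

Liver fibrosis is driven by collagen III deposition. sPAI acquires one
photoacoustic frame per optical wavelength (680–970 nm in 5 nm steps, 59
frames) co-registered with B-mode ultrasound; per pixel, the signal across
wavelengths is a non-negative mixture of chromophore absorption spectra
(HbO2, Hb, water, fat, collagen) distorted with depth by wavelength-dependent
light fluence ("spectral coloring"). `spaxr` implements the superpixel
photoacoustic unmixing (SPAX) chain for resolving that mixture blindly, and
the downstream metrics used to follow fibrosis longitudinally. It is aimed at
photoacoustic/ultrasound imaging researchers who need a reproducible,
testable reference implementation with a ground-truthed synthetic phantom.

## The method

For a pixel-spectra matrix $X \ge 0$ (samples × wavelengths) built from a
fluence-corrected stack, the core factorization is

$$ X \approx A\,S, \qquad A \ge 0,\; S \ge 0, $$

with endmember spectra $S$ (rows unit-maximum) and relative abundances $A$.
The chain: per-column skinline segmentation (Otsu) → division by the modelled
fluence $\Phi(\lambda, z) = \Phi_0\, e^{-\mu_\mathrm{eff}(\lambda) d}$ with
$d$ the depth below the skinline → SLIC-style superpixel subsampling of the
ROI → SVD truncation at 99% energy, whose rank sets the component count K →
NNMF (NNDSVD init, multiplicative updates, exact alternating-NNLS polish) →
full-resolution per-pixel NNLS abundance projection → greedy one-to-one
component identification by Pearson correlation against a reference library,
band-restricted to 880–970 nm for collagen (absorption peak near 930 nm).
Downstream metrics: collagen reference correlation, collagen percent-area,
SO2 = HbO2/(HbO2+Hb) from supervised spectral fitting, the collagen/SO2
ratio, echointensity and heterogeneity of the B-mode companion. A synthetic
liver phantom (`liverPhantom()`, `simulateProgression()`) provides stacks
with known concentration maps, SO2 field and noise level.

## Worked example

```r
library(spaxr)
lib  <- defaultSpectraLibrary()            # collagen3, hbo2, hb, water, fat
spec <- liverPhantom(seed = 42)            # 128 x 256 px, 2% noise
sim  <- simulateStack(spec, lib)
sim$stack
#> MultispectralStack: 59 wavelengths (680-970 nm), 128 x 256 px (0.1 mm/px), ROI 29952 px

pl <- spaxPipeline(sim$stack, lib)         # correct -> superpixels -> SVD -> NNMF
pl$result
#> UnmixingResult: K = 2, relative reconstruction error 1.73e-06
#>   component chromophore correlation
#> 1         1          hb   0.9798085
#> 2         2   collagen3   0.9997714

roi  <- pl$result@roi
i    <- which(componentAssignment(pl$result)$chromophore == "collagen3")
cmap <- abundanceMaps(pl$result)[, , i]
cor(cmap[roi], phantomSpec(sim$truth)@concMaps$collagen3[roi])
#> 0.932
percentArea(cmap, roi)                     # Otsu threshold
#> 17.0
echointensity(bmodeImage(sim$stack), roi); heterogeneity(bmodeImage(sim$stack), roi)
#> 103.4
#> 134.6
```

Read: the blind factorization found two components; the one identified as
collagen correlates 0.9998 with the library collagen III reference on the
880–970 nm band, and its abundance map correlates 0.93 with the true
concentration map. 17% of the ROI is collagen-positive, and the simulated
B-mode sits at its baseline echogenicity/heterogeneity targets (103.4, 135).
For a longitudinal series use `simulateProgression()` +
`longitudinalMetrics()` (which holds the percent-area threshold fixed from
baseline) and `longitudinalTable()`; the file-based pipeline is
`cmdSimulate()` / `cmdUnmix()` / `cmdQuantify()` / `cmdReport()`, or
`Rscript inst/cli/spax.R <subcommand> ...` from a shell.

See `vignettes/spax-unmixing.Rmd` for the model, parameter choices, phantom
design and limitations.

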