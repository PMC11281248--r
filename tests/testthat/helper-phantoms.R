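# Shared fixtures, all built in code at test time.

refLib <- defaultSpectraLibrary()
grid59 <- wavelengthGrid()

# Minimal stack wrapper around a raw (nwl x depth x lateral) array.
stackFromArray <- function(arr, grid = grid59, bmode = NULL, roi = NULL,
                           pixelSizeMm = 0.1) {
  d <- dim(arr)
  if (is.null(bmode)) bmode <- matrix(100, d[2L], d[3L])
  if (is.null(roi)) roi <- matrix(TRUE, d[2L], d[3L])
  new("MultispectralStack", data = arr, wavelengths = grid, bmode = bmode,
      roi = roi, pixelSizeMm = pixelSizeMm)
}

# Uniform single-chromophore phantom column: depth x 1 px, concentration 1.
columnSpec <- function(chrom = "collagen3", depth = 2L, conc = 1,
                       pixelSizeMm = 1, muEff = NULL, noiseSd = 0,
                       seed = 1L) {
  maps <- stats::setNames(list(matrix(conc, depth, 1L)), chrom)
  PhantomSpec(maps, pixelSizeMm = pixelSizeMm, muEff = muEff,
              noiseSd = noiseSd, skinDepthPx = 0L, bmodeLocalVar = 0,
              seed = seed)
}

# Small liver phantom for fast end-to-end tests.
smallPhantom <- function(seed = 1L, noiseFrac = 0.02, ...) {
  liverPhantom(depth = 64L, lateral = 96L, lib = refLib,
               noiseFrac = noiseFrac, nBlobs = 3L, skinDepthPx = 6L,
               seed = seed, ...)
}

# Flat attenuation spectrum on the standard grid.
flatMu <- function(value, grid = grid59) Spectrum(grid, rep(value, length(grid)), "mu_eff")

randomSpectrum <- function(grid = grid59) {
  Spectrum(grid, stats::runif(length(grid)), "random")
}
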