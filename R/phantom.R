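#' Construct a PhantomSpec
#'
#' @param concMaps named list of non-negative `depth x lateral` concentration
#'   matrices; names must be chromophores of the library used at simulation.
#' @param pixelSizeMm pixel pitch in mm (default 0.1, ~100 um axial
#'   resolution).
#' @param gamma Grueneisen-like photoacoustic efficiency (default 1).
#' @param surfaceFluence fluence at the skinline (default 1).
#' @param muEff effective attenuation [Spectrum-class] in 1/mm, or NULL to use
#'   [defaultMuEff()] of the simulation library.
#' @param noiseSd additive Gaussian noise sd, absolute signal units.
#' @param skinDepthPx first tissue row (0-based) per column; scalar recycled.
#' @param bmodeMean,bmodeLocalVar B-mode targets: ROI mean gray level and mean
#'   local gray-level variance. Defaults 103.4 and 135, typical healthy-liver
#'   baseline echogenicity/heterogeneity values.
#' @param seed integer; all phantom randomness derives from it.
#' @return a [PhantomSpec-class].
#' @export
PhantomSpec <- function(concMaps, pixelSizeMm = 0.1, gamma = 1,
                        surfaceFluence = 1, muEff = NULL, noiseSd = 0,
                        skinDepthPx = 0L, bmodeMean = 103.4,
                        bmodeLocalVar = 135, seed = 1L) {
  new("PhantomSpec", concMaps = concMaps, pixelSizeMm = pixelSizeMm,
      gamma = gamma, surfaceFluence = surfaceFluence, muEff = muEff,
      noiseSd = noiseSd, skinDepthPx = as.integer(skinDepthPx),
      bmodeMean = bmodeMean, bmodeLocalVar = bmodeLocalVar,
      seed = as.integer(seed))
}

# Per-column 0-based skinline vector of a spec.
specSkinline <- function(spec) {
  lateral <- ncol(spec@concMaps[[1L]])
  rep_len(spec@skinDepthPx, lateral)
}

# Depth (mm) below the per-column skinline for every pixel; negative above.
depthBelowSkinMm <- function(depth, lateral, skin, pixelSizeMm) {
  z <- matrix(seq_len(depth) - 1L, depth, lateral)
  sweep(z, 2L, skin, "-") * pixelSizeMm
}

#' Simulate a multispectral photoacoustic stack from a phantom
#'
#' Forward optical model: the initial-pressure signal at wavelength lambda and
#' pixel (z, x) is
#' `p = gamma * phi0 * exp(-mu_eff(lambda) * d_mm) * sum_k c_k(z,x) eps_k(lambda)`
#' with `d_mm` the depth below the per-column skinline (signal is zero above
#' the skinline), plus additive Gaussian noise of sd `noiseSd`. The
#' depth-exponential fluence is an analytic stand-in for a full light-transport
#' simulation; `muEff` is pluggable per wavelength. Deterministic given
#' `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param lib a [SpectraLibrary-class] covering every chromophore in
#'   `spec@concMaps`.
#' @param grid wavelength grid of the acquisition (default 680--970 @ 5 nm).
#' @param noiseSeedOffset internal offset so that repeated acquisitions of one
#'   phantom (e.g. longitudinal timepoints) draw fresh noise but share all
#'   structural randomness.
#' @return list with elements `stack` ([MultispectralStack-class]) and
#'   `truth` ([PhantomTruth-class]).
#' @export
simulateStack <- function(spec, lib, grid = wavelengthGrid(),
                          noiseSeedOffset = 0L) {
  stopifnot(is(spec, "PhantomSpec"), is(lib, "SpectraLibrary"))
  validObject(spec)
  chroms <- names(spec@concMaps)
  missing <- setdiff(chroms, chromophoreNames(lib))
  if (length(missing))
    stop("chromophore(s) missing from library: ",
         paste(missing, collapse = ", "))
  d <- dim(spec@concMaps[[1L]])
  depth <- d[1L]; lateral <- d[2L]; nwl <- length(grid)
  E <- t(vapply(chroms, function(k)
    resampleSpectrum(getSpectrum(lib, k), grid)@values, numeric(nwl)))
  C <- vapply(spec@concMaps, as.numeric, numeric(depth * lateral))
  mu <- if (is.null(spec@muEff)) defaultMuEff(lib) else spec@muEff
  mu <- resampleSpectrum(mu, grid)@values
  skin <- specSkinline(spec)
  dmm <- depthBelowSkinMm(depth, lateral, skin, spec@pixelSizeMm)
  atten <- exp(-outer(as.numeric(dmm), mu))        # npix x nwl
  atten[as.numeric(dmm) < 0, ] <- 0                # no source above the skin
  P <- spec@gamma * spec@surfaceFluence * (C %*% E) * atten
  noiseless <- array(t(P), dim = c(nwl, depth, lateral))
  dataArr <- noiseless
  if (spec@noiseSd > 0)
    dataArr <- dataArr + withSeed(
      deriveSeed(spec@seed, 1L + noiseSeedOffset),
      array(stats::rnorm(length(dataArr), 0, spec@noiseSd), dim = dim(dataArr)))
  bmode <- simulateBmode(spec, spec@bmodeMean, spec@bmodeLocalVar,
                         seed = deriveSeed(spec@seed, 2L))
  roi <- tissueRoi(spec)
  thb <- matrix(0, depth, lateral)
  so2 <- matrix(NA_real_, depth, lateral)
  if (all(c("hbo2", "hb") %in% chroms)) {
    thb <- spec@concMaps[["hbo2"]] + spec@concMaps[["hb"]]
    pos <- thb > 0
    so2[pos] <- spec@concMaps[["hbo2"]][pos] / thb[pos]
  }
  stack <- new("MultispectralStack", data = dataArr, wavelengths = grid,
               bmode = bmode, roi = roi, pixelSizeMm = spec@pixelSizeMm)
  truth <- new("PhantomTruth", spec = spec, noiselessStack = noiseless,
               so2True = so2)
  list(stack = stack, truth = truth)
}

# Default ROI of a phantom: all tissue at least 3 rows below the skinline
# (skips the bright skin echo band of the simulated B-mode).
tissueRoi <- function(spec) {
  d <- dim(spec@concMaps[[1L]])
  skin <- specSkinline(spec)
  z <- matrix(seq_len(d[1L]) - 1L, d[1L], d[2L])
  sweep(z, 2L, skin, "-") >= 3L
}

#' Simulate a speckled B-mode ultrasound image
#'
#' Emulates first-order B-mode statistics, not acoustics: tissue pixels below
#' the skinline receive multiplicative gamma-distributed speckle scaled so
#' that the tissue-region mean approximates `targetMean` and the mean local
#' gray-level variance approximates `targetLocalVariance` (within ~5% on
#' images of 128 x 128 px and larger); values are clipped to [0, 255]. A
#' bright 2-row band marks the skin echo so that skinline segmentation has a
#' realistic interface to find; pixels above the skinline are 0. With
#' `targetLocalVariance = 0` the tissue is constant at `targetMean`.
#'
#' The gamma speckle variance is inflated by n/(n-1) for a 5 x 5 analysis
#' window so that the windowed (population-variance) heterogeneity estimator
#' is centred on the target.
#'
#' @param spec a [PhantomSpec-class] (supplies shape and skinline).
#' @param targetMean tissue mean gray level in [0, 255].
#' @param targetLocalVariance target mean local variance (>= 0).
#' @param seed integer RNG seed.
#' @return numeric `depth x lateral` matrix in [0, 255].
#' @export
simulateBmode <- function(spec, targetMean = spec@bmodeMean,
                          targetLocalVariance = spec@bmodeLocalVar,
                          seed = spec@seed) {
  stopifnot(is(spec, "PhantomSpec"))
  if (targetMean < 0 || targetMean > 255)
    stop("targetMean must lie in [0, 255]")
  if (targetLocalVariance < 0) stop("targetLocalVariance must be >= 0")
  d <- dim(spec@concMaps[[1L]])
  depth <- d[1L]; lateral <- d[2L]
  skin <- specSkinline(spec)
  z <- matrix(seq_len(depth) - 1L, depth, lateral)
  below <- sweep(z, 2L, skin, "-")
  img <- matrix(0, depth, lateral)
  tissue <- below >= 0L
  if (targetLocalVariance == 0) {
    img[tissue] <- targetMean
  } else {
    sigma2 <- targetLocalVariance * 25 / 24   # 5x5-window population-variance bias
    shape <- targetMean^2 / sigma2
    spk <- withSeed(seed,
      stats::rgamma(sum(tissue), shape = shape, rate = shape))
    img[tissue] <- targetMean * spk
  }
  clipped <- img < 0 | img > 255
  img <- pmin(pmax(img, 0), 255)
  if (mean(clipped) > 0.01)
    warning(sprintf(
      "B-mode clipping affected %.1f%% of pixels; target mean/variance may be infeasible",
      100 * mean(clipped)))
  skinband <- below >= 0L & below <= 1L
  if (any(skin > 0)) img[skinband] <- 220
  img
}

#' Simulate a longitudinal fibrosis progression series
#'
#' Produces one stack per timepoint by scaling the collagen3 concentration map
#' by `collagenScales[t]`; all other chromophores, geometry and B-mode
#' parameters stay fixed, and only the additive-noise realization differs
#' between timepoints. This emulates a baseline / 5 / 10 / 13-week series in
#' which collagen deposition grows with fibrosis progression.
#'
#' @param spec a [PhantomSpec-class] whose `concMaps` contain `collagen3`.
#' @param collagenScales positive multipliers, one per timepoint.
#' @param lib reference library for the forward model.
#' @param seed integer overriding `spec@seed` for the whole series (optional).
#' @return list of `list(stack=, truth=)`, one per timepoint.
#' @export
simulateProgression <- function(spec, collagenScales,
                                lib = defaultSpectraLibrary(),
                                seed = spec@seed) {
  stopifnot(is(spec, "PhantomSpec"))
  if (length(collagenScales) == 0L) stop("collagenScales must be non-empty")
  if (any(collagenScales <= 0)) stop("collagenScales must be positive")
  if (!"collagen3" %in% names(spec@concMaps))
    stop("spec must contain a collagen3 concentration map")
  lapply(seq_along(collagenScales), function(t) {
    s <- spec
    s@seed <- as.integer(seed)
    s@concMaps[["collagen3"]] <- spec@concMaps[["collagen3"]] *
      collagenScales[t]
    simulateStack(s, lib, noiseSeedOffset = 100L * t)
  })
}

#' Build the default liver fibrosis phantom
#'
#' A 2-D liver section emulating the imaging conditions of a longitudinal
#' fibrosis study: a perfused hepatic background carrying oxy- and
#' deoxyhemoglobin with a smoothly varying oxygen saturation field
#' (SO2 in roughly [0.3, 0.8]), and fibrotic collagen III deposits as a set of
#' randomly placed blobs plus a septum-like diagonal band. Total hemoglobin is
#' locally reduced where collagen accumulates, reflecting the hypoperfusion of
#' fibrotic tissue. Noise is specified as a fraction of the noiseless signal
#' peak (default 2%).
#'
#' @param depth,lateral image shape in pixels (defaults 128 x 256).
#' @param lib reference library used to convert `noiseFrac` into an absolute
#'   noise sd (default [defaultSpectraLibrary()]).
#' @param collagenAmp peak collagen concentration (default 1.5, giving a
#'   collagen signal comparable to blood within the 880--970 nm band).
#' @param noiseFrac additive noise sd as a fraction of the noiseless stack
#'   peak (default 0.02).
#' @param skinDepthPx skinline row (default 8).
#' @param nBlobs number of collagen deposits (default 6).
#' @param seed integer seed for blob placement and noise.
#' @param ... further arguments passed to [PhantomSpec()].
#' @return a [PhantomSpec-class].
#' @export
liverPhantom <- function(depth = 128L, lateral = 256L,
                         lib = defaultSpectraLibrary(), collagenAmp = 1.5,
                         noiseFrac = 0.02, skinDepthPx = 8L, nBlobs = 6L,
                         seed = 1L, ...) {
  z <- matrix(seq_len(depth) - 1L, depth, lateral)
  x <- matrix(rep(seq_len(lateral) - 1L, each = depth), depth, lateral)
  tissue <- z >= skinDepthPx

  # collagen: random blobs + a diagonal septum
  blob <- matrix(0, depth, lateral)
  centers <- withSeed(deriveSeed(seed, 3L), cbind(
    r = stats::runif(nBlobs, skinDepthPx + 10, depth - 10),
    c = stats::runif(nBlobs, 10, lateral - 10),
    s = stats::runif(nBlobs, 6, 14)))
  for (b in seq_len(nBlobs))
    blob <- blob + exp(-((z - centers[b, 1])^2 + (x - centers[b, 2])^2) /
                         (2 * centers[b, 3]^2))
  septum <- exp(-((z - skinDepthPx - 0.35 * (depth - skinDepthPx) -
                     0.2 * x * depth / lateral)^2) / (2 * 4^2))
  collagen <- collagenAmp * pmin(blob + 0.6 * septum, 1.2) * tissue

  # perfused background with spatially varying SO2; hypoperfused where fibrotic
  so2 <- 0.55 + 0.25 * sin(2 * pi * 1.7 * x / lateral) *
    cos(2 * pi * 1.3 * z / depth)
  thb <- (1 - 0.5 * pmin(collagen / collagenAmp, 1)) * tissue
  maps <- list(collagen3 = collagen, hbo2 = thb * so2, hb = thb * (1 - so2))

  spec0 <- PhantomSpec(maps, skinDepthPx = skinDepthPx, noiseSd = 0,
                       seed = seed, ...)
  if (noiseFrac > 0) {
    peak <- max(simulateStack(spec0, lib)$truth@noiselessStack)
    spec0@noiseSd <- noiseFrac * peak
  }
  spec0
}
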