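#' @import methods
NULL

# NIR-I acquisition window shared by the whole package (nm)
.WL_MIN <- 680
.WL_MAX <- 970

#' Spectrum: absorption values on a wavelength grid
#'
#' Pairs a strictly increasing wavelength grid (nm, restricted to the NIR-I
#' acquisition window 680--970 nm) with absorption values in arbitrary units.
#' Used both for reference chromophore spectra and for unmixed component or
#' ROI-mean spectra.
#'
#' @slot wavelengths numeric, strictly increasing, all within [680, 970] nm.
#' @slot values numeric, same length as `wavelengths`, all finite.
#' @slot name single character label (chromophore or component name).
#'
#' @seealso [Spectrum()], [resampleSpectrum()], [bandRestrict()],
#'   [pearsonSimilarity()]
#' @export
setClass("Spectrum",
  representation(wavelengths = "numeric", values = "numeric",
                 name = "character"),
  prototype(name = "spectrum"))

setValidity("Spectrum", function(object) {
  msgs <- character()
  wl <- object@wavelengths
  if (length(wl) == 0L)
    msgs <- c(msgs, "wavelength grid is empty")
  if (anyNA(wl) || any(!is.finite(wl)))
    msgs <- c(msgs, "wavelengths must be finite")
  if (length(wl) > 1L && any(diff(wl) <= 0))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (length(wl) && (min(wl) < .WL_MIN || max(wl) > .WL_MAX))
    msgs <- c(msgs, sprintf("wavelengths must lie within [%d, %d] nm",
                            .WL_MIN, .WL_MAX))
  if (length(object@values) != length(wl))
    msgs <- c(msgs, "values and wavelengths differ in length")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msgs <- c(msgs, "values must be finite")
  if (length(object@name) != 1L)
    msgs <- c(msgs, "name must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' SpectraLibrary: a keyed collection of reference spectra
#'
#' Holds chromophore reference spectra keyed by unique names. The canonical
#' library shipped with the package ([defaultSpectraLibrary()]) contains
#' collagen3, hbo2, hb, water and fat. Spectra may live on different grids;
#' they are resampled to a common grid on access where an operation needs one.
#'
#' @slot spectra named list of [Spectrum-class] objects; names unique and
#'   matching each spectrum's own `name`.
#' @export
setClass("SpectraLibrary", representation(spectra = "list"))

setValidity("SpectraLibrary", function(object) {
  sp <- object@spectra
  if (length(sp) == 0L) return("library must contain at least one spectrum")
  if (!all(vapply(sp, is, logical(1), "Spectrum")))
    return("all entries must be Spectrum objects")
  nm <- names(sp)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    return("spectra must be uniquely named")
  inner <- vapply(sp, function(s) s@name, character(1))
  if (!identical(unname(inner), unname(nm)))
    return("list names must match each spectrum's name slot")
  TRUE
})

#' MultispectralStack: a multispectral photoacoustic stack plus companions
#'
#' One 2-D photoacoustic frame per optical wavelength, co-registered with a
#' B-mode ultrasound image and an ROI mask. Row index = depth (increasing
#' downward), column index = lateral position.
#'
#' @slot data numeric array, `n_wavelengths x depth x lateral`.
#' @slot wavelengths numeric grid (nm) of length `dim(data)[1]`.
#' @slot bmode numeric matrix `depth x lateral`, gray levels in [0, 255].
#' @slot roi logical matrix `depth x lateral`, TRUE inside the region of
#'   interest.
#' @slot pixelSizeMm scalar pixel pitch in mm (isotropic; defaults to 0.1 mm,
#'   matching a ~100 um axial resolution).
#' @export
setClass("MultispectralStack",
  representation(data = "array", wavelengths = "numeric", bmode = "matrix",
                 roi = "matrix", pixelSizeMm = "numeric"),
  prototype(pixelSizeMm = 0.1))

setValidity("MultispectralStack", function(object) {
  d <- dim(object@data)
  msgs <- character()
  if (length(d) != 3L)
    return("data must be a 3-D array (wavelength x depth x lateral)")
  if (length(object@wavelengths) != d[1L])
    msgs <- c(msgs, "wavelengths length must equal dim(data)[1]")
  if (any(diff(object@wavelengths) <= 0))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (!identical(dim(object@bmode), d[2:3]))
    msgs <- c(msgs, "bmode shape must match frame shape")
  if (!identical(dim(object@roi), d[2:3]))
    msgs <- c(msgs, "roi shape must match frame shape")
  if (!is.logical(object@roi))
    msgs <- c(msgs, "roi must be logical")
  if (length(object@pixelSizeMm) != 1L || object@pixelSizeMm <= 0)
    msgs <- c(msgs, "pixelSizeMm must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' PhantomSpec: parameters of the synthetic liver phantom
#'
#' Describes a 2-D tissue section as per-chromophore concentration maps plus
#' the optical forward-model parameters used to simulate a multispectral
#' photoacoustic stack from them: a Grueneisen-like photoacoustic efficiency
#' `gamma`, the surface fluence, a wavelength-dependent effective attenuation
#' `muEff` (1/mm) driving depth-dependent spectral coloring, additive Gaussian
#' noise, and a per-column skinline.
#'
#' @slot concMaps named list of non-negative `depth x lateral` concentration
#'   matrices, one per chromophore (names must exist in the library used for
#'   simulation).
#' @slot pixelSizeMm scalar pixel pitch (mm).
#' @slot gamma scalar photoacoustic generation efficiency (Grueneisen-like).
#' @slot surfaceFluence scalar fluence at the skinline (arbitrary units, > 0).
#' @slot muEff [Spectrum-class] of effective attenuation (1/mm) or NULL to use
#'   [defaultMuEff()] of the library at simulation time.
#' @slot noiseSd additive Gaussian noise standard deviation (absolute signal
#'   units, >= 0).
#' @slot skinDepthPx integer, first tissue row per lateral column (scalar
#'   recycled across columns).
#' @slot bmodeMean target B-mode ROI mean gray level in [0, 255].
#' @slot bmodeLocalVar target B-mode mean local variance (gray-level^2).
#' @slot seed integer seed from which all phantom randomness flows.
#' @export
setClass("PhantomSpec",
  representation(concMaps = "list", pixelSizeMm = "numeric",
                 gamma = "numeric", surfaceFluence = "numeric",
                 muEff = "ANY", noiseSd = "numeric",
                 skinDepthPx = "integer", bmodeMean = "numeric",
                 bmodeLocalVar = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  cm <- object@concMaps
  if (length(cm) == 0L || is.null(names(cm)) || anyDuplicated(names(cm)))
    return("concMaps must be a uniquely named, non-empty list")
  dims <- lapply(cm, dim)
  if (any(vapply(cm, function(m) !is.matrix(m), logical(1))))
    return("each concentration map must be a matrix")
  if (length(unique(dims)) != 1L)
    msgs <- c(msgs, "all concentration maps must share one shape")
  if (any(vapply(cm, function(m) any(m < 0) || anyNA(m), logical(1))))
    msgs <- c(msgs, "concentration maps must be non-negative and finite")
  if (object@pixelSizeMm <= 0) msgs <- c(msgs, "pixelSizeMm must be > 0")
  if (object@surfaceFluence <= 0) msgs <- c(msgs, "surfaceFluence must be > 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (!is.null(object@muEff)) {
    if (!is(object@muEff, "Spectrum"))
      msgs <- c(msgs, "muEff must be a Spectrum or NULL")
    else if (any(object@muEff@values < 0))
      msgs <- c(msgs, "muEff must be non-negative on the full grid")
  }
  depth <- dims[[1L]][1L]
  if (any(object@skinDepthPx < 0) || any(object@skinDepthPx > depth))
    msgs <- c(msgs, "skinDepthPx out of image depth range")
  if (object@bmodeMean < 0 || object@bmodeMean > 255)
    msgs <- c(msgs, "bmodeMean must lie in [0, 255]")
  if (object@bmodeLocalVar < 0) msgs <- c(msgs, "bmodeLocalVar must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' PhantomTruth: ground truth retained from a phantom simulation
#'
#' @slot spec the [PhantomSpec-class] that generated the stack.
#' @slot noiselessStack numeric array, the stack before additive noise.
#' @slot so2True matrix of true per-pixel oxygen saturation
#'   HbO2/(HbO2+Hb) in [0, 1]; NA where total hemoglobin is zero.
#' @export
setClass("PhantomTruth",
  representation(spec = "PhantomSpec", noiselessStack = "array",
                 so2True = "matrix"))

setValidity("PhantomTruth", function(object) {
  v <- object@so2True
  ok <- is.na(v) | (v >= 0 & v <= 1)
  if (!all(ok)) return("true SO2 must lie in [0,1] where defined")
  TRUE
})

#' SuperpixelMap: SLIC-style superpixel labelling of an ROI
#'
#' @slot labels integer matrix, contiguous labels `0..K-1` inside the ROI and
#'   `-1` outside; every ROI pixel labelled, each superpixel spatially
#'   connected.
#' @slot meanSpectra numeric `K x n_wavelengths` matrix of per-superpixel mean
#'   spectra.
#' @slot wavelengths numeric grid of the spectra columns.
#' @export
setClass("SuperpixelMap",
  representation(labels = "matrix", meanSpectra = "matrix",
                 wavelengths = "numeric"))

setValidity("SuperpixelMap", function(object) {
  lab <- object@labels[object@labels >= 0L]
  K <- nrow(object@meanSpectra)
  msgs <- character()
  if (length(lab) == 0L) msgs <- c(msgs, "no labelled pixels")
  else if (!setequal(unique(lab), 0:(K - 1L)))
    msgs <- c(msgs, "labels must be contiguous 0..K-1")
  if (ncol(object@meanSpectra) != length(object@wavelengths))
    msgs <- c(msgs, "meanSpectra columns must match wavelengths")
  if (length(msgs)) msgs else TRUE
})

#' UnmixingResult: endmembers, abundances and component identities
#'
#' Output of the unmixing pipeline: non-negative endmember spectra `S`
#' (rows normalized to unit maximum), per-pixel non-negative abundance maps,
#' the selected rank with the singular-value spectrum that suggested it, and
#' the greedy one-to-one assignment of components to library chromophores with
#' band-restricted Pearson correlations.
#'
#' @slot S numeric matrix `K x n_wavelengths`, non-negative endmember spectra.
#' @slot abundances numeric array `depth x lateral x K`, non-negative, zero
#'   outside the ROI.
#' @slot rank integer, number of components K.
#' @slot singularValues numeric, singular values of the (superpixel) data
#'   matrix used for rank selection.
#' @slot assignment data.frame with columns `component`, `chromophore`,
#'   `correlation` ("unknown"/NA where the library ran out of entries).
#' @slot wavelengths numeric grid of `S` columns.
#' @slot roi logical ROI the abundances refer to.
#' @slot reconError relative Frobenius reconstruction error of the NNMF fit.
#' @slot errorTrace numeric, reconstruction-error trace across NNMF iterations.
#' @export
setClass("UnmixingResult",
  representation(S = "matrix", abundances = "array", rank = "integer",
                 singularValues = "numeric", assignment = "data.frame",
                 wavelengths = "numeric", roi = "matrix",
                 reconError = "numeric", errorTrace = "numeric"))

setValidity("UnmixingResult", function(object) {
  msgs <- character()
  if (any(object@S < 0)) msgs <- c(msgs, "endmember spectra must be >= 0")
  if (any(object@abundances < 0)) msgs <- c(msgs, "abundances must be >= 0")
  if (nrow(object@S) != object@rank)
    msgs <- c(msgs, "nrow(S) must equal rank")
  if (ncol(object@S) != length(object@wavelengths))
    msgs <- c(msgs, "ncol(S) must equal wavelength grid length")
  cc <- object@assignment$correlation
  if (length(cc) && any(!is.na(cc) & (cc < -1 | cc > 1)))
    msgs <- c(msgs, "assigned correlations must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})
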