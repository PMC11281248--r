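#' @rdname accessors
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)

#' @rdname accessors
setMethod("intensities", "Spectrum", function(x) x@values)

#' @rdname accessors
setMethod("wavelengths", "MultispectralStack", function(x) x@wavelengths)

#' @rdname accessors
setMethod("wavelengths", "UnmixingResult", function(x) x@wavelengths)

#' @rdname accessors
setMethod("chromophoreNames", "SpectraLibrary",
          function(x) names(x@spectra))

#' @rdname accessors
setMethod("getSpectrum", "SpectraLibrary", function(x, name) {
  if (!name %in% names(x@spectra))
    stop("no spectrum named '", name, "' in library (have: ",
         paste(names(x@spectra), collapse = ", "), ")")
  x@spectra[[name]]
})

#' @rdname accessors
setMethod("stackArray", "MultispectralStack", function(x) x@data)

#' @rdname accessors
setMethod("bmodeImage", "MultispectralStack", function(x) x@bmode)

#' @rdname accessors
setMethod("roiMask", "MultispectralStack", function(x) x@roi)

#' @rdname accessors
setMethod("pixelSize", "MultispectralStack", function(x) x@pixelSizeMm)

#' @rdname accessors
setMethod("endmemberSpectra", "UnmixingResult", function(x) x@S)

#' @rdname accessors
setMethod("abundanceMaps", "UnmixingResult", function(x) x@abundances)

#' @rdname accessors
setMethod("componentAssignment", "UnmixingResult",
          function(x) x@assignment)

#' @rdname accessors
setMethod("trueSO2", "PhantomTruth", function(x) x@so2True)

#' @rdname accessors
setMethod("phantomSpec", "PhantomTruth", function(x) x@spec)

#' @rdname accessors
setMethod("noiselessStack", "PhantomTruth", function(x) x@noiselessStack)

setMethod("show", "Spectrum", function(object) {
  wl <- object@wavelengths
  cat(sprintf("Spectrum '%s': %d samples, %g-%g nm\n", object@name,
              length(wl), min(wl), max(wl)))
})

setMethod("show", "SpectraLibrary", function(object) {
  cat(sprintf("SpectraLibrary with %d spectra: %s\n",
              length(object@spectra),
              paste(names(object@spectra), collapse = ", ")))
})

setMethod("show", "MultispectralStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "MultispectralStack: %d wavelengths (%g-%g nm), %d x %d px (%.2g mm/px), ROI %d px\n",
    d[1], min(object@wavelengths), max(object@wavelengths), d[2], d[3],
    object@pixelSizeMm, sum(object@roi)))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: chromophores [%s], noiseless stack %s\n",
              paste(names(object@spec@concMaps), collapse = ", "),
              paste(dim(object@noiselessStack), collapse = " x ")))
})

setMethod("show", "UnmixingResult", function(object) {
  cat(sprintf("UnmixingResult: K = %d, relative reconstruction error %.3g\n",
              object@rank, object@reconError))
  print(object@assignment)
})
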