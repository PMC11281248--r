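#' Accessors for spaxr classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `wavelengths()` returns the wavelength grid (nm); `intensities()` the
#' absorption/signal values of a [Spectrum-class]; `chromophoreNames()` the
#' keys of a [SpectraLibrary-class]; `getSpectrum()` one library entry;
#' `stackArray()`, `bmodeImage()`, `roiMask()` and `pixelSize()` the parts of
#' a [MultispectralStack-class]; `endmemberSpectra()`, `abundanceMaps()` and
#' `componentAssignment()` the parts of an [UnmixingResult-class].
#'
#' @param x object to access.
#' @param name chromophore key (for `getSpectrum`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("chromophoreNames",
           function(x) standardGeneric("chromophoreNames"))

#' @rdname accessors
#' @export
setGeneric("getSpectrum", function(x, name) standardGeneric("getSpectrum"))

#' @rdname accessors
#' @export
setGeneric("stackArray", function(x) standardGeneric("stackArray"))

#' @rdname accessors
#' @export
setGeneric("bmodeImage", function(x) standardGeneric("bmodeImage"))

#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("endmemberSpectra",
           function(x) standardGeneric("endmemberSpectra"))

#' @rdname accessors
#' @export
setGeneric("abundanceMaps", function(x) standardGeneric("abundanceMaps"))

#' @rdname accessors
#' @export
setGeneric("componentAssignment",
           function(x) standardGeneric("componentAssignment"))

#' @rdname accessors
#' @export
setGeneric("trueSO2", function(x) standardGeneric("trueSO2"))

#' @rdname accessors
#' @export
setGeneric("phantomSpec", function(x) standardGeneric("phantomSpec"))

#' @rdname accessors
#' @export
setGeneric("noiselessStack", function(x) standardGeneric("noiselessStack"))
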