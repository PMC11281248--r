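#' Construct a uniform wavelength grid
#'
#' Builds the acquisition wavelength grid in nm. The package models NIR-I
#' spectral photoacoustic acquisitions, so grids must stay within
#' 680--970 nm; the default reproduces the standard 680--970 nm sweep in
#' 5 nm steps (59 wavelengths).
#'
#' @param start,stop grid limits in nm (inclusive).
#' @param step uniform step in nm; `stop - start` must be a whole multiple.
#' @return numeric vector of wavelengths.
#' @examples
#' length(wavelengthGrid())  # 59
#' @export
wavelengthGrid <- function(start = 680, stop = 970, step = 5) {
  if (step <= 0) stop("step must be positive")
  if (stop <= start) stop("stop must exceed start")
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-9)
    stop("(stop - start) must be a whole multiple of step")
  wl <- start + step * seq.int(0L, round(n))
  if (min(wl) < 680 || max(wl) > 970)
    stop("wavelength grid must lie within [680, 970] nm")
  wl
}

#' Construct a Spectrum
#'
#' @param wavelengths numeric grid in nm, strictly increasing, within
#'   [680, 970].
#' @param values numeric absorption/signal values, same length.
#' @param name label for the spectrum.
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum(wavelengthGrid(), rep(1, 59), "flat")
#' @export
Spectrum <- function(wavelengths, values, name = "spectrum") {
  new("Spectrum", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values), name = as.character(name))
}

#' Construct a SpectraLibrary
#'
#' @param ... [Spectrum-class] objects (or a single list of them); keyed by
#'   their `name` slots, which must be unique.
#' @return a [SpectraLibrary-class].
#' @export
SpectraLibrary <- function(...) {
  sp <- list(...)
  if (length(sp) == 1L && is.list(sp[[1L]]) && !is(sp[[1L]], "Spectrum"))
    sp <- sp[[1L]]
  names(sp) <- vapply(sp, function(s) s@name, character(1))
  new("SpectraLibrary", spectra = sp)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; extrapolation is refused because absorption outside
#' the measured band is unknown.
#'
#' @param s a [Spectrum-class].
#' @param target numeric target grid (nm), within the range of `s`.
#' @return a [Spectrum-class] on `target`.
#' @export
resampleSpectrum <- function(s, target) {
  stopifnot(is(s, "Spectrum"))
  target <- as.numeric(target)
  wl <- s@wavelengths
  out <- target[target < min(wl) | target > max(wl)]
  if (length(out))
    stop(sprintf(
      "cannot extrapolate: wavelength %g nm outside spectrum range [%g, %g]",
      out[1L], min(wl), max(wl)))
  v <- stats::approx(wl, s@values, xout = target, method = "linear")$y
  Spectrum(target, v, s@name)
}

#' Restrict a spectrum to a wavelength band
#'
#' Keeps samples with `lo <= lambda <= hi` (closed interval; both band edges
#' are retained). The 880--970 nm band is the collagen detection window:
#' collagen absorbs strongly there (peak near 930 nm) while blood and water
#' absorb comparatively little.
#'
#' @param s a [Spectrum-class].
#' @param lo,hi band edges in nm, `lo <= hi`, inside the grid range.
#' @return the band-restricted [Spectrum-class].
#' @export
bandRestrict <- function(s, lo, hi) {
  stopifnot(is(s, "Spectrum"))
  if (lo > hi) stop("lo must not exceed hi")
  wl <- s@wavelengths
  if (lo < min(wl) || hi > max(wl))
    stop(sprintf("band [%g, %g] outside grid range [%g, %g]",
                 lo, hi, min(wl), max(wl)))
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) stop("band restriction produced an empty spectrum")
  Spectrum(wl[keep], s@values[keep], s@name)
}

#' Pearson similarity of two spectra
#'
#' Standard Pearson correlation of the value vectors; spectra must share a
#' grid (resample first). A constant spectrum has no defined correlation and
#' raises an error rather than returning 0.
#'
#' @param a,b [Spectrum-class] objects on a common grid.
#' @return correlation in [-1, 1].
#' @export
pearsonSimilarity <- function(a, b) {
  stopifnot(is(a, "Spectrum"), is(b, "Spectrum"))
  if (length(a@wavelengths) != length(b@wavelengths) ||
      any(abs(a@wavelengths - b@wavelengths) > 1e-9))
    stop("spectra are on different grids; resample onto a common grid first")
  if (stats::sd(a@values) == 0 || stats::sd(b@values) == 0)
    stop("zero-variance spectrum: correlation undefined for a constant spectrum")
  v <- stats::cor(a@values, b@values)
  max(-1, min(1, v))
}

#' Read / write a chromophore spectra library as CSV
#'
#' Format: header `wavelength_nm,<name1>,<name2>,...`, one row per wavelength,
#' strictly increasing wavelengths, UTF-8, plain floating point.
#'
#' @param path CSV file path.
#' @return `loadSpectraCsv` returns a [SpectraLibrary-class];
#'   `saveSpectraCsv` invisibly returns `path`.
#' @export
loadSpectraCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df))
    stop("CSV must contain a 'wavelength_nm' column")
  if (ncol(df) < 2L) stop("CSV contains no chromophore columns")
  wl <- df$wavelength_nm
  if (anyNA(wl) || any(diff(wl) <= 0))
    stop("wavelength_nm column must be strictly increasing (no duplicates)")
  nm <- setdiff(names(df), "wavelength_nm")
  sp <- lapply(nm, function(k) Spectrum(wl, df[[k]], k))
  SpectraLibrary(sp)
}

#' @rdname loadSpectraCsv
#' @param lib a [SpectraLibrary-class]; all spectra are resampled to the grid
#'   of the first entry before writing.
#' @export
saveSpectraCsv <- function(lib, path) {
  stopifnot(is(lib, "SpectraLibrary"))
  grid <- lib@spectra[[1L]]@wavelengths
  cols <- lapply(lib@spectra, function(s) {
    if (identical(s@wavelengths, grid)) s@values
    else resampleSpectrum(s, grid)@values
  })
  df <- data.frame(wavelength_nm = grid, cols, check.names = FALSE)
  names(df) <- c("wavelength_nm", names(lib@spectra))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged chromophore reference library
#'
#' Loads the synthetic literature-shaped reference spectra shipped with the
#' package on the 680--970 nm @ 5 nm grid: collagen3 (broad NIR peak at
#' 930 nm), hbo2 and hb (oxy-/deoxyhemoglobin with the deoxy peak near 758 nm
#' and an isosbestic-like crossing near 800 nm), water (rising toward its
#' ~975 nm band) and fat (narrow lipid band near 925 nm). These are
#' constructed, smoothly parameterized stand-ins with the qualitative shapes
#' of the literature spectra, not digitized measurements; the simulator and
#' the unmixer share them, so recovery experiments are self-consistent.
#'
#' @return a [SpectraLibrary-class] with entries collagen3, hbo2, hb, water,
#'   fat.
#' @export
defaultSpectraLibrary <- function() {
  path <- system.file("extdata", "chromophore_library_synthetic.csv",
                      package = "spaxr", mustWork = TRUE)
  loadSpectraCsv(path)
}

#' Default effective attenuation spectrum
#'
#' A background effective attenuation mu_eff(lambda) in 1/mm, derived from the
#' library as a fixed blend of blood and water absorption so that depth
#' fluence attenuation is spectrally non-flat (making decoloring a real
#' correction, not a scalar gain). The blend is
#' 0.25 hbo2 + 0.25 hb + 0.5 water, rescaled to `peak` 1/mm at its maximum.
#'
#' @param lib a [SpectraLibrary-class] containing hbo2, hb and water.
#' @param peak maximum attenuation in 1/mm (default 0.15, a soft-tissue-like
#'   NIR value giving ~1/e fluence loss over ~7 mm).
#' @return a [Spectrum-class] named "mu_eff" on the library grid.
#' @export
defaultMuEff <- function(lib, peak = 0.15) {
  stopifnot(is(lib, "SpectraLibrary"))
  grid <- lib@spectra[[1L]]@wavelengths
  get_ <- function(nm) {
    s <- getSpectrum(lib, nm)
    resampleSpectrum(s, grid)@values / max(s@values)
  }
  mix <- 0.25 * get_("hbo2") + 0.25 * get_("hb") + 0.5 * get_("water")
  Spectrum(grid, peak * mix / max(mix), "mu_eff")
}
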