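#' Segment the skinline of a B-mode image
#'
#' The skinline is the tissue/background watershed: per lateral column, the
#' first depth row whose intensity exceeds a global Otsu threshold of the
#' image, median-smoothed across columns. Columns with no supra-threshold
#' pixel are assigned the image depth (no tissue) and counted in a warning.
#'
#' @param bmode numeric `depth x lateral` image.
#' @param smoothPx odd median-filter window across columns (default 5;
#'   1 disables smoothing).
#' @return integer vector of 0-based first-tissue row indices, one per
#'   column (`depth` where no tissue was found).
#' @export
segmentSkinline <- function(bmode, smoothPx = 5L) {
  if (!is.matrix(bmode) || !length(bmode)) stop("bmode must be a non-empty matrix")
  if (smoothPx < 1L || smoothPx %% 2L == 0L)
    stop("smoothPx must be an odd positive integer")
  depth <- nrow(bmode)
  if (diff(range(bmode)) == 0) {
    warning("constant image: no skinline found in any column")
    return(rep(as.integer(depth), ncol(bmode)))
  }
  thr <- otsuThreshold(as.numeric(bmode))
  first <- apply(bmode > thr, 2L, function(col) {
    i <- which(col)
    if (length(i)) i[1L] - 1L else depth
  })
  nmiss <- sum(first == depth)
  if (nmiss > 0)
    warning(sprintf("%d column(s) without supra-threshold pixels; assigned image depth",
                    nmiss))
  k <- min(smoothPx, length(first))
  if (k %% 2L == 0L) k <- k - 1L
  if (k >= 3L)
    first <- as.integer(round(stats::runmed(first, k = k, endrule = "median")))
  as.integer(first)
}

#' Correct a stack for depth-dependent light fluence (spectral decoloring)
#'
#' Divides every voxel by the modelled fluence
#' `Phi(lambda, z) = surfaceFluence * exp(-muEff(lambda) * d_mm)`, where
#' `d_mm` is the depth below the per-column skinline. Wavelength-dependent
#' attenuation distorts ("colors") spectra with depth; dividing it out
#' restores the initial-pressure spectral shape so that unmixing compares
#' like with like across depths. Voxels above the skinline are untouched and
#' the total gain `1/Phi` is capped at `maxGain` so that deep, barely
#' illuminated voxels cannot dominate the unmixing.
#'
#' @param stack a [MultispectralStack-class].
#' @param skin integer skinline (0-based row per column), e.g. from
#'   [segmentSkinline()]; a scalar is recycled.
#' @param muEff effective attenuation [Spectrum-class] (1/mm) resampled to
#'   the stack grid.
#' @param surfaceFluence positive scalar fluence at the skinline.
#' @param maxGain cap on the correction gain (default 50).
#' @return the corrected [MultispectralStack-class].
#' @export
correctFluence <- function(stack, skin, muEff, surfaceFluence = 1,
                           maxGain = 50) {
  stopifnot(is(stack, "MultispectralStack"), is(muEff, "Spectrum"))
  if (surfaceFluence <= 0) stop("surfaceFluence must be positive")
  if (maxGain <= 0) stop("maxGain must be positive")
  d <- dim(stack@data)
  nwl <- d[1L]; depth <- d[2L]; lateral <- d[3L]
  skin <- rep_len(as.integer(skin), lateral)
  mu <- resampleSpectrum(muEff, stack@wavelengths)@values
  dmm <- depthBelowSkinMm(depth, lateral, skin, stack@pixelSizeMm)
  gain <- exp(outer(as.numeric(dmm), mu)) / surfaceFluence  # npix x nwl
  gain[as.numeric(dmm) < 0, ] <- 1                          # above skin: untouched
  ncap <- sum(gain > maxGain)
  if (ncap > 0) {
    gain <- pmin(gain, maxGain)
    message(sprintf("fluence correction gain capped at %gx for %d voxel-wavelengths",
                    maxGain, ncap))
  }
  P <- t(matrix(stack@data, nwl, depth * lateral)) * gain
  out <- stack
  out@data <- array(t(P), dim = d)
  out
}

#' Rectangular ROI mask
#'
#' Builds a boolean mask for the half-open rectangle `[r0, r1) x [c0, c1)` in
#' 0-based coordinates, row 0 being the shallowest row. Note the convention:
#' indices are 0-based and the upper bounds are exclusive, so
#' `rectRoi(0, 0, 2, 2, c(4, 4))` selects exactly 4 pixels.
#'
#' @param r0,c0 inclusive 0-based top-left corner.
#' @param r1,c1 exclusive bottom-right bounds.
#' @param shape integer `c(depth, lateral)` of the image.
#' @return logical `depth x lateral` matrix.
#' @export
rectRoi <- function(r0, c0, r1, c1, shape) {
  if (r0 < 0 || c0 < 0 || r1 > shape[1L] || c1 > shape[2L])
    stop("rectangle exceeds image bounds")
  if (r1 <= r0 || c1 <= c0) stop("rectangle is empty")
  m <- matrix(FALSE, shape[1L], shape[2L])
  m[(r0 + 1L):r1, (c0 + 1L):c1] <- TRUE
  m
}

#' Read / write an ROI mask as an 8-bit PNG
#'
#' Masks are stored as 0/255 grayscale PNGs; any value above half scale reads
#' back as TRUE.
#'
#' @param path PNG file path.
#' @param shape optional expected `c(depth, lateral)` to validate against.
#' @return `loadRoiMask` returns a logical matrix; `saveRoiMask` invisibly
#'   returns `path`.
#' @export
loadRoiMask <- function(path, shape = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- img > 0.5
  if (!is.null(shape) && !identical(dim(mask), as.integer(shape)))
    stop("mask shape does not match expected frame shape")
  if (!any(mask)) stop("ROI mask is empty")
  mask
}

#' @rdname loadRoiMask
#' @param mask logical matrix to write.
#' @export
saveRoiMask <- function(mask, path) {
  checkRoi(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}
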