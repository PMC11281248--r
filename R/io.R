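# Stack file conventions: multi-frame 32-bit TIFF (frame i = wavelength i,
# ascending), values scaled into [0, 1] with the scale recorded in a sidecar
# JSON ({"wavelengths_nm": [...], "scale": s, "pixel_size_mm": p}); B-mode and
# ROI as 8-bit grayscale PNG.

#' Write / read a MultispectralStack to files
#'
#' `writeStack` writes `<prefix>.tif` (one 32-bit float frame per wavelength,
#' ascending), `<prefix>_meta.json` (wavelengths, intensity scale, pixel
#' size), `<prefix>_bmode.png` and `<prefix>_roi.png`. `readStack` reverses
#' it. Because float TIFF storage is defined on [0, 1] and noisy frames can
#' contain small negative values, frames are stored as
#' `(x / scale + 1) / 2` with `scale = max(abs(data))` recorded in the
#' sidecar; values round-trip to 32-bit float precision.
#'
#' @param stack a [MultispectralStack-class].
#' @param prefix file path prefix (no extension).
#' @return `writeStack` invisibly returns `prefix`; `readStack` returns the
#'   [MultispectralStack-class].
#' @export
writeStack <- function(stack, prefix) {
  stopifnot(is(stack, "MultispectralStack"))
  d <- dim(stack@data)
  scale <- max(abs(stack@data), 1e-300)
  frames <- lapply(seq_len(d[1L]), function(i)
    (stack@data[i, , ] / scale + 1) / 2)
  tiff::writeTIFF(frames, paste0(prefix, ".tif"), bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(wavelengths_nm = stack@wavelengths, scale = scale,
         pixel_size_mm = stack@pixelSizeMm, signed = TRUE),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  png::writePNG(stack@bmode / 255, paste0(prefix, "_bmode.png"))
  saveRoiMask(stack@roi, paste0(prefix, "_roi.png"))
  invisible(prefix)
}

#' @rdname writeStack
#' @export
readStack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  frames <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  nwl <- length(frames)
  if (nwl != length(meta$wavelengths_nm))
    stop("TIFF frame count does not match sidecar wavelength count")
  d2 <- dim(frames[[1L]])
  arr <- array(0, dim = c(nwl, d2[1L], d2[2L]))
  signed <- isTRUE(meta$signed)
  for (i in seq_len(nwl))
    arr[i, , ] <- if (signed) (2 * frames[[i]] - 1) * meta$scale
                  else frames[[i]] * meta$scale
  bmode <- png::readPNG(paste0(prefix, "_bmode.png"))
  if (length(dim(bmode)) == 3L) bmode <- bmode[, , 1L]
  roi <- loadRoiMask(paste0(prefix, "_roi.png"))
  new("MultispectralStack", data = arr,
      wavelengths = as.numeric(meta$wavelengths_nm), bmode = bmode * 255,
      roi = roi, pixelSizeMm = as.numeric(meta$pixel_size_mm))
}

# Write a plain numeric matrix (e.g. a truth concentration map) as a scaled
# float TIFF with its scale in a sidecar JSON.
writeMapTiff <- function(map, prefix) {
  scale <- max(abs(map), 1e-300)
  tiff::writeTIFF(pmin(pmax(map / scale, 0), 1), paste0(prefix, ".tif"),
                  bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(scale = scale), paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

readMapTiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  tiff::readTIFF(paste0(prefix, ".tif")) * meta$scale
}
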