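#' ROI-mean spectrum of a stack
#'
#' Per-wavelength arithmetic mean of the (corrected) stack over the ROI
#' pixels; the whole-liver spectrum an animal contributes to the reference
#' correlation.
#'
#' @param stack a [MultispectralStack-class].
#' @param roi logical ROI mask (defaults to the stack ROI).
#' @return a [Spectrum-class] named "roi_mean".
#' @export
roiMeanSpectrum <- function(stack, roi = roiMask(stack)) {
  stopifnot(is(stack, "MultispectralStack"))
  checkRoi(roi)
  X <- pixelSpectra(stack)[which(roi), , drop = FALSE]
  Spectrum(stack@wavelengths, colMeans(X), "roi_mean")
}

#' Correlation of a measured spectrum with the collagen III reference
#'
#' Band-restricted (default 880--970 nm) Pearson correlation between a
#' spectrum derived from the data and the library collagen3 reference. The
#' default entry point is the ROI-mean spectrum of the corrected stack; the
#' alternative is the collagen-assigned endmember of an
#' [UnmixingResult-class].
#'
#' @param x a [MultispectralStack-class] (mode "roi_mean"), an
#'   [UnmixingResult-class] (mode "endmember"), or a [Spectrum-class].
#' @param lib a [SpectraLibrary-class] containing collagen3.
#' @param band numeric `c(lo, hi)` in nm.
#' @param roi ROI mask when `x` is a stack.
#' @return Pearson correlation in [-1, 1].
#' @export
collagenCorrelation <- function(x, lib = defaultSpectraLibrary(),
                                band = c(880, 970), roi = NULL) {
  s <- if (is(x, "Spectrum")) {
    x
  } else if (is(x, "MultispectralStack")) {
    roiMeanSpectrum(x, if (is.null(roi)) roiMask(x) else roi)
  } else if (is(x, "UnmixingResult")) {
    a <- x@assignment
    i <- which(a$chromophore == "collagen3")
    if (!length(i)) stop("no component was assigned to collagen3")
    Spectrum(x@wavelengths, x@S[i[1L], ], "collagen_endmember")
  } else stop("x must be a Spectrum, MultispectralStack or UnmixingResult")
  ref <- resampleSpectrum(getSpectrum(lib, "collagen3"), s@wavelengths)
  pearsonSimilarity(bandRestrict(s, band[1L], band[2L]),
                    bandRestrict(ref, band[1L], band[2L]))
}

#' Percent area of an abundance map above threshold
#'
#' `100 * #(ROI pixels with abundance > tau) / #(ROI pixels)`. The threshold
#' is either Otsu's (default, data-driven) or a fixed fraction of the map
#' maximum.
#'
#' For longitudinal series, note that both `"otsu"` and `"fixed_frac"` adapt
#' to each map's own scale, which by design cancels a uniform intensity
#' increase; `"fixed_value"` with a threshold derived once (e.g. from the
#' baseline map) is the comparable-across-timepoints mode used by
#' [longitudinalMetrics()].
#'
#' @param map numeric abundance matrix.
#' @param roi logical ROI mask.
#' @param thresholdMode `"otsu"`, `"fixed_frac"` or `"fixed_value"`.
#' @param frac threshold fraction of the ROI map maximum for `"fixed_frac"`
#'   (default 0.5).
#' @param tau absolute threshold for `"fixed_value"`.
#' @return percent in [0, 100].
#' @export
percentArea <- function(map, roi,
                        thresholdMode = c("otsu", "fixed_frac",
                                          "fixed_value"),
                        frac = 0.5, tau = NULL) {
  thresholdMode <- match.arg(thresholdMode)
  checkRoi(roi)
  v <- map[roi]
  tau <- switch(thresholdMode,
    otsu = otsuThreshold(v),
    fixed_frac = frac * max(v),
    fixed_value = {
      if (is.null(tau)) stop("fixed_value mode needs a tau")
      tau
    })
  100 * mean(v > tau)
}

#' Per-pixel oxygen saturation from hemoglobin abundances
#'
#' `SO2 = HbO2 / (HbO2 + Hb)` wherever total hemoglobin exceeds `eps`;
#' pixels without hemoglobin are NA (masked out of summaries, never coerced
#' to 0).
#'
#' @param Ahbo2,Ahb non-negative abundance matrices of equal shape.
#' @param eps denominator floor (default 1e-9).
#' @return matrix of SO2 in [0, 1] with NA where undefined.
#' @export
computeSO2 <- function(Ahbo2, Ahb, eps = 1e-9) {
  if (!identical(dim(Ahbo2), dim(Ahb)))
    stop("abundance maps must share one shape")
  if (any(Ahbo2 < 0) || any(Ahb < 0))
    stop("abundance maps must be non-negative")
  tot <- Ahbo2 + Ahb
  out <- matrix(NA_real_, nrow(Ahbo2), ncol(Ahbo2))
  ok <- tot > eps
  out[ok] <- Ahbo2[ok] / tot[ok]
  out
}

#' Summarize an SO2 map over an ROI as a percentage
#'
#' Mode `"mean"` (default): 100 x mean SO2 over valid ROI pixels. Mode
#' `"area"`: percent of ROI pixels whose SO2 is valid and above
#' `areaThreshold`.
#'
#' @param so2 SO2 matrix from [computeSO2()] (NA = undefined).
#' @param roi logical ROI mask.
#' @param mode `"mean"` or `"area"`.
#' @param areaThreshold SO2 cutoff for `"area"` mode (default 0.5).
#' @return percent in [0, 100].
#' @export
so2Percent <- function(so2, roi, mode = c("mean", "area"),
                       areaThreshold = 0.5) {
  mode <- match.arg(mode)
  checkRoi(roi)
  v <- so2[roi]
  if (all(is.na(v))) stop("no valid SO2 pixels inside the ROI")
  switch(mode,
    mean = 100 * mean(v, na.rm = TRUE),
    area = 100 * mean(!is.na(v) & v > areaThreshold))
}

#' Collagen burden normalized by tissue oxygen saturation
#'
#' Ratio of the collagen percent-area to the percent SO2; normalizing the
#' collagen signal by oxygenation removes perfusion fluctuations from the
#' longitudinal trend.
#'
#' @param collagenPercentArea percent in [0, 100].
#' @param so2Percent percent in (0, 100].
#' @return non-negative ratio.
#' @export
collagenSO2Ratio <- function(collagenPercentArea, so2Percent) {
  if (so2Percent <= 0) stop("so2Percent must be positive")
  collagenPercentArea / so2Percent
}

#' Run the full unmixing pipeline on one stack
#'
#' Chains the stages end to end: skinline segmentation on the B-mode
#' companion, fluence correction (unless disabled), superpixel subsampling,
#' SVD denoising with automatic rank selection, NNMF, full-resolution
#' NNLS abundance projection and component identification.
#'
#' @param stack a [MultispectralStack-class].
#' @param lib reference [SpectraLibrary-class].
#' @param roi ROI mask (defaults to the stack ROI).
#' @param muEff attenuation model for the correction (default
#'   [defaultMuEff()] of `lib`).
#' @param surfaceFluence scalar fluence at the skinline.
#' @param fluenceCorrection logical; set FALSE to skip spectral decoloring.
#' @param nSuperpixels superpixel count (default 200).
#' @param energyFrac SVD energy fraction for rank selection (default 0.99).
#' @param K component count; NULL (default) uses the SVD-selected rank.
#' @param band collagen matching band in nm.
#' @param maxGain fluence-correction gain cap.
#' @param seed RNG seed (reserved for stochastic options; the default path is
#'   deterministic).
#' @return list with `result` (an [UnmixingResult-class]), `corrected` (the
#'   decolored [MultispectralStack-class]) and `skinline`.
#' @export
spaxPipeline <- function(stack, lib = defaultSpectraLibrary(),
                         roi = roiMask(stack), muEff = defaultMuEff(lib),
                         surfaceFluence = 1, fluenceCorrection = TRUE,
                         nSuperpixels = 200L, energyFrac = 0.99, K = NULL,
                         band = c(880, 970), maxGain = 50, seed = 1L) {
  stopifnot(is(stack, "MultispectralStack"))
  checkRoi(roi)
  skin <- segmentSkinline(stack@bmode)
  corrected <- if (fluenceCorrection)
    correctFluence(stack, skin, muEff, surfaceFluence, maxGain)
  else stack
  sp <- superpixelSubsample(corrected, roi,
                            min(nSuperpixels, sum(roi)))
  dn <- svdDenoise(sp@meanSpectra, energyFrac)
  if (is.null(K)) K <- dn$rank
  K <- max(1L, min(K, min(dim(sp@meanSpectra))))
  fit <- nnmfUnmix(dn$X, K, seed = seed)
  A <- projectAbundances(corrected, roi, fit$S)
  assign <- assignComponents(fit$S, lib, grid = corrected@wavelengths,
                             band = band)
  res <- new("UnmixingResult", S = fit$S, abundances = A,
             rank = as.integer(K), singularValues = dn$singularValues,
             assignment = assign, wavelengths = corrected@wavelengths,
             roi = roi, reconError = fit$reconError,
             errorTrace = fit$errorTrace)
  list(result = res, corrected = corrected, skinline = skin)
}

# Pull one chromophore's abundance map out of an UnmixingResult (zeros if the
# chromophore was not assigned to any component).
chromophoreMap <- function(result, chromophore) {
  a <- result@assignment
  i <- which(a$chromophore == chromophore)
  d <- dim(result@abundances)
  if (!length(i)) return(matrix(0, d[1L], d[2L]))
  result@abundances[, , i[1L]]
}

#' Compute all per-timepoint metrics for one stack
#'
#' Runs [spaxPipeline()] and summarizes one acquisition into the longitudinal
#' metric set: collagen reference correlation (ROI-mean spectrum by default),
#' collagen percent-area of the collagen-assigned abundance map, percent SO2,
#' the collagen/SO2 ratio, and the first-order B-mode features.
#'
#' SO2 comes from supervised spectral fitting: abundances of the library hbo2
#' and hb spectra obtained by NNLS on the corrected stack — the standard
#' oximetry route, independent of the blind factorization.
#'
#' @param stack a [MultispectralStack-class].
#' @param lib reference library.
#' @param label timepoint label (e.g. "baseline", "wk05").
#' @param animal animal/replicate identifier.
#' @param correlationMode `"roi_mean"` (default) or `"endmember"`.
#' @param so2Mode `"mean"` or `"area"` (see [so2Percent()]).
#' @param thresholdMode percent-area thresholding (see [percentArea()]).
#' @param collagenTau absolute percent-area threshold; overrides
#'   `thresholdMode` with `"fixed_value"` when given (longitudinal use).
#' @param pipeline optional precomputed result of [spaxPipeline()] for this
#'   stack, to avoid recomputation.
#' @param ... further arguments to [spaxPipeline()].
#' @return one-row data.frame of metrics.
#' @export
timepointMetrics <- function(stack, lib = defaultSpectraLibrary(),
                             label = "baseline", animal = "a1",
                             correlationMode = c("roi_mean", "endmember"),
                             so2Mode = c("mean", "area"),
                             thresholdMode = c("otsu", "fixed_frac"),
                             collagenTau = NULL, pipeline = NULL, ...) {
  correlationMode <- match.arg(correlationMode)
  so2Mode <- match.arg(so2Mode)
  thresholdMode <- match.arg(thresholdMode)
  pl <- if (is.null(pipeline)) spaxPipeline(stack, lib, ...) else pipeline
  roi <- pl$result@roi
  corr <- if (correlationMode == "roi_mean")
    collagenCorrelation(pl$corrected, lib, roi = roi)
  else collagenCorrelation(pl$result, lib)
  cmap <- chromophoreMap(pl$result, "collagen3")
  parea <- if (is.null(collagenTau))
    percentArea(cmap, roi, thresholdMode)
  else percentArea(cmap, roi, "fixed_value", tau = collagenTau)
  hbS <- rbind(resampleSpectrum(getSpectrum(lib, "hbo2"),
                                pl$corrected@wavelengths)@values,
               resampleSpectrum(getSpectrum(lib, "hb"),
                                pl$corrected@wavelengths)@values)
  Ahb <- projectAbundances(pl$corrected, roi, hbS)
  so2 <- computeSO2(Ahb[, , 1L], Ahb[, , 2L])
  so2p <- so2Percent(so2, roi, so2Mode)
  data.frame(
    animal = animal, label = label,
    collagen_ref_correlation = corr,
    collagen_percent_area = parea,
    so2_percent = so2p,
    collagen_to_so2_ratio = collagenSO2Ratio(parea, so2p),
    echogenicity = echointensity(stack@bmode, roi),
    heterogeneity = heterogeneity(stack@bmode, roi),
    stringsAsFactors = FALSE)
}

#' Metrics for one animal's longitudinal series
#'
#' Runs the pipeline on each timepoint stack of one animal and computes
#' [timepointMetrics()] rows with a percent-area threshold held fixed across
#' the series: Otsu's threshold of the first (baseline) timepoint's collagen
#' abundance map. Abundance units are comparable across timepoints (endmember
#' rows are unit-maximum and the corrected stacks share physical units), and
#' a series-fixed threshold is what makes percent-area trends reflect signal
#' growth rather than re-adapting to each map — an adaptive per-map threshold
#' would, by construction, cancel a uniform intensity increase.
#'
#' @param stacks list of [MultispectralStack-class], one per timepoint, in
#'   temporal order.
#' @param labels character timepoint labels (same length).
#' @param animal animal identifier.
#' @param lib reference library.
#' @param ... further arguments to [timepointMetrics()] / [spaxPipeline()].
#' @return list with `metrics` (data.frame, one row per timepoint),
#'   `pipelines` (per-timepoint [spaxPipeline()] outputs) and
#'   `collagenTau` (the series threshold).
#' @export
longitudinalMetrics <- function(stacks, labels, animal = "a1",
                                lib = defaultSpectraLibrary(), ...) {
  stopifnot(length(stacks) == length(labels), length(stacks) >= 1L)
  dots <- list(...)
  plArgs <- dots[names(dots) %in% names(formals(spaxPipeline))]
  pls <- lapply(stacks, function(st)
    do.call(spaxPipeline, c(list(st, lib), plArgs)))
  base <- pls[[1L]]
  tau <- otsuThreshold(chromophoreMap(base$result,
                                      "collagen3")[base$result@roi])
  rows <- lapply(seq_along(stacks), function(t)
    timepointMetrics(stacks[[t]], lib, label = labels[t], animal = animal,
                     collagenTau = tau, pipeline = pls[[t]], ...))
  list(metrics = do.call(rbind, rows), pipelines = pls, collagenTau = tau)
}

#' Aggregate per-animal metrics into a longitudinal table
#'
#' One row per timepoint label with mean and sd of every metric across the
#' animals sharing that label (sd is NA for single-animal labels). Rows are
#' sorted by label so the table is invariant to input order.
#'
#' @param metrics data.frame of rows from [timepointMetrics()] (or rbind of
#'   them).
#' @param labelOrder optional character vector fixing the row order;
#'   defaults to `sort(unique(metrics$label))`.
#' @return data.frame with `label`, `n_animals`, and `<metric>_mean` /
#'   `<metric>_sd` columns.
#' @export
longitudinalTable <- function(metrics, labelOrder = NULL) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L)
    stop("metrics must be a non-empty data.frame")
  if (!all(c("label", "animal") %in% names(metrics)))
    stop("metrics must have 'label' and 'animal' columns")
  num <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  if (is.null(labelOrder)) labelOrder <- sort(unique(metrics$label))
  rows <- lapply(labelOrder, function(lb) {
    sub <- metrics[metrics$label == lb, , drop = FALSE]
    out <- data.frame(label = lb, n_animals = nrow(sub))
    for (m in num) {
      out[[paste0(m, "_mean")]] <- mean(sub[[m]])
      out[[paste0(m, "_sd")]] <- if (nrow(sub) > 1L) stats::sd(sub[[m]])
        else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}
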