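# First-order B-mode ultrasound features: echointensity (mean gray level)
# and heterogeneity (local or global gray-level variance).

#' Echointensity of a B-mode ROI
#'
#' Arithmetic mean of the gray levels over the ROI pixels — the first-order
#' echogenicity feature tracking tissue density changes.
#'
#' @param bmode numeric `depth x lateral` image, gray levels in [0, 255].
#' @param roi logical ROI mask.
#' @return mean gray level.
#' @export
echointensity <- function(bmode, roi) {
  checkRoi(roi)
  if (!identical(dim(bmode), dim(roi)))
    stop("bmode and roi must share one shape")
  mean(bmode[roi])
}

#' Heterogeneity of a B-mode ROI
#'
#' Mode `"local"` (default): for every ROI pixel, the population variance of
#' the gray levels in its `windowPx x windowPx` neighbourhood (clipped at
#' image borders and restricted to ROI pixels), averaged over the ROI — the
#' local-variance texture feature. Mode `"global"`: the population variance
#' over the whole ROI. Variance uses the population (n) convention, fixed for
#' reproducibility.
#'
#' @param bmode numeric image.
#' @param roi logical ROI mask.
#' @param mode `"local"` or `"global"`.
#' @param windowPx odd window size >= 3 for local mode (default 5).
#' @return variance in squared gray levels.
#' @export
heterogeneity <- function(bmode, roi, mode = c("local", "global"),
                          windowPx = 5L) {
  mode <- match.arg(mode)
  checkRoi(roi)
  if (!identical(dim(bmode), dim(roi)))
    stop("bmode and roi must share one shape")
  if (mode == "global") {
    v <- bmode[roi]
    return(mean((v - mean(v))^2))
  }
  if (windowPx < 3L || windowPx %% 2L == 0L)
    stop("windowPx must be an odd integer >= 3")
  rm_ <- roi * 1
  n <- boxSums(rm_, windowPx)
  s <- boxSums(bmode * rm_, windowPx)
  ss <- boxSums(bmode^2 * rm_, windowPx)
  localVar <- pmax(ss / n - (s / n)^2, 0)
  mean(localVar[roi])
}
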