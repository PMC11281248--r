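# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) + 7919 * as.double(k)) %% 2147483647)
}

# Otsu threshold of a numeric vector (delegated to EBImage on a 256-level
# histogram over the observed range). Degenerate (constant) input returns the
# constant itself so that `> tau` selects nothing.
otsuThreshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values to threshold")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  EBImage::otsu(matrix(x, nrow = 1L), range = r, levels = levels)
}

# Sliding-window box sums of `m` (w x w window, clipped at borders), via an
# integral image; exact, O(1) per pixel.
boxSums <- function(m, w) {
  stopifnot(w >= 1L, w %% 2L == 1L)
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(apply(m, 2L, cumsum), nr, nc)
  if (nc > 1L) for (j in 2:nc) cs[, j] <- cs[, j] + cs[, j - 1L]
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- cs
  r0 <- pmax(seq_len(nr) - h - 1L, 0L); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h - 1L, 0L); c1 <- pmin(seq_len(nc) + h, nc)
  ii[r1 + 1L, c1 + 1L, drop = FALSE] - ii[r0 + 1L, c1 + 1L, drop = FALSE] -
    ii[r1 + 1L, c0 + 1L, drop = FALSE] + ii[r0 + 1L, c0 + 1L, drop = FALSE]
}

# Stop unless `x` is a logical mask with at least one TRUE pixel.
checkRoi <- function(roi) {
  if (!is.matrix(roi) || !is.logical(roi))
    stop("roi must be a logical matrix")
  if (!any(roi)) stop("ROI is empty")
  invisible(roi)
}
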