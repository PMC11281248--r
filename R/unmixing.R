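# The SPAX core: SVD denoising with automatic rank selection, superpixel
# subsampling, NNMF endmember extraction, full-resolution abundance
# projection, and identification of components against a reference library.

# Pixel-spectra matrix of a stack: (depth*lateral) x n_wavelengths,
# pixels in column-major (depth-fastest) order.
pixelSpectra <- function(stack) {
  d <- dim(stack@data)
  t(matrix(stack@data, d[1L], d[2L] * d[3L]))
}

#' SVD denoising and automatic rank selection
#'
#' Truncates `X` to the smallest rank whose cumulative squared singular
#' values reach `energyFrac` of the total spectral energy. The selected rank
#' doubles as the suggested NNMF component count, tying the hyperparameter
#' choice to the data's effective dimensionality.
#'
#' @param X numeric matrix (samples x wavelengths).
#' @param energyFrac fraction of squared-singular-value energy to retain,
#'   in (0, 1] (default 0.99).
#' @return list with `X` (the low-rank reconstruction), `rank`, and
#'   `singularValues`.
#' @export
svdDenoise <- function(X, energyFrac = 0.99) {
  X <- as.matrix(X)
  if (energyFrac <= 0 || energyFrac > 1)
    stop("energyFrac must lie in (0, 1]")
  if (all(X == 0)) stop("cannot denoise an all-zero matrix")
  sv <- svd(X)
  en <- cumsum(sv$d^2) / sum(sv$d^2)
  r <- which(en >= energyFrac - 1e-12)[1L]
  Xr <- sv$u[, 1:r, drop = FALSE] %*% (sv$d[1:r] *
          t(sv$v[, 1:r, drop = FALSE]))
  list(X = Xr, rank = as.integer(r), singularValues = sv$d)
}

#' SLIC-style superpixel subsampling of a stack ROI
#'
#' Clusters ROI pixels on (wavelength-mean intensity, spatial position) with
#' a compactness-weighted distance, seeded on a regular grid — the SLIC
#' algorithm restricted to the ROI. Spatial connectivity of every superpixel
#' is enforced by reassigning stray connected components to their most
#' frequent neighbouring label. Subsampling to a few hundred superpixels both
#' averages down pixel noise and rebalances the data so that small structures
#' (weak absorbers such as collagen) are not swamped by large homogeneous
#' regions during factorization. Deterministic given its inputs.
#'
#' @param stack a (fluence-corrected) [MultispectralStack-class].
#' @param roi logical ROI mask.
#' @param nSuperpixels requested superpixel count, `1..#ROI pixels`.
#' @param compactness spatial-regularity weight (default 0.25; larger values
#'   give squarer superpixels).
#' @param maxIter SLIC iterations (default 10).
#' @return a [SuperpixelMap-class]; the realized count can differ slightly
#'   from the request, as is usual for SLIC.
#' @export
superpixelSubsample <- function(stack, roi = roiMask(stack), nSuperpixels,
                                compactness = 0.25, maxIter = 10L) {
  stopifnot(is(stack, "MultispectralStack"))
  checkRoi(roi)
  npixroi <- sum(roi)
  if (nSuperpixels < 1L) stop("nSuperpixels must be >= 1")
  if (nSuperpixels > npixroi)
    stop("nSuperpixels exceeds the ROI pixel count")
  d <- dim(stack@data)
  depth <- d[2L]; lateral <- d[3L]
  X <- pixelSpectra(stack)
  roiIdx <- which(roi)

  if (nSuperpixels == npixroi) {
    lab <- matrix(-1L, depth, lateral)
    lab[roiIdx] <- seq_len(npixroi) - 1L
    return(new("SuperpixelMap", labels = lab,
               meanSpectra = X[roiIdx, , drop = FALSE],
               wavelengths = stack@wavelengths))
  }

  I <- matrix(colMeans(matrix(stack@data, d[1L], depth * lateral)),
              depth, lateral)
  rI <- range(I[roi])
  In <- if (diff(rI) > 0) (I - rI[1L]) / diff(rI) else I * 0
  rc <- arrayInd(roiIdx, c(depth, lateral))
  step <- sqrt(npixroi / nSuperpixels)
  rb <- range(rc[, 1L]); cb <- range(rc[, 2L])
  H <- diff(rb) + 1L; W <- diff(cb) + 1L
  # seed grid sized to the requested count, respecting the bbox aspect ratio
  nsc <- max(1L, round(sqrt(nSuperpixels * W / H)))
  nsr <- max(1L, round(nSuperpixels / nsc))
  sr <- rb[1L] + (seq_len(nsr) - 0.5) * H / nsr
  sc <- cb[1L] + (seq_len(nsc) - 0.5) * W / nsc
  cen <- expand.grid(r = sr, c = sc)
  # snap each seed to its nearest ROI pixel; collapse duplicates
  for (k in seq_len(nrow(cen))) {
    j <- which.min((rc[, 1L] - cen$r[k])^2 + (rc[, 2L] - cen$c[k])^2)
    cen$r[k] <- rc[j, 1L]; cen$c[k] <- rc[j, 2L]
  }
  cen <- unique(cen)
  K <- nrow(cen)
  cenI <- In[cbind(round(cen$r), round(cen$c))]
  m2 <- compactness^2
  lab1 <- integer(npixroi)   # 1-based label per ROI pixel
  for (it in seq_len(maxIter)) {
    best <- rep(Inf, npixroi); lab1 <- integer(npixroi)
    for (k in seq_len(K)) {
      w <- which(abs(rc[, 1L] - cen$r[k]) <= 1.5 * step &
                 abs(rc[, 2L] - cen$c[k]) <= 1.5 * step)
      if (!length(w)) next
      dd <- (In[roiIdx[w]] - cenI[k])^2 +
        m2 * ((rc[w, 1L] - cen$r[k])^2 + (rc[w, 2L] - cen$c[k])^2) / step^2
      upd <- dd < best[w]
      best[w[upd]] <- dd[upd]
      lab1[w[upd]] <- k
    }
    un <- which(lab1 == 0L)
    if (length(un)) {   # pixels outside every search window: nearest centre
      for (i in un) {
        d2 <- (cen$r - rc[i, 1L])^2 + (cen$c - rc[i, 2L])^2
        lab1[i] <- which.min(d2)
      }
    }
    for (k in seq_len(K)) {
      w <- lab1 == k
      if (any(w)) {
        cen$r[k] <- mean(rc[w, 1L]); cen$c[k] <- mean(rc[w, 2L])
        cenI[k] <- mean(In[roiIdx[w]])
      }
    }
  }

  lab <- matrix(-1L, depth, lateral)
  lab[roiIdx] <- lab1
  lab <- enforceConnectivity(lab, cen)
  # contiguous relabel 0..K-1 by first occurrence over ROI pixel order
  seen <- lab[roiIdx]
  u <- unique(seen)
  lab[roiIdx] <- match(seen, u) - 1L
  Kf <- length(u)
  ms <- rowsum(X[roiIdx, , drop = FALSE], lab[roiIdx]) /
    as.numeric(table(factor(lab[roiIdx], levels = 0:(Kf - 1L))))
  new("SuperpixelMap", labels = lab, meanSpectra = unname(as.matrix(ms)),
      wavelengths = stack@wavelengths)
}

# Reassign connected components that are not their label's largest component
# to the most frequent 4-neighbour label; a few passes suffice.
enforceConnectivity <- function(lab, cen) {
  depth <- nrow(lab); lateral <- ncol(lab)
  for (pass in 1:5) {
    changed <- FALSE
    for (k in sort(unique(lab[lab >= 0L]))) {
      mask <- lab == k
      comp <- EBImage::bwlabel(mask)
      nc <- max(comp)
      if (nc <= 1) next
      sizes <- tabulate(comp[comp > 0L], nbins = nc)
      main <- which.max(sizes)
      for (cc in seq_len(nc)) {
        if (cc == main) next
        px <- which(comp == cc)
        rcpx <- arrayInd(px, dim(lab))
        nb <- integer(0)
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          rr <- rcpx[, 1L] + d[1L]; ccx <- rcpx[, 2L] + d[2L]
          ok <- rr >= 1L & rr <= depth & ccx >= 1L & ccx <= lateral
          v <- lab[cbind(rr[ok], ccx[ok])]
          nb <- c(nb, v[v >= 0L & v != k])
        }
        lab[px] <- if (length(nb)) {
          tb <- table(nb)
          as.integer(names(tb)[which.max(tb)])
        } else k   # isolated island keeps its label (stays a component)
        if (length(nb)) changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# NNDSVD initialization (Boutsidis & Gallopoulos): deterministic non-negative
# factors from the truncated SVD; sign convention fixed for reproducibility.
nndsvdInit <- function(X, K, eps = 1e-12) {
  sv <- svd(X, nu = K, nv = K)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, n, K); H <- matrix(0, K, p)
  W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  if (K >= 2L) for (j in 2:K) {
    if (sv$d[j] <= eps) { W[, j] <- eps; H[j, ] <- eps; next }
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      sig <- nup * nvp
      if (sig > eps) {
        W[, j] <- sqrt(sv$d[j] * sig) * up / nup
        H[j, ] <- sqrt(sv$d[j] * sig) * vp / nvp
      }
    } else {
      sig <- nun * nvn
      W[, j] <- sqrt(sv$d[j] * sig) * un / nun
      H[j, ] <- sqrt(sv$d[j] * sig) * vn / nvn
    }
  }
  W[W < eps] <- eps; H[H < eps] <- eps
  list(W = W, H = H)
}

#' Non-negative matrix factorization of pixel spectra
#'
#' Factorizes the non-negative data matrix `X ~ A %*% S` into K endmember
#' spectra (rows of `S`) and their abundances, using deterministic NNDSVD
#' initialization and multiplicative (Lee-Seung, Frobenius) updates. The
#' non-negativity of both factors is what makes the decomposition physically
#' interpretable: spectra are absorption signatures and abundances are
#' relative concentrations. Rows of `S` are normalized to unit maximum with
#' the scale absorbed into the abundances. Negative entries of `X` (possible
#' after noise or fluence correction) are clipped to zero with a message.
#'
#' @param X numeric matrix, samples x wavelengths.
#' @param K number of components, `1 <= K <= min(dim(X))`.
#' @param seed RNG seed (only used for `init = "random"`; the default NNDSVD
#'   path is deterministic).
#' @param maxIter,tol stopping rule: at most `maxIter` multiplicative update
#'   sweeps, or relative improvement of the reconstruction error below `tol`.
#' @param init `"nndsvd"` (default) or `"random"`.
#' @return list with `S` (K x wavelengths), `A` (samples x K), `errorTrace`
#'   (relative Frobenius error per iteration) and `reconError`.
#' @export
nnmfUnmix <- function(X, K, seed = 1L, maxIter = 500L, tol = 1e-9,
                      init = c("nndsvd", "random")) {
  X <- as.matrix(X)
  init <- match.arg(init)
  if (K < 1L) stop("K must be >= 1")
  if (K > min(dim(X)))
    stop(sprintf("K = %d exceeds min(dim(X)) = %d", K, min(dim(X))))
  nneg <- sum(X < 0)
  if (nneg > 0) {
    message(sprintf("clipped %d negative entries of X to 0 before NNMF", nneg))
    X[X < 0] <- 0
  }
  if (all(X == 0)) stop("cannot factorize an all-zero matrix")
  eps <- 1e-12
  if (init == "nndsvd") {
    f <- nndsvdInit(X, K, eps)
  } else {
    f <- withSeed(seed, list(
      W = matrix(stats::runif(nrow(X) * K, 0, max(X)), ncol = K),
      H = matrix(stats::runif(K * ncol(X)), nrow = K)))
  }
  W <- f$W; H <- f$H
  nX <- sqrt(sum(X^2))
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    err <- sqrt(sum((X - W %*% H)^2)) / nX
    trace <- c(trace, err)
    if (is.finite(prev) && prev - err < tol * max(err, 1e-30) &&
        prev - err >= 0) break
    prev <- err
  }
  # alternating exact-NNLS refinement: multiplicative updates approach the
  # optimum slowly near zero entries; a few ANLS sweeps finish the job and
  # keep the error trace non-increasing (each half-step is an exact minimizer)
  if (K <= 10L) {
    for (it2 in seq_len(500L)) {
      prevErr <- trace[length(trace)]
      W2 <- nnlsBatch(X, H)
      H2 <- t(nnlsBatch(t(X), t(W2)))
      if (any(rowSums(H2) == 0) || any(colSums(W2) == 0)) break
      err <- sqrt(sum((X - W2 %*% H2)^2)) / nX
      if (err > prevErr) break
      W <- W2; H <- H2; trace <- c(trace, err)
      if (err < 1e-12 || prevErr - err < tol * max(err, 1e-30)) break
    }
  }
  # unit-maximum rows of S; scale absorbed into abundances
  for (j in seq_len(K)) {
    m <- max(H[j, ])
    if (m > 0) { H[j, ] <- H[j, ] / m; W[, j] <- W[, j] * m }
  }
  list(S = H, A = W, errorTrace = trace, reconError = trace[length(trace)])
}

#' Project endmember abundances at full resolution
#'
#' Solves, for every ROI pixel, the non-negative least-squares problem
#' `min ||x - t(S) a||^2, a >= 0` — the pixel spectrum expressed as a
#' non-negative combination of the endmember spectra. The solver enumerates
#' all active supports (exact for the small K of spectral unmixing) and is
#' vectorized across pixels.
#'
#' @param stack the (corrected) [MultispectralStack-class].
#' @param roi logical ROI mask.
#' @param S endmember matrix `K x n_wavelengths` with no zero rows.
#' @return numeric array `depth x lateral x K`; zero outside the ROI.
#' @export
projectAbundances <- function(stack, roi = roiMask(stack), S) {
  stopifnot(is(stack, "MultispectralStack"))
  checkRoi(roi)
  S <- as.matrix(S)
  if (ncol(S) != length(stack@wavelengths))
    stop("S columns must match the stack wavelength grid")
  if (any(rowSums(abs(S)) == 0)) stop("degenerate S: zero endmember row")
  K <- nrow(S)
  if (K > 10L) stop("support-enumeration NNLS supports at most 10 components")
  X <- pixelSpectra(stack)[which(roi), , drop = FALSE]
  A <- nnlsBatch(X, S)
  d <- dim(stack@data)
  out <- array(0, dim = c(d[2L], d[3L], K))
  for (j in seq_len(K)) {
    m <- matrix(0, d[2L], d[3L])
    m[which(roi)] <- A[, j]
    out[, , j] <- m
  }
  out
}

# Exact batch NNLS by active-support enumeration: for each of the 2^K - 1
# non-empty supports solve the unconstrained least-squares problem for all
# pixels at once (QR on the support design, not normal equations, to avoid
# squaring the condition number), keep the feasible solution with the
# smallest residual. The NNLS optimum is the unconstrained solution on its
# own support, hence always among the candidates.
nnlsBatch <- function(X, S, tolNeg = 1e-10) {
  K <- nrow(S)
  n <- nrow(X)
  tX <- t(X)
  x2 <- rowSums(X^2)
  bestRes <- x2                       # empty support: a = 0
  bestA <- matrix(0, n, K)
  for (mask in seq_len(2^K - 1L)) {
    J <- which(bitwAnd(mask, bitwShiftL(1L, 0:(K - 1L))) > 0L)
    D <- t(S[J, , drop = FALSE])      # nwl x |J| design
    qrD <- qr(D)
    if (qrD$rank < length(J)) next    # collinear subset: skip
    coefs <- t(qr.coef(qrD, tX))      # n x |J|
    feas <- rowSums(coefs < -tolNeg) == 0L
    if (!any(feas)) next
    res <- colSums((tX - D %*% t(coefs))^2)
    # improvement measured relative to the incumbent residual: supports that
    # interpolate (residual ~ 0) must still displace near-degenerate rivals
    upd <- feas & res < bestRes * (1 - 1e-12)
    if (any(upd)) {
      bestRes[upd] <- res[upd]
      bestA[upd, ] <- 0
      bestA[upd, J] <- pmax(coefs[upd, , drop = FALSE], 0)
    }
  }
  bestA
}

#' Identify endmembers against a reference library
#'
#' Correlates every endmember with every library spectrum and assigns
#' chromophores greedily one-to-one by descending correlation, so that two
#' components can never both claim the same chromophore. Correlations with
#' the collagen3 entry are computed on the collagen detection band
#' (default 880--970 nm, where collagen absorbs strongly and blood/water
#' interference is low); other chromophores use the full grid. Ties are
#' broken by chromophore name order. Components left over when the library
#' is exhausted are labelled `"unknown"`.
#'
#' @param S endmember matrix `K x n_wavelengths`.
#' @param lib a [SpectraLibrary-class].
#' @param grid wavelength grid of the columns of `S`.
#' @param band numeric `c(lo, hi)` collagen matching band.
#' @return data.frame with columns `component`, `chromophore`, `correlation`.
#' @export
assignComponents <- function(S, lib, grid = wavelengthGrid(),
                             band = c(880, 970)) {
  stopifnot(is(lib, "SpectraLibrary"))
  S <- as.matrix(S)
  K <- nrow(S)
  chroms <- sort(chromophoreNames(lib))   # name order fixes tie-breaks
  cm <- matrix(-Inf, K, length(chroms), dimnames = list(NULL, chroms))
  for (j in seq_along(chroms)) {
    ref <- resampleSpectrum(getSpectrum(lib, chroms[j]), grid)
    useBand <- identical(chroms[j], "collagen3")
    for (i in seq_len(K)) {
      si <- Spectrum(grid, S[i, ], sprintf("component_%d", i))
      cm[i, j] <- tryCatch({
        if (useBand)
          pearsonSimilarity(bandRestrict(si, band[1L], band[2L]),
                            bandRestrict(ref, band[1L], band[2L]))
        else pearsonSimilarity(si, ref)
      }, error = function(e) -Inf)     # constant spectrum: unmatchable
    }
  }
  comp <- rep(NA_character_, K)
  corr <- rep(NA_real_, K)
  avail <- rep(TRUE, length(chroms))
  free <- rep(TRUE, K)
  for (step in seq_len(min(K, length(chroms)))) {
    sub <- cm
    sub[!free, ] <- -Inf; sub[, !avail] <- -Inf
    if (all(!is.finite(sub))) break
    ij <- which(sub == max(sub), arr.ind = TRUE)
    ij <- ij[order(colnames(cm)[ij[, 2L]], ij[, 1L]), , drop = FALSE][1L, ]
    comp[ij[1L]] <- chroms[ij[2L]]
    corr[ij[1L]] <- cm[ij[1L], ij[2L]]
    free[ij[1L]] <- FALSE; avail[ij[2L]] <- FALSE
  }
  comp[is.na(comp)] <- "unknown"
  data.frame(component = seq_len(K), chromophore = comp,
             correlation = corr)
}
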