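test_that("SVD rank selection recovers constructed ranks", {
  set.seed(2)
  u1 <- runif(30); u2 <- runif(30); v1 <- runif(59); v2 <- runif(59)
  X2 <- outer(u1, v1) + outer(u2, v2)
  dn <- svdDenoise(X2, 0.99)
  expect_identical(dn$rank, 2L)
  expect_lt(max(abs(dn$X - X2)), 1e-9)

  dn1 <- svdDenoise(X2, 1.0)
  expect_equal(dn1$X, X2, tolerance = 1e-12)

  X1 <- outer(u1, v1)
  noise <- matrix(rnorm(length(X1), sd = 1e-6 * max(X1)), nrow(X1))
  expect_identical(svdDenoise(X1 + noise, 0.95)$rank, 1L)
  expect_error(svdDenoise(matrix(0, 3, 3)), "all-zero")
  expect_error(svdDenoise(X1, 0), "energyFrac")
})

test_that("superpixel subsampling honours its contracts", {
  spec <- smallPhantom(noiseFrac = 0)
  st <- simulateStack(spec, refLib)$stack
  roi <- rectRoi(10, 10, 16, 16, dim(bmodeImage(st)))

  # one superpixel per pixel: mean spectra are the pixel spectra
  sp <- superpixelSubsample(st, roi, sum(roi))
  expect_identical(nrow(sp@meanSpectra), sum(roi))
  X <- spaxr:::pixelSpectra(st)[which(roi), ]
  expect_equal(unname(sp@meanSpectra), unname(X))

  # homogeneous ROI: all superpixel spectra identical
  arr <- array(rep(intensities(getSpectrum(refLib, "hb")), 20 * 24),
               dim = c(59, 20, 24))
  hst <- stackFromArray(arr)
  sph <- superpixelSubsample(hst, roiMask(hst), 4)
  expect_lt(max(apply(sph@meanSpectra, 2, function(col)
    diff(range(col)))), 1e-9)

  expect_error(superpixelSubsample(st, roi, sum(roi) + 1), "exceeds")
})

test_that("two-region phantom yields two pure superpixel spectra", {
  epsA <- intensities(getSpectrum(refLib, "hb"))
  epsB <- intensities(getSpectrum(refLib, "water"))
  arr <- array(0, dim = c(59, 24, 40))
  for (i in 1:59) {
    arr[i, , 1:20] <- epsA[i]
    arr[i, , 21:40] <- epsB[i]
  }
  st <- stackFromArray(arr)
  sp <- superpixelSubsample(st, roiMask(st), 2, compactness = 2)
  expect_identical(nrow(sp@meanSpectra), 2L)
  cors <- sapply(1:2, function(k) c(
    cor(sp@meanSpectra[k, ], epsA), cor(sp@meanSpectra[k, ], epsB)))
  expect_gt(max(cors[1, ]), 0.99)
  expect_gt(max(cors[2, ]), 0.99)
  # labels partition the ROI and are contiguous
  expect_setequal(unique(as.numeric(sp@labels)), c(0, 1))
})

test_that("NNMF factorizes exact low-rank data and is deterministic", {
  a <- c(0.5, 1, 2, 0.1, 3, 0.7)
  eps <- intensities(getSpectrum(refLib, "collagen3"))
  X <- outer(a, eps)
  fit <- nnmfUnmix(X, 1)
  expect_lt(fit$reconError, 1e-6)
  expect_equal(cor(fit$S[1, ], eps), 1.0, tolerance = 1e-9)
  expect_equal(max(fit$S[1, ]), 1)

  # spatially disjoint two-chromophore phantom: recovery up to permutation
  epsB <- intensities(getSpectrum(refLib, "hb"))
  X2 <- rbind(outer(runif(15, 0.5, 2), eps), outer(runif(15, 0.5, 2), epsB))
  fit2 <- nnmfUnmix(X2, 2)
  cors <- outer(1:2, 1:2, Vectorize(function(i, j)
    cor(fit2$S[i, ], list(eps, epsB)[[j]])))
  expect_gt(max(cors[1, ]), 0.99)
  expect_gt(max(cors[2, ]), 0.99)
  expect_true(all(apply(cors, 2, max) >= 0.99))

  refit <- nnmfUnmix(X2, 2)
  expect_identical(fit2$S, refit$S)
  expect_identical(fit2$A, refit$A)

  expect_error(nnmfUnmix(X2, 70), "exceeds")
  expect_message(nnmfUnmix(X2 - 0.06, 2), "clipped")
})

test_that("NNMF reconstruction error never increases across iterations", {
  set.seed(31)
  X <- matrix(runif(40 * 59), 40) + 0.1
  fit <- nnmfUnmix(X, 3, maxIter = 200)
  expect_true(all(diff(fit$errorTrace) <= 1e-10))
})

test_that("abundance projection solves exact NNLS", {
  # orthogonal design: closed form
  S <- rbind(c(1, 0, 0, 0), c(0, 0, 2, 0))
  arr <- array(0, dim = c(4, 1, 3))
  arr[, 1, 1] <- 1 * S[1, ] + 3 * S[2, ]
  arr[, 1, 2] <- 2 * S[1, ]
  arr[, 1, 3] <- 0
  st <- new("MultispectralStack", data = arr,
            wavelengths = c(700, 750, 800, 850),
            bmode = matrix(0, 1, 3), roi = matrix(TRUE, 1, 3),
            pixelSizeMm = 0.1)
  A <- projectAbundances(st, roiMask(st), S)
  expect_equal(A[1, 1, ], c(1, 3), tolerance = 1e-9)
  expect_equal(A[1, 2, ], c(2, 0), tolerance = 1e-9)
  expect_equal(A[1, 3, ], c(0, 0))
  expect_error(projectAbundances(st, roiMask(st), rbind(S, 0)),
               "degenerate")
})

test_that("batch NNLS matches the reference solver on random problems", {
  skip_if_not_installed("pracma")
  set.seed(12)
  for (K in c(2, 4)) {
    S <- matrix(runif(K * 20), K)
    X <- matrix(rnorm(30 * 20, sd = 1), 30)
    A <- spaxr:::nnlsBatch(X, S)
    for (i in sample(30, 8)) {
      ref <- pracma::lsqnonneg(t(S), X[i, ])$x
      expect_equal(A[i, ], ref, tolerance = 1e-7)
    }
  }
})

test_that("component assignment is greedy, one-to-one and band-aware", {
  chroms <- chromophoreNames(refLib)
  S <- t(sapply(chroms, function(k)
    intensities(getSpectrum(refLib, k))))
  asg <- assignComponents(S, refLib)
  expect_identical(asg$chromophore, chroms)
  expect_true(all(asg$correlation > 1 - 1e-9))

  set.seed(6)
  rng <- apply(S, 1, function(v) diff(range(v)))
  Sn <- S + matrix(rnorm(length(S), sd = 0.01 * rng), nrow(S))
  Sn[Sn < 0] <- 0
  asgn <- assignComponents(Sn, refLib)
  expect_identical(asgn$chromophore, chroms)
  expect_true(all(asgn$correlation >= 0.95))

  one <- SpectraLibrary(getSpectrum(refLib, "collagen3"))
  two <- assignComponents(S[1:2, ], one)
  expect_identical(sort(two$chromophore), c("collagen3", "unknown"))
  expect_true(is.na(two$correlation[two$chromophore == "unknown"]))
})
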