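test_that("skinline segmentation finds a flat interface", {
  img <- matrix(0, 40, 30)
  img[15:40, ] <- 200
  expect_identical(segmentSkinline(img), rep(14L, 30))

  # one outlier column is repaired by the median smoothing
  noisy <- img
  noisy[5, 17] <- 250
  expect_identical(segmentSkinline(noisy, smoothPx = 5), rep(14L, 30))
  expect_identical(segmentSkinline(noisy, smoothPx = 1)[17], 4L)

  expect_warning(sk <- segmentSkinline(matrix(0, 10, 5)), "no skinline")
  expect_identical(sk, rep(10L, 5))
  expect_error(segmentSkinline(img, smoothPx = 4), "odd")
})

test_that("fluence correction inverts the forward attenuation", {
  spec <- liverPhantom(depth = 48L, lateral = 40L, lib = refLib,
                       noiseFrac = 0, skinDepthPx = 5L, seed = 2L)
  sim <- simulateStack(spec, refLib)
  mu <- defaultMuEff(refLib)
  corr <- correctFluence(sim$stack, rep(5L, 40), mu,
                         surfaceFluence = 1, maxGain = 1e9)
  # corrected sub-skin voxels must equal the unattenuated mixture signal
  E <- t(sapply(names(spec@concMaps), function(k)
    intensities(getSpectrum(refLib, k))))
  C <- sapply(spec@concMaps, as.numeric)
  want <- array(t(C %*% E), dim = dim(stackArray(sim$stack)))
  got <- stackArray(corr)
  sub <- slice.index(got, 2) > 5   # rows strictly below the skin row
  nz <- sub & want > 1e-12
  expect_lt(max(abs(got[nz] - want[nz]) / want[nz]), 1e-9)
})

test_that("zero attenuation leaves the stack untouched and the cap engages", {
  spec <- columnSpec("hb", depth = 10L, pixelSizeMm = 1, muEff = flatMu(0.1))
  sim <- simulateStack(spec, refLib)
  same <- correctFluence(sim$stack, 0L, flatMu(0))
  expect_identical(stackArray(same), stackArray(sim$stack))

  expect_message(capped <- correctFluence(sim$stack, 0L, flatMu(1),
                                          maxGain = 100),
                 "capped at 100x")
  # deepest voxel: uncapped gain exp(9) > 100, so applied gain is exactly 100
  expect_equal(stackArray(capped)[, 10, 1],
               stackArray(sim$stack)[, 10, 1] * 100)
  expect_error(correctFluence(sim$stack, 0L, flatMu(0.1),
                              surfaceFluence = 0), "positive")
})

test_that("correction gain is monotone in depth and sign-preserving", {
  spec <- smallPhantom(noiseFrac = 0.05)
  sim <- simulateStack(spec, refLib)
  corr <- correctFluence(sim$stack, rep(6L, 96), defaultMuEff(refLib))
  raw <- stackArray(sim$stack); cor_ <- stackArray(corr)
  expect_true(all(sign(cor_) == sign(raw)))
  gain <- abs(cor_) / pmax(abs(raw), 1e-300)
  # fixed wavelength and column: gain never decreases with depth below skin
  g <- gain[10, 7:64, 20]
  expect_true(all(diff(g) > -1e-9))
})

test_that("rectangular ROIs follow the half-open 0-based contract", {
  m <- rectRoi(0, 0, 2, 2, c(4, 4))
  expect_equal(sum(m), 4)
  expect_true(all(m[1:2, 1:2]))
  expect_error(rectRoi(0, 0, 5, 2, c(4, 4)), "bounds")
  expect_error(rectRoi(2, 2, 2, 3, c(4, 4)), "empty")
})

test_that("ROI masks round-trip through PNG", {
  mask <- rectRoi(2, 3, 10, 12, c(16, 16))
  f <- withr::local_tempfile(fileext = ".png")
  saveRoiMask(mask, f)
  expect_identical(loadRoiMask(f), mask)
  expect_error(loadRoiMask(f, shape = c(8, 8)), "shape")
  empty <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 4, 4), empty)
  expect_error(loadRoiMask(empty), "empty")
})
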