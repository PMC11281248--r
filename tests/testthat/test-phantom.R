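test_that("forward model collapses to the absorption spectrum", {
  spec <- columnSpec("collagen3", depth = 1L, muEff = flatMu(0))
  sim <- simulateStack(spec, refLib)
  eps <- intensities(getSpectrum(refLib, "collagen3"))
  expect_equal(as.numeric(stackArray(sim$stack)[, 1, 1]), eps)
  expect_equal(as.numeric(noiselessStack(sim$truth)), eps)
})

test_that("depth attenuation follows the closed-form exponential", {
  spec <- columnSpec("hb", depth = 2L, pixelSizeMm = 1, muEff = flatMu(0.1))
  sim <- simulateStack(spec, refLib)
  arr <- stackArray(sim$stack)
  expect_equal(arr[, 2, 1], arr[, 1, 1] * exp(-0.1), tolerance = 1e-12)
})

test_that("simulation is bit-deterministic given the seed", {
  spec <- smallPhantom(seed = 3)
  a <- simulateStack(spec, refLib)
  b <- simulateStack(spec, refLib)
  expect_identical(stackArray(a$stack), stackArray(b$stack))
  expect_identical(bmodeImage(a$stack), bmodeImage(b$stack))
  spec2 <- spec; spec2@seed <- 4L
  expect_false(identical(stackArray(simulateStack(spec2, refLib)$stack),
                         stackArray(a$stack)))
})

test_that("forward model is linear in the concentration maps", {
  d <- c(6L, 5L)
  set.seed(8)
  m1 <- matrix(runif(prod(d)), d[1]); m2 <- matrix(runif(prod(d)), d[1])
  mk <- function(m) PhantomSpec(list(hbo2 = m), noiseSd = 0,
                                bmodeLocalVar = 0, seed = 1L)
  s1 <- simulateStack(mk(m1), refLib)$stack
  s2 <- simulateStack(mk(m2), refLib)$stack
  s12 <- simulateStack(mk(m1 + m2), refLib)$stack
  expect_equal(stackArray(s12), stackArray(s1) + stackArray(s2),
               tolerance = 1e-12)
  expect_true(all(stackArray(s1) >= 0))
})

test_that("stronger attenuation strictly dims every absorbing sub-skin pixel", {
  spec <- columnSpec("water", depth = 4L, pixelSizeMm = 1,
                     muEff = flatMu(0.05))
  hi <- spec; hi@muEff <- flatMu(0.2)
  a <- noiselessStack(simulateStack(spec, refLib)$truth)
  b <- noiselessStack(simulateStack(hi, refLib)$truth)
  deeper <- a[, -1, , drop = FALSE] # depth 0 is at the skinline: unattenuated
  expect_true(all(b[, -1, ][deeper > 0] < deeper[deeper > 0]))
})

test_that("B-mode simulator hits its first-order targets", {
  spec <- liverPhantom(depth = 256L, lateral = 256L, lib = refLib,
                       noiseFrac = 0, skinDepthPx = 0L, seed = 2L)
  roi <- matrix(TRUE, 256, 256)
  img <- simulateBmode(spec, 103.4, 135, seed = 21L)
  expect_true(all(img >= 0 & img <= 255))
  expect_lt(abs(echointensity(img, roi) - 103.4) / 103.4, 0.05)
  expect_lt(abs(heterogeneity(img, roi) - 135) / 135, 0.05)

  # zero variance collapses to a constant tissue level
  flat <- simulateBmode(spec, 50, 0, seed = 1L)
  expect_true(all(flat == 50))

  # different seeds: different speckle, same summary statistics
  img2 <- simulateBmode(spec, 103.4, 135, seed = 22L)
  expect_false(identical(img, img2))
  expect_lt(abs(echointensity(img2, roi) - echointensity(img, roi)), 5)
})

test_that("progression scales only the collagen contribution", {
  spec <- smallPhantom(noiseFrac = 0)
  series <- simulateProgression(spec, c(1, 1, 1), refLib)
  expect_identical(stackArray(series[[1]]$stack),
                   stackArray(series[[2]]$stack))
  expect_identical(stackArray(series[[2]]$stack),
                   stackArray(series[[3]]$stack))

  two <- simulateProgression(spec, c(1, 2), refLib)
  colOnly <- spec
  colOnly@concMaps <- spec@concMaps["collagen3"]
  colStack <- stackArray(simulateStack(colOnly, refLib)$stack)
  expect_equal(stackArray(two[[2]]$stack) - stackArray(two[[1]]$stack),
               colStack, tolerance = 1e-10)

  expect_error(simulateProgression(spec, numeric(0)), "non-empty")
  expect_error(simulateProgression(spec, c(1, -1)), "positive")
})

test_that("phantom truth tracks SO2 and rejects bad specs", {
  spec <- smallPhantom()
  sim <- simulateStack(spec, refLib)
  so2 <- trueSO2(sim$truth)
  ok <- !is.na(so2)
  expect_true(all(so2[ok] >= 0 & so2[ok] <= 1))
  thb <- spec@concMaps$hbo2 + spec@concMaps$hb
  expect_identical(unname(ok), unname(thb > 0))

  bad <- spec; bad@concMaps$extra <- spec@concMaps$hb
  names(bad@concMaps)[4] <- "melanin"
  expect_error(simulateStack(bad, refLib), "melanin")
  expect_error(PhantomSpec(list(hb = matrix(-1, 2, 2))), "non-negative")
})
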