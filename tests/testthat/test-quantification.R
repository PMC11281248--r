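test_that("ROI mean spectrum averages pixel spectra", {
  arr <- array(7, dim = c(59, 3, 3))
  st <- stackFromArray(arr)
  expect_equal(intensities(roiMeanSpectrum(st)), rep(7, 59))

  s1 <- runif(59); s2 <- runif(59)
  arr2 <- array(0, dim = c(59, 1, 2))
  arr2[, 1, 1] <- s1; arr2[, 1, 2] <- s2
  st2 <- stackFromArray(arr2)
  expect_equal(intensities(roiMeanSpectrum(st2)), (s1 + s2) / 2)
  expect_error(roiMeanSpectrum(st, roi = matrix(FALSE, 3, 3)), "empty")

  # single-chromophore phantom without attenuation: mean spectrum is pure
  spec <- columnSpec("fat", depth = 5L, muEff = flatMu(0))
  sim <- simulateStack(spec, refLib)
  expect_equal(pearsonSimilarity(
    roiMeanSpectrum(sim$stack, matrix(TRUE, 5, 1)),
    getSpectrum(refLib, "fat")), 1.0, tolerance = 1e-12)
})

test_that("collagen correlation matches the direct band-restricted formula", {
  c3 <- getSpectrum(refLib, "collagen3")
  expect_equal(collagenCorrelation(c3, refLib), 1.0)

  hbo2 <- getSpectrum(refLib, "hbo2")
  direct <- cor(intensities(bandRestrict(hbo2, 880, 970)),
                intensities(bandRestrict(c3, 880, 970)))
  expect_equal(collagenCorrelation(hbo2, refLib), direct, tolerance = 1e-12)

  # more collagen in the mixture: strictly higher band correlation
  spec <- smallPhantom(noiseFrac = 0)
  series <- simulateProgression(spec, c(1, 4), refLib)
  roi <- roiMask(series[[1]]$stack)
  c1 <- collagenCorrelation(series[[1]]$stack, refLib, roi = roi)
  c4 <- collagenCorrelation(series[[2]]$stack, refLib, roi = roi)
  expect_gt(c4, c1)
})

test_that("percent area thresholds as specified", {
  roi <- matrix(TRUE, 10, 10)
  map <- matrix(0, 10, 10)
  map[1:25] <- 1
  expect_equal(percentArea(map, roi, "fixed_value", tau = 0.5), 25)

  expect_equal(percentArea(matrix(0, 10, 10), roi, "fixed_value", tau = 0.1), 0)

  bim <- matrix(c(rep(0.1, 60), rep(0.9, 40)), 10)
  expect_equal(percentArea(bim, roi, "otsu"), 40)

  # fixed_frac mode is invariant to strictly monotone rescaling
  set.seed(3)
  m <- matrix(runif(100), 10)
  p0 <- percentArea(m, roi, "fixed_frac", frac = 0.4)
  expect_equal(percentArea(3.7 * m, roi, "fixed_frac", frac = 0.4), p0)
})

test_that("SO2 maps follow the hemoglobin ratio and masking rules", {
  so2 <- computeSO2(matrix(0.8), matrix(0.2))
  expect_equal(so2[1, 1], 0.8)
  expect_true(is.na(computeSO2(matrix(0), matrix(0))[1, 1]))
  expect_error(computeSO2(matrix(-1), matrix(1)), "non-negative")

  # summaries invariant to common rescaling of both abundances
  set.seed(9)
  A <- matrix(runif(64), 8); B <- matrix(runif(64), 8)
  roi <- matrix(TRUE, 8, 8)
  expect_equal(so2Percent(computeSO2(5 * A, 5 * B), roi),
               so2Percent(computeSO2(A, B), roi), tolerance = 1e-12)
  expect_equal(so2Percent(computeSO2(A, B), roi, mode = "area"),
               100 * mean(A / (A + B) > 0.5))
})

test_that("collagen/SO2 ratio is guarded and correct", {
  expect_equal(collagenSO2Ratio(40, 80), 0.5)
  expect_equal(collagenSO2Ratio(0, 55), 0)
  expect_error(collagenSO2Ratio(10, 0), "positive")
})

test_that("supervised SO2 recovery is exact on noiseless phantoms", {
  spec <- smallPhantom(noiseFrac = 0)
  sim <- simulateStack(spec, refLib)
  mu <- defaultMuEff(refLib)
  corr <- correctFluence(sim$stack, rep(6L, 96), mu, maxGain = 1e9)
  S <- t(sapply(c("collagen3", "hbo2", "hb"), function(k)
    intensities(getSpectrum(refLib, k))))
  A <- projectAbundances(corr, roiMask(corr), S)
  so2 <- computeSO2(A[, , 2], A[, , 3])
  roi <- roiMask(corr)
  truth <- trueSO2(sim$truth)
  ok <- roi & !is.na(so2) & !is.na(truth)
  expect_gt(sum(ok), 0.9 * sum(roi))
  expect_lt(max(abs(so2[ok] - truth[ok])), 1e-9)
})

test_that("longitudinal tables aggregate with correct arithmetic", {
  one <- data.frame(animal = "a1", label = "baseline",
                    collagen_percent_area = 12.5)
  t1 <- longitudinalTable(one)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$collagen_percent_area_mean, 12.5)
  expect_true(is.na(t1$collagen_percent_area_sd))

  set.seed(13)
  met <- expand.grid(animal = paste0("a", 1:4),
                     label = c("t1", "t2", "t3", "t4"),
                     stringsAsFactors = FALSE)
  met$echogenicity <- runif(16, 90, 150)
  tab <- longitudinalTable(met, labelOrder = c("t1", "t2", "t3", "t4"))
  for (lb in unique(met$label)) {
    expect_equal(tab$echogenicity_mean[tab$label == lb],
                 mean(met$echogenicity[met$label == lb]))
    expect_equal(tab$echogenicity_sd[tab$label == lb],
                 sd(met$echogenicity[met$label == lb]))
  }
  shuf <- met[sample(nrow(met)), ]
  expect_equal(longitudinalTable(shuf, c("t1", "t2", "t3", "t4")), tab)
})

test_that("series-fixed thresholding makes percent area track collagen growth", {
  spec <- smallPhantom(seed = 5)
  series <- simulateProgression(spec, c(1, 2, 3), refLib)
  lm <- longitudinalMetrics(lapply(series, `[[`, "stack"),
                            c("t1", "t2", "t3"), lib = refLib,
                            nSuperpixels = 120L)
  pa <- lm$metrics$collagen_percent_area
  expect_true(all(diff(pa) >= 0))
  expect_true(all(diff(lm$metrics$collagen_ref_correlation) >= 0))
  expect_true(all(lm$metrics$collagen_percent_area >= 0 &
                  lm$metrics$collagen_percent_area <= 100))
})
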