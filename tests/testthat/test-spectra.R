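test_that("wavelength grids enforce the acquisition window", {
  expect_length(wavelengthGrid(), 59L)
  expect_equal(wavelengthGrid()[2] - wavelengthGrid()[1], 5)
  expect_error(wavelengthGrid(600, 970, 5), "within")
  expect_error(wavelengthGrid(680, 971, 5), "multiple")
  expect_error(Spectrum(c(700, 700, 710), 1:3), "strictly increasing")
  expect_error(Spectrum(c(700, 710), c(1, NA)), "finite")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  s <- Spectrum(c(680, 970), c(0, 1), "ramp")
  expect_identical(intensities(resampleSpectrum(s, c(680, 970))), c(0, 1))
  expect_equal(intensities(resampleSpectrum(s, 825))[1], 0.5)
  expect_error(resampleSpectrum(Spectrum(c(700, 900), c(1, 2)), 680),
               "extrapolate.*680")

  # round-trip oracle: piecewise-linear on the 5 nm grid survives 5 -> 1 -> 5 nm
  set.seed(11)
  s5 <- randomSpectrum()
  fine <- seq(680, 970, by = 1)
  back <- resampleSpectrum(resampleSpectrum(s5, fine), grid59)
  expect_lt(max(abs(intensities(back) - intensities(s5))), 1e-12)
})

test_that("band restriction keeps the closed interval", {
  s <- Spectrum(grid59, seq_along(grid59), "idx")
  b <- bandRestrict(s, 880, 970)
  expect_length(wavelengths(b), 19L)       # (970-880)/5 + 1, both edges kept
  expect_equal(range(wavelengths(b)), c(880, 970))
  expect_equal(intensities(bandRestrict(s, 680, 970)), intensities(s))
  single <- bandRestrict(s, 970, 970)
  expect_identical(wavelengths(single), 970)
  expect_error(bandRestrict(s, 500, 900), "outside")
})

test_that("pearson similarity behaves as a correlation", {
  set.seed(4)
  s <- randomSpectrum()
  expect_equal(pearsonSimilarity(s, s), 1.0)
  aff <- Spectrum(grid59, 2 * intensities(s) + 7, "affine")
  expect_equal(pearsonSimilarity(s, aff), 1.0)
  neg <- Spectrum(grid59, -intensities(s), "neg")
  expect_equal(pearsonSimilarity(s, neg), -1.0)
  flat <- Spectrum(grid59, rep(3, 59), "flat")
  expect_error(pearsonSimilarity(s, flat), "zero-variance")
  sub <- bandRestrict(s, 880, 970)
  expect_error(pearsonSimilarity(s, sub), "different grids")
})

test_that("pearson similarity is symmetric, bounded and affine-invariant", {
  set.seed(99)
  for (i in 1:100) {
    a <- randomSpectrum(); b <- randomSpectrum()
    r <- pearsonSimilarity(a, b)
    expect_equal(pearsonSimilarity(b, a), r)
    expect_lte(abs(r), 1)
    a2 <- Spectrum(grid59, runif(1, 0.1, 5) * intensities(a) + rnorm(1), "a2")
    expect_equal(pearsonSimilarity(a2, b), r, tolerance = 1e-12)
  }
})

test_that("resample and band restriction commute on compatible grids", {
  set.seed(5)
  s <- randomSpectrum()
  target <- seq(680, 970, by = 1)
  a <- bandRestrict(resampleSpectrum(s, target), 880, 970)
  b <- resampleSpectrum(bandRestrict(s, 880, 970), seq(880, 970, by = 1))
  expect_equal(intensities(a), intensities(b), tolerance = 1e-12)
})

test_that("spectra CSV round-trips and validates", {
  lib <- refLib
  expect_setequal(chromophoreNames(lib),
                  c("collagen3", "hbo2", "hb", "water", "fat"))
  df <- read.csv(system.file("extdata", "chromophore_library_synthetic.csv",
                             package = "spaxr"))
  expect_equal(dim(df), c(59L, 6L))
  expect_true(all(df[-1] >= 0))
  # collagen reference peaks at 930 nm
  c3 <- getSpectrum(lib, "collagen3")
  expect_equal(wavelengths(c3)[which.max(intensities(c3))], 930)

  f <- withr::local_tempfile(fileext = ".csv")
  saveSpectraCsv(lib, f)
  lib2 <- loadSpectraCsv(f)
  expect_identical(chromophoreNames(lib2), chromophoreNames(lib))
  for (nm in chromophoreNames(lib))
    expect_lt(max(abs(intensities(getSpectrum(lib2, nm)) -
                      intensities(getSpectrum(lib, nm)))), 1e-9)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,x", "700,1", "700,2", "710,3"), bad)
  expect_error(loadSpectraCsv(bad), "strictly increasing")
  nohdr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nm,x", "700,1"), nohdr)
  expect_error(loadSpectraCsv(nohdr), "wavelength_nm")
})

test_that("default attenuation model is non-flat and bounded", {
  mu <- defaultMuEff(refLib)
  expect_equal(max(intensities(mu)), 0.15)
  expect_true(all(intensities(mu) >= 0))
  expect_gt(sd(intensities(mu)), 0.01)  # spectrally non-trivial
})
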