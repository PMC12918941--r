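test_that("contrast scaling hits the requested RMS ratio about midgray", {
  set.seed(11)
  img <- matrix(runif(64^2), 64)
  out <- scaleContrast(img, fraction = 0.2, midgray = 0.449)
  expect_equal(sd(out), 0.2 * sd(img), tolerance = 1e-12)
  expect_equal(mean(out), 0.449, tolerance = 1e-12)

  centered <- matrix(0.449 + 0.1 * sin(seq_len(64^2) / 7), 64)
  centered <- centered - mean(centered) + 0.449
  expect_equal(scaleContrast(centered, 1, 0.449), centered,
               tolerance = 1e-12)

  flat <- matrix(0.7, 32, 32)
  expect_true(all(scaleContrast(flat, 0.2) == 0.449))

  expect_error(scaleContrast(matrix(1.2, 4, 4), 0.2), "\\[0, 1\\]")
  expect_error(scaleContrast(matrix(0.5, 4, 4), 1.3), "fraction")
})

test_that("Laplacian pyramid is exactly invertible", {
  set.seed(21)
  for (n in c(64, 128)) {
    x <- matrix(rnorm(n^2), n)
    p <- laplacianPyramid(x, as.integer(log2(n)) - 1L)
    expect_lt(max(abs(reconstructPyramid(p) - x)), 1e-9)
  }
  expect_error(laplacianPyramid(matrix(0, 100, 100), 3), "power of two")
  expect_error(laplacianPyramid(matrix(0, 64, 64), 9), "nLevels")
})

test_that("band centers are octave-spaced and match the canonical set", {
  b <- buildPyramidBands(512, 7)
  expect_equal(b@centers, c(1.75, 3.5, 7, 14, 28, 56, 112))
  expect_equal(b@centers[-1] / b@centers[-7], rep(2, 6))
  expect_error(buildPyramidBands(500, 7), "power of two")
})

test_that("band filters concentrate energy near their nominal centers", {
  # 128-px grid: centers 1.75, 3.5, 7, 14, 28; half-octave check per band
  b <- buildPyramidBands(128, 5)
  set.seed(31)
  peaks <- matrix(NA_real_, 3, 5)
  for (s in 1:3) {
    x <- matrix(rnorm(128^2), 128)
    bands <- bandDecompose(b, x)
    peaks[s, ] <- vapply(bands, radialSpectralPeak, numeric(1))
  }
  mp <- colMeans(peaks)
  expect_true(all(mp / b@centers > 1 / sqrt(2)))
  expect_true(all(mp / b@centers < sqrt(2)))
  # ordering: finer levels peak strictly higher
  expect_true(all(diff(mp) > 0))
})

test_that("bandpass noise has exactly the requested contrast and is reproducible", {
  b <- buildPyramidBands(128, 5)
  n1 <- makeBandpassNoise(b, level = 2, sigma = 0.04, seed = 7)
  expect_equal(sd(n1), 0.04, tolerance = 1e-12)
  expect_equal(mean(n1), 0, tolerance = 1e-12)
  n2 <- makeBandpassNoise(b, level = 2, sigma = 0.04, seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(n1, makeBandpassNoise(b, 2, 0.04, seed = 8)))
  expect_true(all(makeBandpassNoise(b, 2, 0, seed = 7) == 0))
  expect_error(makeBandpassNoise(b, 2, -0.1, 1), "sigma")
})

test_that("stimulus composition clips to [0,1] and is additive", {
  b <- buildPyramidBands(128, 5)
  n <- makeBandpassNoise(b, level = 4, sigma = 0.16, seed = 3)
  out <- composeStimulus(NULL, n)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(out[abs(n) < 0.4][1], (0.449 + n[abs(n) < 0.4])[1])

  scene <- matrix(runif(128^2, 0.3, 0.6), 128)
  expect_equal(composeStimulus(scene, matrix(0, 128, 128)), scene,
               ignore_attr = TRUE)
  expect_error(composeStimulus(scene[1:64, 1:64], n), "shapes differ")
})

test_that("radial spectral peak identifies known spectra", {
  n <- 128
  g <- outer(seq_len(n), seq_len(n),
             function(i, j) sin(2 * pi * 14 * i / n))
  expect_equal(radialSpectralPeak(g), 14)

  # unfiltered white noise: annulus power grows with area, peak near Nyquist
  set.seed(5)
  w <- matrix(rnorm(256^2), 256)
  expect_gt(radialSpectralPeak(w), 64)

  expect_error(radialSpectralPeak(matrix(1, 16, 16)), "constant")
})

test_that("PNG writer round-trips pixels and writes the sidecar", {
  b <- buildPyramidBands(64, 3)
  n <- makeBandpassNoise(b, 1, 0.08, seed = 2)
  img <- composeStimulus(NULL, n)
  path <- tempfile(fileext = ".png")
  writeStimulusPNG(img, path, meta = list(band = 1, sigma = 0.08, seed = 2))
  expect_true(file.exists(path))
  back <- png::readPNG(path)
  expect_equal(back, matrix(as.numeric(img), 64), tolerance = 1 / 255)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$sigma, 0.08)
  expect_equal(side$clipFraction, attr(img, "clipFraction"))
  unlink(c(path, paste0(path, ".json")))
})

test_that("scene preprocessing preserves size, range and contrast contracts", {
  scene <- proceduralScene(300, seed = 9)
  expect_true(all(scene >= 0 & scene <= 1))
  expect_identical(scene, proceduralScene(300, seed = 9))

  prep <- prepareSceneImage(scene, size = 256)
  expect_equal(dim(prep), c(256L, 256L))
  expect_equal(mean(prep), 0.449, tolerance = 1e-12)
  # low-contrast output adds to strong noise without leaving [0,1] often
  expect_lt(sd(prep), 0.2 * sd(scene) + 1e-9)

  # crop takes the central window; resample of a constant is constant
  m <- matrix(0, 8, 8); m[4:5, 4:5] <- 1
  expect_equal(centerCrop(m, 2), matrix(1, 2, 2))
  expect_equal(resampleImage(matrix(0.3, 5, 5), 16),
               matrix(0.3, 16, 16), tolerance = 1e-12)
  # 1/f texture has most power at low frequencies
  sp <- radialPowerSpectrum(scene - mean(scene))
  expect_lt(radialSpectralPeak(scene - mean(scene)), 10)
})
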