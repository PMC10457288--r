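# Image-quality metrics: 100% lines, spatial noise, SNR, slant-edge MTF,
# Siemens-star resolution, speckle contrast.

test_that("100 percent line is zero for identical backgrounds and follows the delta method", {
  ax <- SpectralAxis(seq(801, 1900, length.out = 100))
  b <- rep(1.3, 100)
  h0 <- hundredPercentLine(b, b, ax)
  expect_equal(h0$absorbance, rep(0, 100))
  expect_equal(h0$rms, 0)
  # i.i.d. relative noise sigma on both shots: RMS = sqrt(2) sigma / ln 10
  set.seed(31)
  n <- 1e4
  a1 <- rnorm(n, 1, 0.005); a2 <- rnorm(n, 1, 0.005)
  h <- hundredPercentLine(a1, a2)
  expect_equal(h$rms, sqrt(2) * 0.005 / log(10), tolerance = 0.05)
  expect_error(hundredPercentLine(c(1, -1), c(1, 1)), "positive")
  # windowing restricts the RMS region
  spikes <- rep(1, 100); spikes[1] <- 3
  hw <- hundredPercentLine(spikes, rep(1, 100), ax, windowCm1 = c(1300, 1700))
  expect_equal(hw$rms, 0)
})

test_that("100 percent line RMS scales as 1 / sqrt(n) over coadditions", {
  set.seed(32)
  n <- 1e4
  shot <- function(k) rowMeans(matrix(rnorm(n * k, 1, 0.008), n))
  r2 <- hundredPercentLine(shot(2), shot(2))$rms
  r16 <- hundredPercentLine(shot(16), shot(16))$rms
  expect_equal(r2 / r16, sqrt(8), tolerance = 0.05)
})

test_that("spatial noise estimates the per-band sigma from a frame pair", {
  expect_equal(spatialNoise(matrix(2, 10, 10), matrix(2, 10, 10)), 0)
  set.seed(33)
  a <- matrix(rnorm(500^2, 0.5, 0.003), 500)
  b <- matrix(rnorm(500^2, 0.5, 0.003), 500)
  expect_equal(spatialNoise(a, b), 0.003, tolerance = 0.03)
  expect_error(spatialNoise(a, matrix(0, 2, 2)), "shapes")
  # band sweep reproduces the transition maxima of the noise model
  cfg <- instrumentPreset("lsm10x")
  nm <- NoiseModel()
  nus <- c(1260, 1310, 1360)
  est <- vapply(seq_along(nus), function(i) {
    A1 <- acquireAbsorbance(uniformScene(0, 128, bandCm1 = nus[i]), nus[i],
                            cfg, noise = nm, seedSample = 40 + i,
                            seedBackground = 140 + i)
    A2 <- acquireAbsorbance(uniformScene(0, 128, bandCm1 = nus[i]), nus[i],
                            cfg, noise = nm, seedSample = 240 + i,
                            seedBackground = 340 + i)
    spatialNoise(A1, A2)
  }, numeric(1))
  expect_gt(est[2], est[1])
  expect_gt(est[2], est[3])
})

test_that("SNR is the plain ratio with its invariances", {
  expect_equal(snr(0.5, 0.005), 100)
  expect_error(snr(0.5, 0), "noise")
  g <- 3.7
  expect_equal(snr(g * 0.5, g * 0.005), snr(0.5, 0.005))
})

test_that("slant-edge MTF matches the pixel-aperture and Gaussian oracles", {
  # pixel-aperture-only step edge: MTF at Nyquist = 2/pi
  sc <- makeSlantEdge(5, 200, 1, antialias = TRUE)
  ea <- slantEdgeMtf(sceneMap(sc, 1658), 1)
  expect_equal(ea@edgeAngleDeg, 5, tolerance = 0.05)
  expect_equal(mtfAt(ea, 0.5), 2 / pi, tolerance = 0.02)
  # estimator bias bound on an unblurred (pixel-aperture) edge
  expect_lte(max(mtfModulation(ea)), 1.02)
  # Gaussian ESF: MTF = exp(-2 pi^2 sigma^2 f^2)
  eaG <- slantEdgeMtf(gaussianEdgeImage(200, 2), 1)
  f <- seq(0.05, 0.4, by = 0.05)
  tru <- exp(-2 * pi^2 * 4 * f^2)
  est <- mtfAt(eaG, f)
  expect_lt(max(abs(est - tru)), 0.02)
  sel <- tru > 0.1
  expect_lt(max(abs(est[sel] - tru[sel]) / tru[sel]), 0.02)
})

test_that("slant-edge estimate is invariant to gain, offset and rotation", {
  sc <- makeSlantEdge(5, 200, 1, antialias = TRUE)
  img <- sceneMap(sc, 1658)
  ea <- slantEdgeMtf(img, 1)
  eaT <- slantEdgeMtf(3 + 7 * img, 1)
  expect_equal(mtfModulation(eaT), mtfModulation(ea), tolerance = 1e-9)
  eaR <- slantEdgeMtf(t(img), 1)
  f <- seq(0.05, 0.5, by = 0.05)
  expect_equal(mtfAt(eaR, f), mtfAt(ea, f), tolerance = 0.01)
  expect_error(slantEdgeMtf(matrix(0, 50, 50), 1), "no edge")
  expect_error(suppressWarnings(
    slantEdgeMtf(sceneMap(makeSlantEdge(0.2, 128, 1, antialias = TRUE),
                          1658), 1)), "slant|no edge")
})

test_that("slant edge blurred by the diffraction model recovers the pupil MTF", {
  slope <- tan(5 * pi / 180)
  nf <- 256
  ccf <- (nf + 1) / 2
  edge <- ((col(matrix(0, nf, nf)) - ccf -
              slope * (row(matrix(0, nf, nf)) - ccf)) > 0) * 1
  kern <- psf(PupilSpec(0.4, 1658), 1)
  blur <- irlsm:::convolve2d(edge, psfSamples(kern))
  sub <- blur[seq(1, nf, by = 2), seq(1, nf, by = 2)]    # 2 um point sampling
  ea <- slantEdgeMtf(sub, 2)
  cutoff <- 2 * 0.4 / (1e4 / 1658)
  fq <- seq(0.01, 0.8, by = 0.02) * cutoff
  expect_lt(sqrt(mean((mtfAt(ea, fq) -
                         mtfAt(mtf(PupilSpec(0.4, 1658)), fq))^2)), 0.03)
})

test_that("star resolution reads the threshold crossing of the blur", {
  star <- makeSiemensStar(72, 400, 1)
  img <- sceneMap(star, 1658)
  # blur-free star resolves essentially to the sampling limit
  sr0 <- starResolution(img, star, 0.25, 1)
  expect_gte(sr0$limitFreqCycPerUm, 0.8 * 0.5)
  expect_gt(sr0$modulation[1], 0.9)                  # outer ring ~ unity
  # Gaussian blur: crossing matches the closed form within 5%
  sig <- 2.5
  blur <- irlsm:::gaussianSmooth(img, sig)
  sr <- starResolution(blur, star, 0.25, 1)
  fTrue <- sqrt(-log(0.25) / (2 * pi^2 * sig^2))
  expect_equal(sr$limitFreqCycPerUm, fTrue, tolerance = 0.05)
  # a stricter threshold fails at a lower frequency
  expect_lt(starResolution(blur, star, 0.8, 1)$limitFreqCycPerUm,
            sr$limitFreqCycPerUm)
  expect_error(starResolution(img, list(nSpokes = 72, centerPx = c(-5, 10)),
                              0.25, 1), "centre")
})

test_that("star and slant-edge agree on the 25% frequency across blur levels", {
  star <- makeSiemensStar(72, 400, 1)
  img <- sceneMap(star, 1658)
  for (sig in c(1.8, 3)) {
    sr <- starResolution(irlsm:::gaussianSmooth(img, sig), star, 0.25, 1)
    ea <- slantEdgeMtf(gaussianEdgeImage(200, sig), 1)
    fEdge <- mtfCrossing(ea, 0.25)
    expect_equal(sr$limitFreqCycPerUm, fEdge, tolerance = 0.05)
  }
})

test_that("speckle contrast separates coherent and incoherent imaging", {
  expect_equal(speckleContrast(matrix(2, 40, 40)), 0)
  expect_error(speckleContrast(matrix(1, 4, 4), matrix(FALSE, 4, 4)), "mask")
  expect_warning(speckleContrast(matrix(runif(25), 5)), "1000")
  sc <- uniformScene(0.3, 192)
  wf <- simulateWidefieldCoherent(sc, 1658, PupilSpec(0.62, 1658), seed = 8)
  expect_equal(speckleContrast(wf), 1, tolerance = 0.05)
  # mask argument restricts the region
  m <- matrix(FALSE, 192, 192); m[1:100, 1:100] <- TRUE
  expect_equal(speckleContrast(wf, m), 1, tolerance = 0.08)
})
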