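# Acquisition chain: noise model, raster frames, bidirectional alignment,
# coaddition buffer, referencing and the coherent widefield comparator.

test_that("noise magnitude has cutoff and transition structure", {
  nm <- NoiseModel(baseRelSigma = 0.005, cutoffCm1 = 900, cutoffScale = 3,
                   transitionBandsCm1 = c(1030, 1310, 1610),
                   transitionRelSigma = 0.01)
  expect_equal(sigmaAt(nm, 1450), 0.005)             # far from everything
  expect_gt(sigmaAt(nm, 1310), sigmaAt(nm, 1360))    # transition bump
  nu <- seq(900, 1020, by = 5)                       # toward cutoff, below bands
  expect_true(all(diff(sigmaAt(nm, nu)) <= 1e-12))
  expect_equal(sigmaAt(nm, 850), 0.015)              # saturated at the cutoff
  expect_error(sigmaAt(nm, -5), "bandCm1")
})

test_that("noiseless delta-PSF acquisition is the identity chain", {
  cfg <- instrumentPreset("lsm10x")
  sc <- uniformScene(0.7, 32)
  sc@absorbance[5, 7, 1] <- 1.2
  fr <- acquireFrame(sc, 1658, cfg)
  expect_equal(frameData(fr), 10^(-sc@absorbance[, , 1]))
  expect_error(acquireFrame(sc, 1500, cfg), "no band")
})

test_that("reverse lines are shifted by the injected offset", {
  cfg <- instrumentPreset("lsm10x")
  vert <- matrix(rep(c(0, 1), length.out = 32), 32, 32, byrow = TRUE)
  stripes <- Scene(array(vert, c(32, 32, 1)), matrix(0L, 32, 32),
                   SpectralAxis(1658), 2)
  fr <- acquireFrame(stripes, 1658, cfg, lineOffsetPx = 3)
  d <- frameData(fr)
  base <- 10^(-stripes@absorbance[, , 1])
  expect_equal(d[1, ], base[1, ])                       # forward line untouched
  expect_equal(d[2, 4:32], base[2, 1:29])               # reverse line shifted 3
  # acquisition is linear in scene reflectance at zero noise
  kern <- psf(PupilSpec(0.4, 1658), 2)
  mk <- function(A) Scene(array(A, c(32, 32, 1)), matrix(0L, 32, 32),
                          SpectralAxis(1658), 2)
  set.seed(3)
  A1 <- matrix(runif(32 * 32), 32); A2 <- matrix(runif(32 * 32), 32)
  mix <- -log10(0.3 * 10^(-A1) + 0.7 * 10^(-A2))
  fMix <- frameData(acquireFrame(mk(mix), 1658, cfg, kern))
  f1 <- frameData(acquireFrame(mk(A1), 1658, cfg, kern))
  f2 <- frameData(acquireFrame(mk(A2), 1658, cfg, kern))
  expect_equal(fMix, 0.3 * f1 + 0.7 * f2, tolerance = 1e-12)
})

test_that("per-pixel noise matches the requested magnitude", {
  cfg <- instrumentPreset("lsm10x")
  nm <- NoiseModel(baseRelSigma = 0.01, transitionRelSigma = 0, cutoffScale = 1)
  sc <- uniformScene(0, 1000)                      # 1e6 px, reflectance 1
  fr <- acquireFrame(sc, 1658, cfg, noise = nm, seed = 42)
  expect_equal(sd(frameData(fr)), 0.01, tolerance = 0.05)
  # and the session RNG is untouched by seeded acquisition
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(acquireFrame(uniformScene(0, 8), 1658, cfg,
                                      noise = nm, seed = 9))
  expect_identical(runif(1), before)
})

test_that("bidirectional offsets are recovered and cancelled", {
  cfg <- instrumentPreset("lsm10x")
  for (d in c(-5L, -2L, 0L, 1L, 4L)) {
    ph <- offsetPhantom(seed = 3 + abs(d))
    fr <- acquireFrame(ph, 1658, cfg, lineOffsetPx = d)
    al <- alignBidirectional(fr)
    expect_true(al$confident)
    expect_equal(round(al$offsetPx), d)
    expect_lt(abs(al$offsetPx - d), 0.05)
  }
  # zero offset leaves the frame untouched up to the tiny estimated shift
  ph <- offsetPhantom(seed = 3)
  fr0 <- acquireFrame(ph, 1658, cfg)
  al0 <- alignBidirectional(fr0)
  expect_lt(abs(al0$offsetPx), 0.05)
  expect_lt(max(abs(frameData(al0$frame) - frameData(fr0))), 0.02)
  # subpixel offset at SNR ~100 through the optics
  kern <- psf(PupilSpec(0.4, 1658), 2)
  nm <- NoiseModel(baseRelSigma = 0.01, transitionRelSigma = 0, cutoffScale = 1)
  for (s in 1:3) {
    fr <- acquireFrame(offsetPhantom(seed = 10 + s), 1658, cfg, kern,
                       noise = nm, lineOffsetPx = 0.4, seed = s)
    expect_lt(abs(alignBidirectional(fr)$offsetPx - 0.4), 0.1)
  }
  # featureless frame: low-confidence zero
  flat <- acquireFrame(uniformScene(0.3, 64), 1658, cfg, noise = nm,
                       lineOffsetPx = 2, seed = 1)
  alF <- alignBidirectional(flat)
  expect_false(alF$confident)
  expect_equal(alF$offsetPx, 0)
})

test_that("coaddition buffer averages, flushes on state change and bounds n", {
  cfg <- instrumentPreset("lsm10x")
  nm <- NoiseModel(baseRelSigma = 0.01, transitionRelSigma = 0, cutoffScale = 1)
  sc <- uniformScene(0, 128)
  buf <- FrameBuffer(16L)
  for (i in 1:16) {
    fr <- acquireFrame(sc, 1658, cfg, noise = nm, seed = 100 + i)
    st <- pushAndAverage(buf, fr, 16L)
    buf <- st$buffer
    if (i == 2) sd2 <- sd(frameData(st$frame))
  }
  sd16 <- sd(frameData(st$frame))
  expect_equal(st$frame@coadditions, 16L)
  expect_equal(sd2 / sd16, sqrt(8), tolerance = 0.05 * sqrt(8))
  # n = 1 returns the most recent frame unchanged
  fr <- acquireFrame(sc, 1658, cfg, noise = nm, seed = 999)
  st1 <- pushAndAverage(buf, fr, 1L)
  expect_equal(frameData(st1$frame), frameData(fr))
  # a state change (new band) empties the buffer first
  sc2 <- uniformScene(0, 128, bandCm1 = 1079)
  frB <- acquireFrame(sc2, 1079, cfg, noise = nm, seed = 1000)
  stB <- pushAndAverage(st1$buffer, frB, 16L)
  expect_equal(stB$frame@coadditions, 1L)
  expect_equal(frameData(stB$frame), frameData(frB))
  expect_error(pushAndAverage(stB$buffer, frB, 17L), "capacity")
})

test_that("absorbance conversion cancels shared gain and floors the ratio", {
  s <- matrix(0.1, 4, 4); b <- matrix(1, 4, 4)
  expect_equal(as.vector(toAbsorbance(b, b)), rep(0, 16))
  expect_equal(as.vector(toAbsorbance(s, b)), rep(1, 16))
  g <- matrix(runif(16, 0.5, 2), 4)
  expect_equal(as.vector(toAbsorbance(s * g, b * g)),
               as.vector(toAbsorbance(s, b)), tolerance = 1e-14)
  expect_equal(as.vector(toAbsorbance(matrix(0, 2, 2), matrix(1, 2, 2))),
               rep(6, 4))                       # floored at 1e-6
  expect_error(toAbsorbance(s, matrix(0, 4, 4)), "zero")
  expect_error(toAbsorbance(s, matrix(1, 2, 2)), "shapes")
})

test_that("referenced acquisition recovers smooth scenes (Beer-Lambert)", {
  cfg <- instrumentPreset("lsm10x")
  kern <- psf(PupilSpec(0.4, 1658), 2)
  ph <- makeTissuePhantom(96, 2, defaultSpectralLibrary(),
                          SpectralAxis(c(1079, 1658)), seed = 2, mixSigmaPx = 4)
  A <- acquireAbsorbance(ph, 1658, cfg, kern)
  expect_lt(max(abs(A - sceneMap(ph, 1658))), 0.1)    # convolution-limited
  expect_lt(sqrt(mean((A - sceneMap(ph, 1658))^2)), 0.05)
})

test_that("widefield coherent imaging speckles while point scanning does not", {
  sc <- uniformScene(0.3, 192)
  contrasts <- vapply(1:3, function(s)
    speckleContrast(simulateWidefieldCoherent(sc, 1658, PupilSpec(0.62, 1658),
                                              seed = s)), numeric(1))
  expect_true(all(abs(contrasts - 1) < 0.05))          # fully developed
  smooth <- simulateWidefieldCoherent(sc, 1658, PupilSpec(0.62, 1658),
                                      roughnessUm = 0, seed = 1)
  expect_lt(speckleContrast(smooth), 1e-10)            # no phase, no speckle
  nm <- NoiseModel(baseRelSigma = 0.01, transitionRelSigma = 0, cutoffScale = 1)
  ps <- acquireFrame(sc, 1658, instrumentPreset("lsm10x"), noise = nm, seed = 4)
  expect_lt(speckleContrast(frameData(ps)), 0.05)
})

test_that("point spectra sweep the axis with band-dependent noise", {
  cfg <- instrumentPreset("lsm10x")
  lib <- defaultSpectralLibrary()
  ax <- SpectralAxis(c(1079, 1213, 1544, 1658, 1765))
  ph <- makeTissuePhantom(32, 2, lib, ax, seed = 6)
  sp <- pointSpectrum(ph, cfg, c(10, 12))
  expect_equal(unname(sp), ph@absorbance[10, 12, ], tolerance = 1e-9)
  expect_identical(pointSpectrum(ph, cfg, c(10, 12), noise = NoiseModel(),
                                 seed = 5),
                   pointSpectrum(ph, cfg, c(10, 12), noise = NoiseModel(),
                                 seed = 5))
  expect_error(pointSpectrum(ph, cfg, c(40, 2)), "outside")
  # repeat-sweep noise reproduces sigmaAt structure
  nm <- NoiseModel(baseRelSigma = 0.01, transitionRelSigma = 0.02,
                   cutoffScale = 1, transitionBandsCm1 = 1213)
  flat <- uniformScene(0, 16, bandCm1 = 1213)
  flat@axis <- SpectralAxis(c(1079, 1213, 1658))
  flat@absorbance <- array(0, c(16, 16, 3))
  sweeps <- vapply(1:400, function(s)
    pointSpectrum(flat, cfg, c(8, 8), noise = nm, seed = s), numeric(3))
  sdA <- unname(apply(sweeps, 1, sd))
  theory <- sqrt(2) * sigmaAt(nm, c(1079, 1213, 1658)) / log(10)
  expect_equal(sdA, theory, tolerance = 0.1)
  expect_gt(sdA[2], 2 * sdA[1])                        # transition band noisier
})
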