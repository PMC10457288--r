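# Chemical-imaging analyses: composites, contaminant masking, registration,
# volumes, spectrum extraction.

test_that("false color maps listed bands to channels with a bounded stretch", {
  ax <- SpectralAxis(c(1079, 1658, 1765))
  set.seed(41)
  cube <- HyperCube(array(runif(32 * 32 * 3), c(32, 32, 3)), ax, 2)
  rgb <- falseColor(cube)
  expect_true(all(rgb >= 0 & rgb <= 1))
  # three identical bands give a gray image
  same <- HyperCube(array(rep(cube@data[, , 2], 3), c(32, 32, 3)), ax, 2)
  g <- falseColor(same, c(1079, 1658, 1765))
  expect_equal(g[, , 1], g[, , 2])
  expect_equal(g[, , 2], g[, , 3])
  expect_error(falseColor(cube, c(1079, 1300, 1765)), "nearest")
  # monotone before clamping: raising a band value never lowers its channel
  cube2 <- cube
  cube2@data[5, 5, 1] <- cube2@data[5, 5, 1] + 0.1
  r1 <- falseColor(cube)[5, 5, 1]; r2 <- falseColor(cube2)[5, 5, 1]
  expect_gte(r2, r1)
  # phantom: phosphate-rich class has the highest channel-1 mean
  ph <- makeTissuePhantom(64, 2, defaultSpectralLibrary(), ax, seed = 4)
  rgbP <- falseColor(HyperCube(ph@absorbance, ax, 2))
  cls <- classMap(ph)
  m1 <- vapply(seq_along(sceneTruth(ph)$classes),
               function(k) mean(rgbP[, , 1][cls == k]), numeric(1))
  expect_equal(which.max(m1),
               which(sceneTruth(ph)$classes == "phosphate_rich"))
})

test_that("band mask flags contaminants robustly", {
  # phantom without inclusions: empty mask
  ax <- SpectralAxis(c(1079, 1213, 1544, 1658, 1765))
  ph <- makeTissuePhantom(96, 1, defaultSpectralLibrary(), ax, seed = 3)
  cube <- HyperCube(ph@absorbance[, , c(2, 4)], SpectralAxis(c(1213, 1658)), 1)
  expect_false(any(bandMask(cube)))
  # constant marker band: empty mask with a warning
  flat <- HyperCube(array(c(rep(0.2, 96 * 96), ph@absorbance[, , 4]),
                          c(96, 96, 2)), SpectralAxis(c(1213, 1658)), 1)
  expect_warning(mEmpty <- bandMask(flat), "constant")
  expect_false(any(mEmpty))
  # mask is invariant to a global multiplicative gain
  fix <- ptfePhantomCube(seed = 2)
  m <- bandMask(fix$cube)
  gained <- HyperCube(cubeData(fix$cube) * 2.5, SpectralAxis(c(1213, 1658)), 1)
  expect_identical(bandMask(gained), m)
})

test_that("detected inclusions overlap the truth discs at high SNR", {
  jac <- vapply(2:4, function(s) {
    fix <- ptfePhantomCube(seed = s)
    m <- bandMask(fix$cube)
    sum(m & fix$truthMask) / sum(m | fix$truthMask)
  }, numeric(1))
  expect_true(all(jac >= 0.95))
  # precision and recall at SNR ~50
  fix50 <- ptfePhantomCube(seed = 6, relSigma = 0.02)
  m50 <- bandMask(fix50$cube)
  expect_gte(sum(m50 & fix50$truthMask) / sum(m50), 0.9)
  expect_gte(sum(m50 & fix50$truthMask) / sum(fix50$truthMask), 0.9)
})

test_that("mask overlay paints flagged pixels green over grayscale", {
  g <- matrix(runif(64), 8)
  m <- matrix(FALSE, 8, 8); m[2, 3] <- TRUE
  ov <- maskOverlay(g, m)
  expect_equal(ov[2, 3, ], c(0, 1, 0))
  expect_equal(ov[1, 1, 1], ov[1, 1, 2])
})

test_that("section registration recovers jitter step by step", {
  secs <- makeSerialSections(nSlices = 8, jitterPx = 4, seed = 3,
                             imagePx = 96, wanderPx = 0)
  truth <- t(vapply(secs, function(s) sceneTruth(s)$shiftPx, numeric(2)))
  est <- registerSections(secs)
  expect_equal(est[1, ], c(dy = 0, dx = 0))
  expect_lt(max(abs(diff(est) - diff(truth))), 0.1)    # per-step recovery
  # identical slices: all shifts zero
  same <- registerSections(list(secs[[1]], secs[[1]], secs[[1]]))
  expect_equal(max(abs(same)), 0)
  # anti-symmetry of the pairwise estimate
  a <- secs[[3]]@absorbance[, , 1]; b <- secs[[4]]@absorbance[, , 1]
  s1 <- irlsm:::.phaseCorrelate(a, b)$shift
  s2 <- irlsm:::.phaseCorrelate(b, a)$shift
  expect_lt(max(abs(s1 + s2)), 0.05)
  # featureless pair: zero shift, flagged unconfident
  flat <- matrix(0.5, 64, 64)
  noisy <- flat + matrix(rnorm(64^2, 0, 1e-6), 64)
  r <- registerSections(list(flat, noisy), minPeak = 0.5)
  expect_false(attr(r, "confident")[2])
  expect_equal(r[2, ], c(dy = 0, dx = 0))
  expect_error(registerSections(list(flat)), "2 slices")
})

test_that("volumes stack aligned slices with the stated z extent", {
  secs <- makeSerialSections(nSlices = 10, jitterPx = 4, seed = 5, imagePx = 64)
  est <- registerSections(secs)
  vol <- assembleVolume(secs, est, zSpacingUm = 5)
  expect_equal(dim(volumeData(vol)), c(10L, 64L, 64L))
  expect_equal(zSpacing(vol) * dim(volumeData(vol))[1], 50)  # z extent in um
  # alignment restores cross-slice continuity
  unaligned <- assembleVolume(secs, matrix(0, 10, 2), 5)
  expect_gt(adjacentSliceCorrelation(vol), adjacentSliceCorrelation(unaligned))
  # single slice is the identity
  v1 <- assembleVolume(secs[1], matrix(0, 1, 2), 5)
  expect_equal(crossSection(v1, "z", 1), secs[[1]]@absorbance[, , 1])
  # orthogonal sections have consistent shapes and bounds are checked
  expect_equal(dim(crossSection(vol, "y", 10)), c(10L, 64L))
  expect_equal(dim(crossSection(vol, "x", 10)), c(10L, 64L))
  expect_error(crossSection(vol, "z", 11), "outside")
  expect_error(assembleVolume(secs, matrix(0, 3, 2)), "one row per slice")
})

test_that("the full serial-section pipeline mirrors the 100-slice 5-um design", {
  # scaled-down block: the geometry math is what is under test
  n <- 100
  expect_equal(n * 5, 500)                      # 0.5 mm block depth
  secs <- makeSerialSections(nSlices = 6, thicknessUm = 5, jitterPx = 3,
                             seed = 9, imagePx = 48)
  vol <- assembleVolume(secs, registerSections(secs), 5)
  expect_equal(zSpacing(vol), 5)
  expect_true(mean(is.na(volumeData(vol))) < 0.5)
})

test_that("spectrum extraction returns the pixel or its neighbourhood mean", {
  ax <- SpectralAxis(c(1079, 1658, 1765))
  set.seed(43)
  cube <- HyperCube(array(runif(8 * 8 * 3), c(8, 8, 3)), ax, 2)
  sp <- extractSpectrum(cube, c(3, 5))
  expect_equal(unname(sp), cube@data[3, 5, ])
  expect_equal(names(sp), as.character(bands(cube)))
  avg <- extractSpectrum(cube, c(3, 5), average = TRUE)
  expect_equal(unname(avg), apply(cube@data[2:4, 4:6, ], 3, mean))
  zero <- HyperCube(array(0, c(4, 4, 3)), ax, 2)
  expect_equal(unname(extractSpectrum(zero, c(2, 2))), c(0, 0, 0))
  expect_error(extractSpectrum(cube, c(9, 1)), "outside")
  # end-to-end: class-pure phantom pixel through noiseless acquisition
  lib <- defaultSpectralLibrary()
  ph <- makeTissuePhantom(48, 2, lib, ax, seed = 5)
  cfg <- instrumentPreset("lsm10x")
  slab <- array(NA_real_, c(48, 48, 3))
  for (k in 1:3)
    slab[, , k] <- acquireAbsorbance(ph, bands(ax)[k], cfg)
  hc <- HyperCube(slab, ax, 2)
  cls <- classMap(ph)
  i <- which(cls == cls[25, 25], arr.ind = TRUE)[1, ]
  expect_equal(unname(extractSpectrum(hc, i)),
               evalSpectrum(lib, sceneTruth(ph)$classes[cls[i[1], i[2]]], ax),
               tolerance = 1e-9)
})
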