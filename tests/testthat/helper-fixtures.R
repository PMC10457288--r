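# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files.

# round-trip a vector through IEEE float32
f32 <- function(x) {
  con <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), con, size = 4L)
  v <- rawConnectionValue(con)
  close(con)
  readBin(v, "numeric", n = length(x), size = 4L)
}

# analytic Airy intensity (clear circular pupil), normalized to 1 at r = 0
airyIntensity <- function(rUm, na, wavenumberCm1) {
  fc <- na / (1e4 / wavenumberCm1)
  v <- 2 * pi * fc * rUm
  ifelse(v == 0, 1, (2 * besselJ(v, 1) / v)^2)
}

# analytic clear-pupil incoherent MTF at normalized frequency s = f / cutoff
clearPupilMtf <- function(s) {
  ifelse(s >= 1, 0, (2 / pi) * (acos(s) - s * sqrt(1 - s^2)))
}

# point-sampled edge with a Gaussian edge-spread (sigma in px), slant in deg
gaussianEdgeImage <- function(n, sigmaPx, angleDeg = 5) {
  cc <- (n + 1) / 2
  slope <- tan(angleDeg * pi / 180)
  t_ <- (col(matrix(0, n, n)) - cc - slope * (row(matrix(0, n, n)) - cc)) /
    sqrt(1 + slope^2)
  stats::pnorm(t_ / sigmaPx)
}

# a small textured phantom suited to line-offset estimation
offsetPhantom <- function(seed, imagePx = 128, blobScalePx = 3) {
  makeTissuePhantom(imagePx, 2, defaultSpectralLibrary(),
                    SpectralAxis(c(1079, 1658)), seed = seed,
                    blobScalePx = blobScalePx)
}

# uniform single-band scene of absorbance a0
uniformScene <- function(a0, imagePx, pixelSizeUm = 2, bandCm1 = 1658) {
  Scene(array(a0, c(imagePx, imagePx, 1)),
        matrix(1L, imagePx, imagePx), SpectralAxis(bandCm1), pixelSizeUm)
}

# acquire a referenced absorbance image of a scene band through the given
# kernel/noise chain (blank-substrate background, same conditions)
acquireAbsorbance <- function(scene, bandCm1, cfg, kern = NULL, noise = NULL,
                              seedSample = NULL, seedBackground = NULL) {
  blank <- Scene(array(0, dim(scene@absorbance)), classMap(scene),
                 scene@axis, pixelSize(scene))
  fr <- acquireFrame(scene, bandCm1, cfg, kern, noise, seed = seedSample)
  bg <- acquireFrame(blank, bandCm1, cfg, kern, noise, seed = seedBackground)
  frameData(toAbsorbance(fr, bg))
}

# tissue phantom with PTFE inclusions imaged at the marker and reference
# bands through the confocal 20x chain; returns cube + truth mask
ptfePhantomCube <- function(seed, relSigma = 0.01, imagePx = 160,
                            radiusPx = 25, nInclusions = 3) {
  cfg <- instrumentPreset("lsm20x")
  ax <- SpectralAxis(c(1079, 1213, 1544, 1658, 1765))
  nm <- NoiseModel(baseRelSigma = relSigma, transitionRelSigma = 0,
                   cutoffScale = 1)
  ph <- makeTissuePhantom(imagePx, 1, defaultSpectralLibrary(), ax,
                          seed = seed, blobScalePx = 14)
  ph <- addInclusions(ph, "ptfe", nInclusions = nInclusions,
                      radiusPx = radiusPx, seed = seed + 50)
  slab <- array(NA_real_, c(imagePx, imagePx, 2))
  for (k in 1:2) {
    b <- c(1213, 1658)[k]
    kern <- confocalPsf(PupilSpec(cfg@na, b), cfg@pinholeDiameterUm,
                        cfg@detectionMagnification, 1)
    slab[, , k] <- acquireAbsorbance(ph, b, cfg, kern, nm,
                                     seedSample = seed * 100 + k,
                                     seedBackground = seed * 100 + k + 10)
  }
  list(cube = HyperCube(slab, SpectralAxis(c(1213, 1658)), 1),
       truthMask = classMap(ph) == sceneTruth(ph)$inclusionLabel)
}
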