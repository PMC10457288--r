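# Acquisition-chain simulator: point-scan raster with bidirectional lines,
# band-dependent noise, coaddition buffering, background referencing and
# absorbance conversion, plus a widefield coherent comparator.
#
# Modelling conventions: the transflection double pass is absorbed into the
# scene's ground-truth absorbance (no separate x2 path factor); noise is a
# multiplicative (laser/shot) term N(1, sigma(nu)) plus an additive detector
# floor, one laser shot per pixel — pulse-level timing is not simulated.

#' Band-dependent relative noise magnitude
#'
#' Baseline relative noise, amplified toward the detector cutoff on the
#' low-wavenumber side (quadratic roll-off, exactly the baseline beyond
#' `cutoffCm1 + cutoffRolloffCm1`), plus triangular excess within
#' +/- 10 cm^-1 of each laser module-transition band.
#'
#' @param model a [NoiseModel()].
#' @param bandCm1 wavenumber(s), > 0.
#' @return relative sigma (fraction), vectorized over `bandCm1`.
#' @examples
#' nm <- NoiseModel()
#' sigmaAt(nm, c(850, 1030, 1450))
#' @export
sigmaAt <- function(model, bandCm1) {
  stopifnot(is(model, "NoiseModel"))
  if (any(bandCm1 <= 0)) stop("'bandCm1' must be > 0")
  above <- pmax(bandCm1 - model@cutoffCm1, 0)
  g <- 1 + (model@cutoffScale - 1) *
    pmax(1 - above / model@cutoffRolloffCm1, 0)^2
  sig <- model@baseRelSigma * g
  for (tb in model@transitionBandsCm1) {
    w <- pmax(1 - abs(bandCm1 - tb) / 10, 0)
    sig <- sig + model@transitionRelSigma * w
  }
  sig
}

# reflectance of a scene band under transflection Beer-Lambert
.sceneReflectance <- function(scene, bandCm1, tolCm1 = 4) {
  i <- which.min(abs(scene@axis@bands - bandCm1))
  if (abs(scene@axis@bands[i] - bandCm1) > tolCm1)
    stop(sprintf("scene has no band within %g cm-1 of %g (nearest: %g)",
                 tolCm1, bandCm1, scene@axis@bands[i]))
  10^(-scene@absorbance[, , i])
}

#' Acquire one raster frame from a scene
#'
#' Image formation: scene reflectance `10^(-A)` convolved with the effective
#' PSF, sampled on the scene grid.  The raster is bidirectional: odd lines
#' (0-based; rows 2, 4, ... in R's 1-based indexing) are acquired on the
#' return sweep and shifted by `lineOffsetPx` when the forward/reverse
#' alignment is imperfect.  Per-pixel noise is multiplicative
#' `N(1, sigma(nu))` plus additive `N(0, additiveSigma)`.
#'
#' @param scene a [Scene()].
#' @param bandCm1 wavenumber to acquire (must match a scene band within
#'   4 cm^-1).
#' @param cfg an [InstrumentConfig()]; its name and pixel size go into the
#'   frame's state token.
#' @param psfKernel a `PSFKernel` sampled at the scene pixel size, or `NULL`
#'   for an ideal delta PSF.
#' @param noise a [NoiseModel()] or `NULL` for noiseless acquisition.
#' @param lineOffsetPx forward/reverse line misregistration in pixels.
#' @param seed RNG seed; the session RNG is left untouched.
#' @return a [Frame()] of detector intensities.
#' @examples
#' sc <- makeSiemensStar(36, 128, 2)
#' fr <- acquireFrame(sc, 1658, instrumentPreset("lsm10x"))
#' @export
acquireFrame <- function(scene, bandCm1, cfg, psfKernel = NULL, noise = NULL,
                         lineOffsetPx = 0, seed = NULL) {
  stopifnot(is(scene, "Scene"), is(cfg, "InstrumentConfig"))
  refl <- .sceneReflectance(scene, bandCm1)
  if (!is.null(psfKernel)) {
    stopifnot(is(psfKernel, "PSFKernel"))
    if (abs(psfKernel@pixelSizeUm - scene@pixelSizeUm) > 1e-9)
      stop(sprintf("PSF sampling (%g um) does not match the scene (%g um)",
                   psfKernel@pixelSizeUm, scene@pixelSizeUm))
    refl <- convolve2d(refl, psfKernel@samples)
  }
  if (lineOffsetPx != 0) {
    rev_ <- seq(2L, nrow(refl), by = 2L)      # 0-based odd lines
    for (r in rev_) refl[r, ] <- shiftVector(refl[r, ], lineOffsetPx)
  }
  data <- withSeed(seed, {
    if (is.null(noise)) refl
    else {
      sig <- sigmaAt(noise, bandCm1)
      refl * stats::rnorm(length(refl), 1, sig) +
        stats::rnorm(length(refl), 0, noise@additiveSigma)
    }
  })
  Frame(matrix(data, nrow(refl), ncol(refl)), bandCm1 = bandCm1,
        configName = cfg@name, lineOffsetPx = lineOffsetPx)
}

#' Estimate and cancel bidirectional line misregistration
#'
#' The offset between forward (even, 0-based) and reverse (odd) line sets is
#' estimated by cross-correlating each reverse line against the mean of its
#' adjacent forward lines over integer lags, refined to subpixel precision
#' by parabolic interpolation of the correlation peak, and cancelled by
#' resampling the reverse lines.  On a featureless frame (correlation peak
#' below `minPeak`) the offset defaults to 0 with a low-confidence flag.
#'
#' @param frame a [Frame()] with at least 4 lines.
#' @param maxLagPx largest integer lag searched.
#' @param minPeak minimum normalized correlation at the peak to trust the
#'   estimate.
#' @return list with `frame` (corrected [Frame()]), `offsetPx` (estimate)
#'   and `confident` (logical).
#' @export
alignBidirectional <- function(frame, maxLagPx = 8L, minPeak = 0.2) {
  stopifnot(is(frame, "Frame"))
  img <- frame@data
  if (nrow(img) < 4L) stop("frame must have at least 4 lines")
  odd <- seq(2L, nrow(img), by = 2L)
  lags <- -maxLagPx:maxLagPx
  nc <- ncol(img)
  score <- numeric(length(lags))
  weight <- 0
  for (r in odd) {
    nb <- c(r - 1L, if (r + 1L <= nrow(img)) r + 1L)
    ref <- colMeans(img[nb, , drop = FALSE])
    ref <- ref - mean(ref)
    row <- img[r, ] - mean(img[r, ])
    for (k in seq_along(lags)) {
      d <- lags[k]
      if (d >= 0) { a <- ref[seq_len(nc - d)]; b <- row[d + seq_len(nc - d)] }
      else { a <- ref[-d + seq_len(nc + d)]; b <- row[seq_len(nc + d)] }
      score[k] <- score[k] + sum(a * b)
    }
    weight <- weight + sum(ref^2) + sum(row^2)
  }
  norm <- score / (weight / 2 + .Machine$double.eps)
  kmax <- which.max(norm)
  confident <- norm[kmax] >= minPeak
  offset <- 0
  if (confident) {
    # subpixel refinement: maximize the normalized correlation between the
    # reverse line shifted by -d/2 and its forward-line reference shifted by
    # +d/2.  Shifts use the unitary Fourier operator, whose magnitude
    # response is flat, so the objective carries no resampling-attenuation
    # reward (an interpolating shift would bias the peak toward half-sample
    # positions); the split keeps any residual phase effects symmetric.
    interior <- (maxLagPx + 3L):(nc - maxLagPx - 2L)
    ncc <- function(d) {
      s <- 0
      for (r in odd) {
        nb <- c(r - 1L, if (r + 1L <= nrow(img)) r + 1L)
        ref <- colMeans(img[nb, , drop = FALSE])
        a <- fourierShiftVector(ref - mean(ref), d / 2)[interior]
        a <- a - mean(a)
        b <- fourierShiftVector(img[r, ] - mean(img[r, ]), -d / 2)[interior]
        b <- b - mean(b)
        s <- s + sum(a * b) / sqrt(sum(a^2) * sum(b^2) +
                                     .Machine$double.eps)
      }
      s
    }
    offset <- stats::optimize(ncc, lags[kmax] + c(-1, 1), maximum = TRUE,
                              tol = 1e-4)$maximum
  }
  out <- img
  if (offset != 0)
    for (r in odd) out[r, ] <- shiftVector(img[r, ], -offset)
  corrected <- frame
  corrected@data <- out
  corrected@lineOffsetPx <- 0
  list(frame = corrected, offsetPx = offset, confident = confident)
}

#' Push a frame into the coaddition buffer and read the co-averaged image
#'
#' The displayed image is the pixelwise mean of the `n` most recent frames
#' sharing the incoming frame's acquisition-state token; a state change
#' (band, configuration or shape) flushes the buffer first so frames from
#' different states are never blended.
#'
#' @param buf a [FrameBuffer()].
#' @param frame the newly acquired [Frame()].
#' @param n coadditions requested; must not exceed the buffer capacity.
#'   Fewer stored frames than `n` average over what is available.
#' @return list with `buffer` (updated [FrameBuffer()]) and `frame` (the
#'   co-averaged [Frame()], `coadditions` set to the number actually used).
#' @export
pushAndAverage <- function(buf, frame, n = 1L) {
  stopifnot(is(buf, "FrameBuffer"), is(frame, "Frame"))
  if (n > buf@capacity)
    stop(sprintf("n = %d exceeds buffer capacity %d", n, buf@capacity))
  if (n < 1L) stop("'n' must be >= 1")
  if (!identical(buf@stateToken, frame@stateToken)) buf@frames <- list()
  buf@stateToken <- frame@stateToken
  buf@frames <- c(buf@frames, list(frame@data))
  if (length(buf@frames) > buf@capacity)
    buf@frames <- buf@frames[seq.int(length(buf@frames) - buf@capacity + 1L,
                                     length(buf@frames))]
  use <- min(n, length(buf@frames))
  idx <- seq.int(length(buf@frames) - use + 1L, length(buf@frames))
  avg <- Reduce(`+`, buf@frames[idx]) / use
  out <- frame
  out@data <- avg
  out@coadditions <- as.integer(use)
  list(buffer = buf, frame = out)
}

#' Convert referenced intensities to absorbance
#'
#' `A = -log10(sample / background)` with the ratio floored at `floorRatio`
#' before the logarithm.  Fixed-pattern gain present in both frames cancels
#' exactly; this is the purpose of measuring the spectral background on a
#' blank substrate.
#'
#' @param sample,background [Frame()]s (or matrices) of matching shape; for
#'   frames the bands must agree.
#' @param floorRatio lower floor on the intensity ratio (flagged in the
#'   provenance attribute `flooredPx` of the result).
#' @return object of the same type as `sample` holding absorbance (a.u.).
#' @examples
#' toAbsorbance(matrix(0.1, 2, 2), matrix(1, 2, 2))   # 1.0 everywhere
#' @export
toAbsorbance <- function(sample, background, floorRatio = 1e-6) {
  sFrame <- is(sample, "Frame")
  s <- if (sFrame) sample@data else sample
  b <- if (is(background, "Frame")) background@data else background
  if (!identical(dim(s), dim(b))) stop("sample/background shapes differ")
  if (sFrame && is(background, "Frame") &&
      abs(sample@bandCm1 - background@bandCm1) > 1e-9)
    stop("sample and background bands differ")
  if (all(b == 0)) stop("background is identically zero")
  ratio <- s / b
  floored <- sum(!is.finite(ratio) | ratio < floorRatio)
  ratio[!is.finite(ratio) | ratio < floorRatio] <- floorRatio
  A <- -log10(ratio)
  if (sFrame) {
    out <- sample
    out@data <- A
    attr(out@data, "flooredPx") <- floored
    out
  } else {
    attr(A, "flooredPx") <- floored
    A
  }
}

#' Widefield coherent comparator image
#'
#' Simulates widefield laser illumination of an optically rough sample: the
#' coherent field is the square-root reflectance with a per-pixel random
#' phase `4 pi h / lambda` from a Gaussian surface-height roughness `h`,
#' low-pass filtered by the coherent pupil (cutoff `NA / lambda`); the
#' returned image is the squared field magnitude.  For roughness much larger
#' than the wavelength the phases are effectively uniform and the image
#' shows fully developed speckle (contrast ~ 1); zero roughness gives a
#' speckle-free image.
#'
#' @param scene a [Scene()].
#' @param bandCm1 wavenumber to image.
#' @param pupil a [PupilSpec()] for the widefield system.
#' @param roughnessUm RMS surface height in micrometres.
#' @param seed RNG seed.
#' @return intensity matrix (arbitrary units).
#' @examples
#' sc <- makeTissuePhantom(64, 2, defaultSpectralLibrary(),
#'                         SpectralAxis(c(1079, 1658)), seed = 1)
#' img <- simulateWidefieldCoherent(sc, 1658, PupilSpec(0.62, 1658), seed = 2)
#' @export
simulateWidefieldCoherent <- function(scene, bandCm1, pupil,
                                      roughnessUm = 10, seed = NULL) {
  stopifnot(is(scene, "Scene"), is(pupil, "PupilSpec"))
  refl <- .sceneReflectance(scene, bandCm1)
  lambda <- wavenumberToWavelengthUm(pupil@wavenumberCm1)
  fcut <- pupil@na / lambda
  withSeed(seed, {
    h <- matrix(stats::rnorm(length(refl), 0, roughnessUm),
                nrow(refl), ncol(refl))
    field <- sqrt(refl) * exp(1i * 4 * pi * h / lambda)
    nr <- nrow(field); nc <- ncol(field)
    fy <- stats::fft(field)
    fr <- outer((c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / (nr * scene@pixelSizeUm))^2,
                (c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / (nc * scene@pixelSizeUm))^2,
                "+")
    mask <- sqrt(fr) <= fcut
    filt <- stats::fft(fy * mask, inverse = TRUE) / length(fy)
    Mod(filt)^2
  })
}

#' Point spectrum at one pixel
#'
#' Sweeps all axis bands at a single pixel: per band the scene is blurred by
#' the band's PSF (optional), band-dependent noise is applied to both the
#' sample and a blank-substrate background shot, and the referenced
#' absorbance is returned.
#'
#' @param scene a [Scene()].
#' @param cfg an [InstrumentConfig()].
#' @param locationPx length-2 (row, col) pixel inside the field of view.
#' @param psfs optional list of `PSFKernel`s, one per axis band.
#' @param noise a [NoiseModel()] or `NULL`.
#' @param seed RNG seed.
#' @return numeric absorbance spectrum with the axis bands as names.
#' @export
pointSpectrum <- function(scene, cfg, locationPx, psfs = NULL, noise = NULL,
                          seed = NULL) {
  stopifnot(is(scene, "Scene"))
  d <- dim(scene@absorbance)
  r <- locationPx[1]; c_ <- locationPx[2]
  if (r < 1 || r > d[1] || c_ < 1 || c_ > d[2])
    stop(sprintf("location (%g, %g) is outside the %d x %d field of view",
                 r, c_, d[1], d[2]))
  nb <- length(scene@axis@bands)
  if (!is.null(psfs) && length(psfs) != nb)
    stop("'psfs' must provide one kernel per band")
  withSeed(seed, {
    out <- numeric(nb)
    for (b in seq_len(nb)) {
      refl <- 10^(-scene@absorbance[, , b])
      if (!is.null(psfs)) refl <- convolve2d(refl, psfs[[b]]@samples)
      v <- refl[r, c_]
      bg <- 1
      if (!is.null(noise)) {
        sig <- sigmaAt(noise, scene@axis@bands[b])
        v <- v * stats::rnorm(1, 1, sig) + stats::rnorm(1, 0, noise@additiveSigma)
        bg <- bg * stats::rnorm(1, 1, sig) + stats::rnorm(1, 0, noise@additiveSigma)
      }
      out[b] <- -log10(max(v / bg, 1e-6))
    }
    names(out) <- scene@axis@bands
    out
  })
}
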