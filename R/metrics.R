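# Instrument-evaluation machinery: 100% lines, spatial/spectral noise, SNR,
# slant-edge MTF (ISO 12233 dialect), Siemens-star resolution and speckle
# contrast.
#
# The slant-edge dialect: centroid edge detection per row, 4x oversampled
# ESF binning, discrete-derivative LSF with a Hamming window, |DFT|
# normalization at zero frequency, and compensation of the bin/derivative
# sampling response.  All of these are exposed as arguments.

#' 100 percent line and its RMS
#'
#' The ratio spectrum of two successive background measurements,
#' `A(nu) = -log10(bgA / bgB)`; ideally zero at every band, its RMS over a
#' spectral window quantifies spectral noise.  The default window
#' (1300-1700 cm^-1) avoids the detector cutoff and laser-transition
#' regions.
#'
#' @param bgA,bgB positive intensity spectra on the same axis.
#' @param axis a [SpectralAxis()] (or numeric band vector) for windowing.
#' @param windowCm1 length-2 window over which the RMS is computed; bands
#'   outside every window fall back to the full axis.
#' @return list with `absorbance` (the 100 percent line, a.u.) and `rms`.
#' @examples
#' b <- rep(1, 100)
#' hundredPercentLine(b, b, SpectralAxis(seq(801, 1900, length.out = 100)))$rms
#' @export
hundredPercentLine <- function(bgA, bgB, axis = NULL,
                               windowCm1 = c(1300, 1700)) {
  if (length(bgA) != length(bgB)) stop("spectra lengths differ")
  if (any(bgA <= 0) || any(bgB <= 0)) stop("intensities must be positive")
  A <- -log10(bgA / bgB)
  nu <- if (is(axis, "SpectralAxis")) axis@bands else axis
  sel <- rep(TRUE, length(A))
  if (!is.null(nu)) {
    sel <- nu >= windowCm1[1] & nu <= windowCm1[2]
    if (!any(sel)) sel <- rep(TRUE, length(A))
  }
  list(absorbance = A, rms = sqrt(mean(A[sel]^2)))
}

#' Spatial noise from a pair of blank frames
#'
#' The pixelwise standard deviation of `(frameA - frameB) / sqrt(2)`;
#' differencing removes fixed-pattern structure so only stochastic noise
#' remains, and the sqrt(2) undoes the variance doubling.
#'
#' @param frameA,frameB same-band absorbance matrices (or [Frame()]s) of a
#'   blank region.
#' @return noise estimate (a.u.).
#' @export
spatialNoise <- function(frameA, frameB) {
  a <- if (is(frameA, "Frame")) frameA@data else frameA
  b <- if (is(frameB, "Frame")) frameB@data else frameB
  if (!identical(dim(a), dim(b))) stop("frame shapes differ")
  stats::sd((a - b) / sqrt(2))
}

#' Signal-to-noise ratio
#'
#' `signal / noise` with the package's convention: signal is the peak-band
#' absorbance of a reference film and noise the 100-percent-line RMS at the
#' same band.  A per-band spatial-noise denominator can be used instead by
#' passing that estimate — the formula is the plain ratio either way.
#'
#' @param signalAbsorbance peak signal absorbance (a.u.).
#' @param noiseRms noise RMS (a.u.), > 0.
#' @return dimensionless ratio.
#' @examples
#' snr(0.5, 0.005)   # 100
#' @export
snr <- function(signalAbsorbance, noiseRms) {
  if (any(noiseRms == 0)) stop("noise must be > 0")
  signalAbsorbance / noiseRms
}

#' Slant-edge MTF estimate (ISO 12233 dialect)
#'
#' Locates the edge per row by the centroid of the line derivative, fits a
#' straight line to get the slant, projects every pixel onto the edge
#' normal into an oversampled edge-spread function, differentiates to the
#' line-spread function, applies a Hamming window, and reports the
#' normalized DFT magnitude in cycles per micrometre.  The known transfer
#' of the ESF binning and the discrete derivative is divided out when
#' `correctSampling` is `TRUE`.
#'
#' Near-horizontal edges are handled by transposing the image first, which
#' makes the estimate invariant to 90-degree rotation.
#'
#' @param image matrix containing one straight near-vertical or
#'   near-horizontal edge.
#' @param pixelSizeUm sampling.
#' @param oversampling ESF bins per pixel (>= 4).
#' @param windowFun `"hamming"` or `"none"`.
#' @param correctSampling divide out the bin/derivative sinc response.
#' @param maxFreqCycPerPx highest reported frequency in cycles per pixel.
#' @param slantRangeDeg acceptable absolute slant range; outside it the
#'   call fails with a diagnostic.
#' @return an `EdgeAnalysis`.
#' @examples
#' sc <- makeSlantEdge(5, 128, 2, antialias = TRUE)
#' ea <- slantEdgeMtf(sceneMap(sc, 1658), 2)
#' @export
slantEdgeMtf <- function(image, pixelSizeUm = 1, oversampling = 4L,
                         windowFun = c("hamming", "none"),
                         correctSampling = TRUE, maxFreqCycPerPx = 1,
                         slantRangeDeg = c(1, 14)) {
  windowFun <- match.arg(windowFun)
  oversampling <- as.integer(oversampling)
  if (oversampling < 4L) stop("'oversampling' must be >= 4")
  # orient the edge near-vertical: value transitions along rows
  rowVar <- sum(abs(diff(t(image))))   # variation along each row
  colVar <- sum(abs(diff(image)))      # variation down each column
  if (colVar > rowVar) image <- t(image)
  nr <- nrow(image); nc <- ncol(image)
  centroid <- rep(NA_real_, nr)
  for (r in seq_len(nr)) {
    dv <- diff(image[r, ])
    if (max(abs(dv)) < 1e-12) next
    i0 <- which.max(abs(dv))
    win <- max(1L, i0 - 15L):min(length(dv), i0 + 15L)
    w <- abs(dv[win])
    centroid[r] <- sum((win + 0.5) * w) / sum(w)
  }
  ok <- which(is.finite(centroid))
  if (length(ok) < 4L) stop("no edge found: too few rows with a transition")
  fit <- stats::lm.fit(cbind(1, ok), centroid[ok])
  slope <- fit$coefficients[2]
  angle <- atan(slope) * 180 / pi
  if (abs(angle) < slantRangeDeg[1] || abs(angle) > slantRangeDeg[2])
    stop(sprintf("edge slant %.2f deg outside the usable range [%g, %g]",
                 abs(angle), slantRangeDeg[1], slantRangeDeg[2]))
  cosTh <- 1 / sqrt(1 + slope^2)
  # normal distance of every pixel from the fitted edge, in pixels
  rr <- as.vector(row(image)); cc <- as.vector(col(image))
  t_ <- (cc - fit$coefficients[1] - slope * rr) * cosTh
  binW <- 1 / oversampling
  halfWidthPx <- min(20, (nc - 4) / 2)
  keep <- abs(t_) <= halfWidthPx
  bin <- floor((t_[keep] + halfWidthPx) / binW) + 1L
  nb <- as.integer(ceiling(2 * halfWidthPx / binW))
  esf <- rep(NA_real_, nb)
  sums <- tapply(as.vector(image)[keep], bin, mean)
  esf[as.integer(names(sums))] <- sums
  if (anyNA(esf)) {    # fill empty bins by linear interpolation
    idx <- which(is.finite(esf))
    esf <- stats::approx(idx, esf[idx], xout = seq_len(nb), rule = 2)$y
  }
  lsf <- c(0, (esf[-1] - esf[-length(esf)]))   # two-tap derivative
  ctr <- sum(seq_along(lsf) * abs(lsf)) / sum(abs(lsf))
  if (windowFun == "hamming") {
    # Hamming taper centred on the LSF centroid, stretched to twice the
    # record length: suppresses ESF end noise while keeping the window
    # nearly flat over a compact LSF (small multiplicative bias)
    n <- length(lsf)
    w <- 0.54 + 0.46 * cos(pi * (seq_len(n) - ctr) / n)
    lsf <- lsf * w
  }
  N <- length(lsf)
  spec <- Mod(stats::fft(lsf))
  freqPx <- (seq_len(N) - 1) / (N * binW)      # cycles per pixel
  keepF <- freqPx <= maxFreqCycPerPx
  m <- spec[keepF] / spec[1]
  f <- freqPx[keepF]
  if (correctSampling) {
    corr <- sinc(f * binW)^2                   # bin box x derivative response
    m <- m / pmax(corr, 0.2)
  }
  curve <- MTFCurve(f / pixelSizeUm, m / m[1],
                    meta = list(estimator = "slant-edge ISO 12233",
                                angleDeg = angle,
                                oversampling = oversampling,
                                window = windowFun))
  new("EdgeAnalysis", edgeAngleDeg = as.numeric(angle), esf = esf, lsf = lsf,
      mtf = curve, oversampling = oversampling)
}

#' Interpolate an MTF curve at given frequencies
#'
#' @param curve an [MTFCurve()] or `EdgeAnalysis`.
#' @param freq frequencies in cycles per micrometre.
#' @return modulation values (0 beyond the sampled range).
#' @export
mtfAt <- function(curve, freq) {
  if (is(curve, "EdgeAnalysis")) curve <- curve@mtf
  stopifnot(is(curve, "MTFCurve"))
  stats::approx(curve@freqCycPerUm, curve@modulation, xout = freq,
                yleft = 1, yright = 0)$y
}

#' Frequency at which an MTF curve crosses a modulation threshold
#'
#' @param curve an [MTFCurve()] or `EdgeAnalysis`.
#' @param threshold modulation level (default 0.25, the common
#'   approximation of the Rayleigh criterion).
#' @return frequency in cycles per micrometre (linear interpolation).
#' @export
mtfCrossing <- function(curve, threshold = 0.25) {
  if (is(curve, "EdgeAnalysis")) curve <- curve@mtf
  f <- curve@freqCycPerUm; m <- curve@modulation
  below <- which(m < threshold)
  below <- below[below > 1]
  if (!length(below)) return(max(f))
  i <- below[1]
  f[i - 1] + (m[i - 1] - threshold) / (m[i - 1] - m[i]) * (f[i] - f[i - 1])
}

#' Limiting resolution from a Siemens-star image
#'
#' Samples concentric rings of the star (bilinear interpolation, 720
#' angular samples per ring), extracts the modulation at the known spoke
#' frequency by least-squares sinusoid fit, normalizes the square-wave
#' fundamental (factor pi/4) so an unblurred star reads 1.0, and walks
#' inward from the outermost ring to the innermost ring frequency at which
#' the modulation still meets the threshold.  The reported limiting
#' frequency interpolates the threshold crossing on the truth mapping
#' `f = nSpokes / (2 pi r)`.
#'
#' @param image star image (same grid as the generating scene).
#' @param truth the star scene (or its `sceneTruth()` list).
#' @param threshold modulation threshold (0.25 approximates the Rayleigh
#'   criterion).
#' @param pixelSizeUm sampling.
#' @param nAngles angular samples per ring.
#' @return list with `limitFreqCycPerUm`, and the per-ring `freq` and
#'   `modulation` profile.
#' @export
starResolution <- function(image, truth, threshold = 0.25, pixelSizeUm = 1,
                           nAngles = 720L) {
  tr <- if (is(truth, "Scene")) truth@truth else truth
  if (is.null(tr$nSpokes)) stop("'truth' does not describe a Siemens star")
  ctr <- tr$centerPx
  if (ctr[1] < 1 || ctr[1] > nrow(image) || ctr[2] < 1 || ctr[2] > ncol(image))
    stop("star centre lies outside the image")
  n <- tr$nSpokes
  maxRpx <- min(ctr[1] - 1, nrow(image) - ctr[1],
                ctr[2] - 1, ncol(image) - ctr[2]) - 2
  # innermost usable ring: circumferential frequency at the sampling Nyquist
  minRpx <- max(n / (2 * pi * 0.5), 4)
  if (maxRpx <= minRpx) stop("image too small for this spoke count")
  radiiPx <- seq(maxRpx, minRpx, by = -1)
  th <- 2 * pi * (seq_len(nAngles) - 1) / nAngles
  basis <- exp(-1i * n * th)
  freq <- mod <- numeric(length(radiiPx))
  for (i in seq_along(radiiPx)) {
    r <- radiiPx[i]
    v <- bilinearSample(image, ctr[1] + r * sin(th), ctr[2] + r * cos(th))
    amp <- 2 * Mod(mean(v * basis))
    mod[i] <- (pi / 4) * amp / mean(v)
    freq[i] <- n / (2 * pi * r * pixelSizeUm)
  }
  fail <- which(mod < threshold)
  limit <- if (!length(fail)) max(freq) else {
    i <- fail[1]
    if (i == 1) freq[1] else
      freq[i - 1] + (mod[i - 1] - threshold) / (mod[i - 1] - mod[i]) *
        (freq[i] - freq[i - 1])
  }
  list(limitFreqCycPerUm = limit, freq = freq, modulation = mod,
       threshold = threshold)
}

#' Speckle contrast of a nominally uniform region
#'
#' `sd / mean` over the masked pixels: ~1 for fully developed coherent
#' speckle, ~the relative noise floor for incoherent point-scan images.
#'
#' @param image intensity matrix.
#' @param mask logical matrix selecting a uniform region (default: all
#'   pixels).  Fewer than 1000 selected pixels draw a warning.
#' @return dimensionless contrast.
#' @export
speckleContrast <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("mask selects no pixels")
  v <- image[mask]
  if (length(v) < 1000)
    warning("fewer than 1000 pixels in the mask; contrast estimate is noisy")
  stats::sd(v) / mean(v)
}
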