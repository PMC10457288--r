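# Scalar Fourier optics for clear, annular and half-blocked circular pupils.
#
# The point-scan detection path is modeled as incoherent in intensity (the
# pinhole-integrated signal is recorded pixel by pixel), so the PSF is the
# squared modulus of the pupil's Fourier transform and the MTF its
# autocorrelation.  Coherence is modeled only in the widefield comparator
# (see simulateWidefieldCoherent).

# first zero of J1, located numerically once
.j1FirstZero <- function() {
  stats::uniroot(function(x) besselJ(x, 1), c(3, 4.5), tol = 1e-13)$root
}

#' Radius of the first dark ring of the focal spot
#'
#' For a clear circular pupil the first intensity null of the focal spot lies
#' at `x1 / (2 pi) * lambda / NA` where `x1` is the first zero of the Bessel
#' function J1 (the familiar 0.61 lambda/NA).  The zero is located
#' numerically rather than taken from the rounded constant.
#'
#' @param pupil a [PupilSpec()] with zero obscuration (an annular pupil
#'   shifts the nulls and is rejected).
#' @return radius in micrometres.
#' @examples
#' airyFirstZeroRadius(PupilSpec(0.4, 1658))   # ~9.2 um
#' @export
airyFirstZeroRadius <- function(pupil) {
  stopifnot(is(pupil, "PupilSpec"))
  if (pupil@obscuration > 0)
    stop("first-zero radius is only defined here for a clear pupil ",
         "(obscuration shifts the nulls)")
  lambda <- wavenumberToWavelengthUm(pupil@wavenumberCm1)
  .j1FirstZero() / (2 * pi) * lambda / pupil@na
}

# Focal amplitude of a (possibly annular) radially symmetric pupil:
# the Fourier transform of a disc of radius a is a J1(2 pi a r)/r, so the
# annulus is the difference of two discs.  fc = NA/lambda is the coherent
# cutoff in cycles/um.
.radialAmplitude <- function(r, fc, eps) {
  out <- numeric(length(r))
  z <- r == 0
  out[z] <- pi * fc^2 * (1 - eps^2)
  rn <- r[!z]
  a <- fc * besselJ(2 * pi * fc * rn, 1) / rn
  if (eps > 0) a <- a - eps * fc * besselJ(2 * pi * eps * fc * rn, 1) / rn
  out[!z] <- a
  out
}

# Anti-aliased pupil mask on a K x K midpoint grid over [-1, 1]^2 in units of
# the pupil radius; each sample holds the approximate covered area fraction.
.pupilMask <- function(eps, blockFraction, K) {
  du <- 2 / K
  u <- -1 + (seq_len(K) - 0.5) * du
  U <- matrix(u, K, K, byrow = TRUE)   # columns vary along u (x direction)
  V <- matrix(u, K, K)                 # rows along v (y direction)
  rho <- sqrt(U^2 + V^2)
  cov <- pmin(pmax(0.5 + (1 - rho) / du, 0), 1)
  if (eps > 0)
    cov <- cov * pmin(pmax(0.5 + (rho - eps) / du, 0), 1)
  if (blockFraction > 0) {
    u0 <- .blockEdge(eps, blockFraction)
    cov <- cov * pmin(pmax(0.5 + (u0 - U) / du, 0), 1)
  }
  list(mask = cov, u = u, du = du)
}

# Position of the half-plane block edge such that the stated fraction of the
# (annular) pupil area lies beyond it.
.blockEdge <- function(eps, fraction) {
  seg <- function(a, x) {                       # area of {u > x} within disc radius a
    if (a <= 0) return(0)
    x <- max(min(x, a), -a)
    a^2 * acos(x / a) - x * sqrt(max(a^2 - x^2, 0))
  }
  total <- pi * (1 - eps^2)
  f <- function(x) (seg(1, x) - seg(eps, x)) / total - fraction
  stats::uniroot(f, c(-1, 1), tol = 1e-12)$root
}

#' Diffraction-limited intensity point-spread function
#'
#' Computes the incoherent intensity PSF of the pupil on a pixel grid and
#' normalizes it to unit sum.  Radially symmetric pupils (clear or annular)
#' use the closed-form Bessel amplitude; a pupil with a fold-mirror
#' half-plane block is evaluated by direct numerical Fourier transform of an
#' anti-aliased pupil mask.
#'
#' The support is auto-sized to +/- 18 first-zero radii when not given
#' (wider for obscured or blocked pupils), and the
#' energy captured inside the support is checked against the pupil-area
#' (Parseval) total: below 99 percent the call fails naming the required
#' support.
#'
#' @param pupil a [PupilSpec()].
#' @param pixelSizeUm grid sampling in micrometres per pixel.
#' @param supportPx odd kernel edge length in pixels; `NULL` auto-sizes.
#' @param pupilGridN mask resolution for the asymmetric path.
#' @return a `PSFKernel` normalized to unit sum.
#' @examples
#' k <- psf(PupilSpec(0.4, 1658), pixelSizeUm = 2)
#' sum(psfSamples(k))
#' @export
psf <- function(pupil, pixelSizeUm, supportPx = NULL, pupilGridN = 400L) {
  stopifnot(is(pupil, "PupilSpec"))
  stopifnotScalar(pixelSizeUm, "pixelSizeUm", 0, openLower = TRUE)
  lambda <- wavenumberToWavelengthUm(pupil@wavenumberCm1)
  fc <- pupil@na / lambda
  r1 <- .j1FirstZero() / (2 * pi) / fc
  if (is.null(supportPx)) {
    # +/- 18 first-zero radii captures > 99% of the Airy energy; annular
    # pupils push energy into the sidelobes, so widen accordingly
    supportPx <- ceiling(36 * r1 / pixelSizeUm /
      ((1 - pupil@obscuration) * (1 - pupil@illuminationPupilFraction)))
    if (supportPx %% 2L == 0L) supportPx <- supportPx + 1L
  }
  supportPx <- as.integer(supportPx)
  if (supportPx < 3L || supportPx %% 2L == 0L)
    stop("'supportPx' must be an odd integer >= 3")
  h <- supportPx %/% 2L
  x <- (-h:h) * pixelSizeUm
  if (pupil@illuminationPupilFraction == 0) {
    r <- sqrt(outer(x^2, x^2, "+"))
    ru <- sort(unique(as.vector(r)))
    amp <- .radialAmplitude(ru, fc, pupil@obscuration)
    I <- matrix(amp[match(as.vector(r), ru)]^2, supportPx, supportPx)
  } else {
    pm <- .pupilMask(pupil@obscuration, pupil@illuminationPupilFraction,
                     as.integer(pupilGridN))
    # separable direct DFT: U(y, x) = Ev^T M Eu with midpoint weights;
    # mask rows index v, columns index u, and the sample grid is shared
    phase <- outer(pm$u * fc, x)             # K x S
    E <- exp(2i * pi * phase) * pm$du * fc
    U <- t(E) %*% pm$mask %*% E              # S x S focal amplitude
    I <- Mod(U)^2
  }
  area <- pi * fc^2 * (1 - pupil@obscuration^2) *
    (1 - pupil@illuminationPupilFraction)
  captured <- sum(I) * pixelSizeUm^2 / area
  if (captured < 0.99) {
    need <- ceiling(36 * r1 / pixelSizeUm /
      ((1 - pupil@obscuration) * (1 - pupil@illuminationPupilFraction)))
    if (need %% 2L == 0L) need <- need + 1L
    stop(sprintf("support %d px captures only %.1f%% of the PSF energy; use supportPx >= %d",
                 supportPx, 100 * captured, max(need, supportPx * 2L + 1L)))
  }
  new("PSFKernel", samples = I / sum(I), pixelSizeUm = pixelSizeUm,
      normalization = "sum-to-one")
}

# Autocorrelation-based MTF of an anti-aliased pupil mask.  Returns the
# normalized modulation sampled on the displacement grid (in pupil-radius
# units) along both axes.
.maskAutocorrSlices <- function(mask, du) {
  K <- nrow(mask)
  N <- stats::nextn(2L * K, c(2, 3, 5))
  P <- padZero(mask, c(N, N))
  A <- Re(stats::fft(Mod(stats::fft(P))^2, inverse = TRUE)) / (N * N)
  # A[1,1] is zero displacement; displacement d along an axis = (k-1) * du
  horiz <- A[1, seq_len(K)]       # shifts along columns (u / x direction)
  vert  <- A[seq_len(K), 1]       # shifts along rows    (v / y direction)
  list(d = (seq_len(K) - 1) * du, horizontal = horiz / A[1, 1],
       vertical = vert / A[1, 1])
}

#' Modulation transfer function of a pupil
#'
#' Incoherent OTF magnitude computed as the normalized autocorrelation of an
#' anti-aliased pupil mask, with cutoff `2 NA / lambda`.  With a fold-mirror
#' illumination block (`illuminationPupilFraction > 0`) the returned system
#' MTF is the product of the full collection-pupil MTF and the asymmetric
#' illumination-pupil MTF, which makes the curves direction dependent — the
#' behaviour seen in transflection measurements with reflective objectives.
#'
#' @param pupil a [PupilSpec()].
#' @param axis `"horizontal"` (frequency along x, across the block edge) or
#'   `"vertical"`.
#' @param freq optional frequency grid in cycles/um; default 257 points from
#'   0 to the cutoff.
#' @param gridN pupil mask resolution (accuracy/speed trade-off).
#' @return an [MTFCurve()].
#' @examples
#' m <- mtf(PupilSpec(0.4, 1658))
#' # analytic clear-pupil value at half cutoff is about 0.391
#' @export
mtf <- function(pupil, axis = c("horizontal", "vertical"), freq = NULL,
                gridN = 1024L) {
  stopifnot(is(pupil, "PupilSpec"))
  axis <- match.arg(axis)
  lambda <- wavenumberToWavelengthUm(pupil@wavenumberCm1)
  cutoff <- 2 * pupil@na / lambda
  if (is.null(freq)) freq <- seq(0, cutoff, length.out = 257L)
  if (any(freq < 0)) stop("frequencies must be >= 0")
  # displacement in pupil-radius units for frequency f: d = 2 f / cutoff
  dWanted <- 2 * freq / cutoff
  coll <- .pupilMask(pupil@obscuration, 0, as.integer(gridN))
  acColl <- .maskAutocorrSlices(coll$mask, coll$du)
  modColl <- stats::approx(acColl$d, acColl[[axis]], xout = pmin(dWanted, max(acColl$d)),
                           rule = 2)$y
  modColl[dWanted >= 2] <- 0
  modulation <- modColl
  if (pupil@illuminationPupilFraction > 0) {
    ill <- .pupilMask(pupil@obscuration, pupil@illuminationPupilFraction,
                      as.integer(gridN))
    acIll <- .maskAutocorrSlices(ill$mask, ill$du)
    modIll <- stats::approx(acIll$d, acIll[[axis]], xout = pmin(dWanted, max(acIll$d)),
                            rule = 2)$y
    modIll[dWanted >= 2] <- 0
    modulation <- modColl * modIll
  }
  modulation <- pmax(modulation, 0)
  if (freq[1] == 0) modulation[1] <- 1
  MTFCurve(freq, modulation,
           meta = list(estimator = "pupil-autocorrelation", axis = axis,
                       wavenumberCm1 = pupil@wavenumberCm1, na = pupil@na,
                       obscuration = pupil@obscuration,
                       illuminationPupilFraction = pupil@illuminationPupilFraction,
                       cutoffCycPerUm = cutoff))
}

#' Effective confocal point-spread function
#'
#' The effective PSF of a point-scanning confocal system with a finite
#' detection pinhole: illumination PSF times the detection PSF convolved
#' with the pinhole disc back-projected to the sample plane (diameter
#' `pinholeDiameterUm / detectionMagnification`).  A zero pinhole gives the
#' ideal pointwise product of the two single-path PSFs; an infinite pinhole
#' recovers the widefield illumination PSF.
#'
#' @param pupil a [PupilSpec()] shared by illumination and detection.
#' @param pinholeDiameterUm physical pinhole diameter (>= 0; `Inf` for a
#'   fully open pinhole).
#' @param detectionMagnification sample-to-pinhole magnification.
#' @param pixelSizeUm grid sampling.
#' @param supportPx odd kernel edge length; `NULL` auto-sizes.
#' @return a `PSFKernel` normalized to unit sum.
#' @examples
#' k <- confocalPsf(PupilSpec(0.4, 1658), 100, 5, pixelSizeUm = 2)
#' @export
confocalPsf <- function(pupil, pinholeDiameterUm, detectionMagnification,
                        pixelSizeUm, supportPx = NULL) {
  if (is.na(pinholeDiameterUm) || pinholeDiameterUm < 0)
    stop("'pinholeDiameterUm' must be >= 0")
  ill <- psf(pupil, pixelSizeUm, supportPx)
  det <- ill@samples                     # same pupil for both paths
  backR <- pinholeDiameterUm / detectionMagnification / 2
  S <- nrow(det)
  if (is.finite(backR) && backR > 0 && backR < S * pixelSizeUm) {
    rPx <- backR / pixelSizeUm
    hk <- ceiling(rPx) + 1L
    xx <- -hk:hk
    rho <- sqrt(outer(xx^2, xx^2, "+"))
    disc <- pmin(pmax(0.5 + (rPx - rho), 0), 1)   # anti-aliased pinhole disc
    disc <- disc / sum(disc)
    detEff <- convolve2d(det, disc)
  } else if (backR == 0) {
    detEff <- det
  } else {
    detEff <- matrix(1, S, S)            # fully open pinhole: no spatial filtering
  }
  eff <- ill@samples * detEff
  new("PSFKernel", samples = eff / sum(eff), pixelSizeUm = pixelSizeUm,
      normalization = "sum-to-one")
}

#' Full width at half maximum of a PSF
#'
#' Interpolated FWHM of the central row profile; used to compare confocal
#' and widefield resolution.
#'
#' @param kernel a `PSFKernel`.
#' @return FWHM in micrometres.
#' @export
psfFwhm <- function(kernel) {
  stopifnot(is(kernel, "PSFKernel"))
  s <- kernel@samples
  c0 <- (nrow(s) + 1L) %/% 2L
  prof <- s[c0, ]
  peak <- max(prof)
  half <- peak / 2
  i0 <- which.max(prof)
  right <- NA_real_
  for (i in i0:(length(prof) - 1L)) {
    if (prof[i] >= half && prof[i + 1L] < half) {
      right <- i + (prof[i] - half) / (prof[i] - prof[i + 1L])
      break
    }
  }
  if (is.na(right)) stop("PSF support too small to bracket the half maximum")
  2 * (right - i0) * kernel@pixelSizeUm
}
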