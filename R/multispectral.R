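# Downstream chemical-imaging analyses: false-color composites, contaminant
# band masking, point-spectrum extraction, serial-section registration and
# 3-D volume assembly.

# nearest band index within tolerance, with an informative error
.bandIndex <- function(cube, bandCm1, tolCm1 = 4) {
  b <- cube@axis@bands
  i <- which.min(abs(b - bandCm1))
  if (abs(b[i] - bandCm1) > tolCm1)
    stop(sprintf("no band within %g cm-1 of %g (nearest available: %g)",
                 tolCm1, bandCm1, b[i]))
  i
}

#' False-color composite of three absorbance bands
#'
#' Combines high-contrast spectral bands into an RGB image with each band
#' driving one channel in the listed order (defaults: phosphate 1079 -> R,
#' Amide I 1658 -> G, ester 1765 -> B; the mapping is configurable).  Each
#' channel is rescaled by a percentile stretch and clamped to [0, 1];
#' before clamping the mapping is monotone in the band absorbance.
#'
#' @param cube a [HyperCube()].
#' @param bandsCm1 three wavenumbers, each matched to the nearest cube band
#'   within `tolCm1`.
#' @param stretch lower/upper percentile of the contrast stretch.
#' @param tolCm1 nearest-band tolerance in cm^-1.
#' @return (row, col, 3) array with values in [0, 1].
#' @export
falseColor <- function(cube, bandsCm1 = c(1079, 1658, 1765),
                       stretch = c(0.01, 0.99), tolCm1 = 4) {
  stopifnot(is(cube, "HyperCube"))
  if (length(bandsCm1) != 3L) stop("'bandsCm1' must list three bands")
  idx <- vapply(bandsCm1, function(b) .bandIndex(cube, b, tolCm1), integer(1))
  d <- dim(cube@data)
  out <- array(0, c(d[1], d[2], 3L))
  for (k in 1:3) {
    ch <- cube@data[, , idx[k]]
    q <- stats::quantile(ch, stretch, names = FALSE)
    if (q[2] <= q[1]) q[2] <- q[1] + 1   # constant band: all-zero channel
    out[, , k] <- pmin(pmax((ch - q[1]) / (q[2] - q[1]), 0), 1)
  }
  out
}

#' Robust contaminant mask at a marker band
#'
#' Flags pixels whose absorbance at the marker band (default the PTFE-like
#' C-F band, 1213 cm^-1) is a robust outlier — more than `kSigma` times the
#' MAD-based sigma above the band median — and exceeds the same pixel's
#' absorbance at a reference band (default Amide I, 1658 cm^-1).  The
#' median/MAD rule makes the mask invariant to a global multiplicative gain.
#'
#' @param cube a [HyperCube()].
#' @param bandCm1 marker band.
#' @param referenceBandCm1 reference band that contaminant pixels must
#'   exceed.
#' @param kSigma robust threshold multiplier.
#' @param tolCm1 nearest-band tolerance.
#' @return logical matrix; a degenerate (constant) marker band yields an
#'   empty mask with a warning.
#' @export
bandMask <- function(cube, bandCm1 = 1213, referenceBandCm1 = 1658,
                     kSigma = 5, tolCm1 = 4) {
  stopifnot(is(cube, "HyperCube"))
  A <- cube@data[, , .bandIndex(cube, bandCm1, tolCm1)]
  Aref <- cube@data[, , .bandIndex(cube, referenceBandCm1, tolCm1)]
  med <- stats::median(A)
  sigRob <- stats::mad(A)                 # 1.4826 * MAD, consistent for Gaussian
  if (sigRob == 0) {
    if (stats::sd(A) == 0) {
      warning("marker band is constant; returning an empty mask")
      return(matrix(FALSE, nrow(A), ncol(A)))
    }
    sigRob <- stats::sd(A)
  }
  (A - med > kSigma * sigRob) & (A > Aref)
}

#' Overlay a mask in green on a grayscale band image
#'
#' Utility for contaminant renderings: the band image (typically Amide I)
#' is percentile-stretched to grayscale and masked pixels are painted green.
#'
#' @param grayBand numeric matrix shown as grayscale background.
#' @param mask logical matrix of the same shape.
#' @param stretch percentile stretch for the background.
#' @return (row, col, 3) RGB array in [0, 1].
#' @export
maskOverlay <- function(grayBand, mask, stretch = c(0.01, 0.99)) {
  if (!identical(dim(grayBand), dim(mask))) stop("shapes differ")
  q <- stats::quantile(grayBand, stretch, names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  g <- pmin(pmax((grayBand - q[1]) / (q[2] - q[1]), 0), 1)
  out <- array(rep(g, 3L), c(dim(g), 3L))
  out[, , 1][mask] <- 0; out[, , 2][mask] <- 1; out[, , 3][mask] <- 0
  out
}

# --------------------------------------------------- registration and volumes

# Phase correlation between two images: returns the (dy, dx) shift of b
# relative to a, subpixel-refined by local Fourier upsampling of the
# cross-power spectrum around the integer peak.
.phaseCorrelate <- function(a, b, upsample = 50L, eps = 1e-12) {
  nr <- nrow(a); nc <- ncol(a)
  # Hann window: images are not periodic, and without tapering the border
  # mismatch of a true (non-circular) shift dominates the whitened spectrum
  w <- outer(0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)),
             0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  a <- (a - mean(a)) * w
  b <- (b - mean(b)) * w
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fa * Conj(Fb)
  R <- R / (Mod(R) + eps)
  corr <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  peak <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  dy <- peak[1] - 1L; dx <- peak[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  peakVal <- max(corr)
  # local DFT upsampling in a +/- 1 px neighbourhood of the integer peak
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  gy <- dy + seq(-1, 1, by = 1 / upsample)
  gx <- dx + seq(-1, 1, by = 1 / upsample)
  Ey <- exp(2i * pi * outer(gy, fy / nr))      # len(gy) x nr
  Ex <- exp(2i * pi * outer(fx / nc, gx))      # nc x len(gx)
  local <- Re(Ey %*% R %*% Ex) / length(R)
  m <- which(local == max(local), arr.ind = TRUE)[1, ]
  list(shift = c(gy[m[1]], gx[m[2]]), peak = peakVal)
}

#' Register serial sections by translation
#'
#' Estimates the rigid (translation-only) shift between consecutive slices
#' by phase correlation with subpixel refinement, and accumulates the
#' shifts relative to the first slice.  A correlation peak below
#' `minPeak` is treated as unreliable: that step contributes zero shift and
#' is flagged.  Rotation and scale changes between sections are a known
#' limitation of this estimator.
#'
#' @param slices list of same-shape matrices (one band per slice), length
#'   >= 2; [Scene()]s are accepted and reduced to their first band.
#' @param minPeak minimum phase-correlation peak for a confident estimate.
#' @return matrix with one (dy, dx) row per slice (first row zero), in
#'   pixels, with a logical attribute `confident` per step.
#' @export
registerSections <- function(slices, minPeak = 0.01) {
  imgs <- lapply(slices, function(s)
    if (is(s, "Scene")) s@absorbance[, , 1] else s)
  if (length(imgs) < 2L) stop("need at least 2 slices")
  d1 <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(m) identical(dim(m), d1), logical(1))))
    stop("slices must share one shape")
  n <- length(imgs)
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  confident <- rep(TRUE, n)
  for (i in 2:n) {
    pc <- .phaseCorrelate(imgs[[i - 1]], imgs[[i]])
    if (pc$peak < minPeak) {
      confident[i] <- FALSE
      step <- c(0, 0)
    } else step <- pc$shift
    # phase correlation returns the displacement of slice i relative to
    # slice i-1; accumulate to express all slices relative to slice 1
    shifts[i, ] <- shifts[i - 1, ] - step
  }
  attr(shifts, "confident") <- confident
  shifts
}

#' Assemble aligned sections into a volume
#'
#' Resamples each slice by the negated recovered shift (bilinear) and
#' stacks them; samples falling outside a slice are `NA`.
#'
#' @param slices list of matrices or [Scene()]s (first band used).
#' @param shifts matrix of per-slice (dy, dx) shifts relative to slice 1,
#'   as returned by [registerSections()].
#' @param zSpacingUm slice thickness.
#' @return a [Volume-class] object.
#' @examples
#' secs <- makeSerialSections(nSlices = 5, seed = 1, imagePx = 48)
#' sh <- registerSections(secs)
#' vol <- assembleVolume(secs, sh)
#' dim(volumeData(vol))
#' @export
assembleVolume <- function(slices, shifts, zSpacingUm = 5) {
  imgs <- lapply(slices, function(s)
    if (is(s, "Scene")) s@absorbance[, , 1] else s)
  n <- length(imgs)
  if (nrow(shifts) != n) stop("'shifts' must have one row per slice")
  d1 <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(m) identical(dim(m), d1), logical(1))))
    stop("slices must share one shape")
  out <- array(NA_real_, c(n, d1[1], d1[2]))
  for (i in seq_len(n)) {
    out[i, , ] <- if (all(shifts[i, ] == 0)) imgs[[i]]
    else shiftImage(imgs[[i]], -shifts[i, 1], -shifts[i, 2])
  }
  new("Volume", data = out, zSpacingUm = as.numeric(zSpacingUm),
      transforms = as.matrix(shifts))
}

#' Orthogonal cross-section of a volume
#'
#' @param volume a [Volume-class] object.
#' @param axis `"z"` (one slice), `"y"` (slice x row) or `"x"`
#'   (slice x col).
#' @param index 1-based position along the chosen axis.
#' @return numeric matrix.
#' @export
crossSection <- function(volume, axis = c("z", "y", "x"), index) {
  stopifnot(is(volume, "Volume"))
  axis <- match.arg(axis)
  d <- dim(volume@data)
  lim <- switch(axis, z = d[1], y = d[2], x = d[3])
  if (index < 1 || index > lim)
    stop(sprintf("index %d outside 1..%d along '%s'", index, lim, axis))
  switch(axis,
         z = volume@data[index, , ],
         y = volume@data[, index, ],
         x = volume@data[, , index])
}

#' Mean correlation of adjacent slices
#'
#' Cross-slice continuity measure used to verify that alignment improves a
#' serially sectioned stack: the mean Pearson correlation of consecutive
#' slices over their jointly finite pixels.
#'
#' @param x a [Volume-class] object or (slice, row, col) array.
#' @return mean adjacent-slice correlation.
#' @export
adjacentSliceCorrelation <- function(x) {
  arr <- if (is(x, "Volume")) x@data else x
  n <- dim(arr)[1]
  if (n < 2L) stop("need at least 2 slices")
  mean(vapply(seq_len(n - 1L), function(i) {
    a <- arr[i, , ]; b <- arr[i + 1L, , ]
    ok <- is.finite(a) & is.finite(b)
    stats::cor(a[ok], b[ok])
  }, numeric(1)))
}

#' Extract the spectrum at one cube pixel
#'
#' @param cube a [HyperCube()].
#' @param pointPx length-2 (row, col) pixel inside the cube.
#' @param average also average the 3 x 3 neighbourhood (clipped at the
#'   borders) instead of the single pixel.
#' @return named numeric absorbance spectrum (names are the bands).
#' @export
extractSpectrum <- function(cube, pointPx, average = FALSE) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  r <- pointPx[1]; c_ <- pointPx[2]
  if (r < 1 || r > d[1] || c_ < 1 || c_ > d[2])
    stop(sprintf("point (%g, %g) outside the %d x %d cube", r, c_, d[1], d[2]))
  if (average) {
    ri <- max(1, r - 1):min(d[1], r + 1)
    ci <- max(1, c_ - 1):min(d[2], c_ + 1)
    out <- apply(cube@data[ri, ci, , drop = FALSE], 3, mean)
  } else {
    out <- cube@data[r, c_, ]
  }
  names(out) <- cube@axis@bands
  out
}
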