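# Synthetic calibration targets and spectrally structured specimens with
# exact ground truth.  All generators are pure functions of their parameters
# and seed; identical calls produce bit-identical scenes.
#
# Target polarity follows reflective-substrate conventions: the background is
# highly reflective (low absorbance) and features absorb.  Rasterized truth
# uses pixel-centre membership (no anti-aliasing); an anti-aliased rendering
# is available by flag where estimators need area-integrated pixels.

#' Built-in library of synthetic component spectra
#'
#' Gaussian-band stand-ins for the tissue and contaminant spectra used by the
#' phantoms: a protein-dominated component (Amide I 1658 / Amide II
#' 1544 cm^-1), a phosphate-rich component (1079 cm^-1 plus weaker protein
#' bands), an ester-lipid component (carbonyl 1765 cm^-1) and a PTFE-like
#' contaminant peaked at the C-F band 1213 cm^-1.  Band positions are the
#' standard fingerprint assignments; shapes and amplitudes are synthetic
#' modelling choices (widths default to ~20 cm^-1 sigma).
#'
#' @return A [SpectralLibrary()].
#' @examples
#' names(defaultSpectralLibrary()@components)
#' @export
defaultSpectralLibrary <- function() {
  g <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], width = m[, 2], peak = m[, 3])
  }
  SpectralLibrary(list(
    protein = g(1658, 25, 0.80,
                1544, 22, 0.55),
    phosphate_rich = g(1079, 30, 0.60,
                       1658, 25, 0.40,
                       1544, 22, 0.30),
    ester_lipid = g(1765, 20, 0.70,
                    1658, 25, 0.15),
    ptfe = g(1213, 15, 0.90,
             1154, 15, 0.50)))
}

#' Evaluate a library component on a wavenumber axis
#'
#' @param library a [SpectralLibrary()].
#' @param component component name.
#' @param axis a [SpectralAxis()].
#' @return numeric absorbance per band (a.u.).
#' @examples
#' evalSpectrum(defaultSpectralLibrary(), "ptfe",
#'              SpectralAxis(c(1079, 1213, 1658)))
#' @export
evalSpectrum <- function(library, component, axis) {
  stopifnot(is(library, "SpectralLibrary"), is(axis, "SpectralAxis"))
  comp <- library@components[[component]]
  if (is.null(comp)) stop("unknown component: ", component)
  nu <- axis@bands
  out <- numeric(length(nu))
  for (i in seq_len(nrow(comp)))
    out <- out + comp$peak[i] * exp(-(nu - comp$center[i])^2 / (2 * comp$width[i]^2))
  out
}

# image-centre coordinates (between pixels for even sizes)
.gridCentre <- function(n) (n + 1) / 2

#' Siemens-star resolution target
#'
#' A radial square-wave pattern with `nSpokes` absorbing sectors per
#' revolution; at radius `r` (micrometres) the circumferential spatial
#' frequency is `nSpokes / (2 pi r)` cycles/um, recorded in the truth
#' metadata.  The pattern is invariant under rotation by `2 pi / nSpokes`.
#'
#' @param nSpokes even number of full cycles per revolution, >= 2.
#' @param imagePx image edge length in pixels.
#' @param pixelSizeUm sampling.
#' @param bandCm1 wavenumber of the single-band scene.
#' @param amplitude absorbance of the spokes (a.u.).
#' @param antialias render pixel coverage fractions (8x supersampling)
#'   instead of pixel-centre membership.
#' @return A [Scene()]; `sceneTruth()` holds `nSpokes`, `centerPx` and the
#'   frequency mapping.
#' @examples
#' star <- makeSiemensStar(72, 256, 1)
#' starFrequency(star, 100)   # cycles/um on the r = 100 um ring
#' @export
makeSiemensStar <- function(nSpokes, imagePx, pixelSizeUm, bandCm1 = 1658,
                            amplitude = 1, antialias = FALSE) {
  if (nSpokes %% 2L != 0L || nSpokes < 2L)
    stop("'nSpokes' must be an even integer >= 2")
  cc <- .gridCentre(imagePx)
  pat <- function(ss) {
    n <- imagePx * ss
    idx <- (seq_len(n) - 0.5) / ss + 0.5   # supersample centres
    y <- matrix(idx - cc, n, n)
    x <- matrix(idx - cc, n, n, byrow = TRUE)
    th <- atan2(y, x)
    (sin(nSpokes * th) > 0) * 1
  }
  if (antialias) {
    ss <- 8L
    fine <- pat(ss)
    m <- matrix(0, imagePx, imagePx)
    for (i in seq_len(ss)) for (j in seq_len(ss))
      m <- m + fine[seq(i, by = ss, length.out = imagePx),
                    seq(j, by = ss, length.out = imagePx)]
    m <- m / ss^2
  } else {
    m <- pat(1L)
  }
  A <- amplitude * m
  Scene(A, classMap = matrix(as.integer(m > 0.5), imagePx, imagePx),
        axis = SpectralAxis(bandCm1), pixelSizeUm = pixelSizeUm,
        truth = list(type = "siemens_star", nSpokes = nSpokes,
                     centerPx = c(cc, cc), amplitude = amplitude,
                     antialias = antialias))
}

#' Circumferential frequency of a Siemens star at a radius
#'
#' @param scene a star [Scene()] (or its truth list).
#' @param radiusUm ring radius in micrometres.
#' @return frequency in cycles per micrometre, `nSpokes / (2 pi r)`.
#' @export
starFrequency <- function(scene, radiusUm) {
  truth <- if (is(scene, "Scene")) scene@truth else scene
  if (is.null(truth$nSpokes)) stop("not a Siemens-star scene")
  truth$nSpokes / (2 * pi * radiusUm)
}

#' Slanted-edge target
#'
#' A two-level image split by a straight edge tilted `angleDeg` from the
#' vertical through the image centre; the exact edge line is recorded in the
#' truth metadata.  ISO 12233 recommends slants of 2-10 degrees; values
#' outside that range draw a warning, not an error.
#'
#' @param angleDeg slant from vertical in degrees.
#' @param imagePx image edge length in pixels.
#' @param pixelSizeUm sampling.
#' @param contrast absorbance of the bright side (a.u.).
#' @param bandCm1 wavenumber of the single-band scene.
#' @param antialias render pixel coverage (exact for a straight edge via
#'   16x supersampling) instead of pixel-centre membership.
#' @return A [Scene()] with truth fields `angleDeg`, `centerPx`,
#'   `edgeColAtRow` (function-free: intercept and slope of the edge line).
#' @export
makeSlantEdge <- function(angleDeg, imagePx, pixelSizeUm, contrast = 1,
                          bandCm1 = 1658, antialias = FALSE) {
  if (angleDeg < 2 || angleDeg > 10)
    warning("slant of ", angleDeg, " deg is outside the recommended 2-10 degree range")
  cc <- .gridCentre(imagePx)
  slope <- tan(angleDeg * pi / 180)   # columns per row
  render <- function(ss) {
    n <- imagePx * ss
    idx <- (seq_len(n) - 0.5) / ss + 0.5
    r <- matrix(idx, n, n)
    c_ <- matrix(idx, n, n, byrow = TRUE)
    # signed horizontal distance from the edge line col = cc + slope*(row-cc)
    (c_ - cc - slope * (r - cc) > 0) * 1
  }
  if (antialias) {
    ss <- 16L
    fine <- render(ss)
    m <- matrix(0, imagePx, imagePx)
    for (i in seq_len(ss)) for (j in seq_len(ss))
      m <- m + fine[seq(i, by = ss, length.out = imagePx),
                    seq(j, by = ss, length.out = imagePx)]
    m <- m / ss^2
  } else {
    m <- render(1L)
  }
  A <- contrast * m
  Scene(A, classMap = matrix(as.integer(m > 0.5), imagePx, imagePx),
        axis = SpectralAxis(bandCm1), pixelSizeUm = pixelSizeUm,
        truth = list(type = "slant_edge", angleDeg = angleDeg,
                     centerPx = c(cc, cc), edgeIntercept = cc,
                     edgeSlope = slope, contrast = contrast,
                     antialias = antialias))
}

#' Tissue-like multispectral phantom
#'
#' Crypt-like class regions generated from thresholded smoothed Gaussian
#' random fields: one field per class, smoothed over `blobScalePx`, with the
#' per-pixel class given by the largest field.  Each pixel's spectrum is its
#' class spectrum sampled on `axis`; with `mixSigmaPx > 0` the one-hot class
#' weights are blurred, giving linear spectral mixing at boundaries.  Fully
#' seeded and reproducible.
#'
#' @param imagePx image edge length in pixels.
#' @param pixelSizeUm sampling.
#' @param library a [SpectralLibrary()] with at least two components.
#' @param axis a [SpectralAxis()].
#' @param seed RNG seed.
#' @param classes component names to use (default: all non-contaminant
#'   components of the library).
#' @param blobScalePx smoothing scale of the class fields in pixels.
#' @param mixSigmaPx boundary mixing scale in pixels (0 = hard labels).
#' @return A [Scene()]; class labels are 1-based indices into `classes`,
#'   recorded in `sceneTruth()$classes`.
#' @examples
#' ax <- SpectralAxis(c(1079, 1213, 1544, 1658, 1765))
#' ph <- makeTissuePhantom(96, 2, defaultSpectralLibrary(), ax, seed = 1)
#' table(classMap(ph))
#' @export
makeTissuePhantom <- function(imagePx, pixelSizeUm, library, axis, seed,
                              classes = NULL, blobScalePx = 12,
                              mixSigmaPx = 0) {
  stopifnot(is(library, "SpectralLibrary"), is(axis, "SpectralAxis"))
  if (is.null(classes))
    classes <- setdiff(names(library@components), "ptfe")
  if (length(classes) < 2L) stop("library must provide at least two components")
  spectra <- vapply(classes, function(cl) evalSpectrum(library, cl, axis),
                    numeric(length(axis@bands)))
  withSeed(seed, {
    fields <- lapply(classes, function(cl)
      gaussianSmooth(matrix(stats::rnorm(imagePx^2), imagePx, imagePx),
                     blobScalePx))
    stacked <- array(unlist(fields), c(imagePx, imagePx, length(classes)))
    cls <- apply(stacked, c(1, 2), which.max)
    if (mixSigmaPx > 0) {
      w <- lapply(seq_along(classes), function(k)
        gaussianSmooth((cls == k) * 1, mixSigmaPx))
      tot <- Reduce(`+`, w)
      w <- lapply(w, function(m) m / tot)
    } else {
      w <- lapply(seq_along(classes), function(k) (cls == k) * 1)
    }
    A <- array(0, c(imagePx, imagePx, length(axis@bands)))
    for (k in seq_along(classes))
      for (b in seq_len(length(axis@bands)))
        A[, , b] <- A[, , b] + w[[k]] * spectra[b, k]
    A <- pmax(A, 0)     # guard FFT round-off undershoot in the mixed weights
    Scene(A, classMap = cls, axis = axis, pixelSizeUm = pixelSizeUm,
          truth = list(type = "tissue", classes = classes, seed = seed,
                       blobScalePx = blobScalePx, mixSigmaPx = mixSigmaPx))
  })
}

#' Insert contaminant inclusions into a scene
#'
#' Discs of a contaminant spectrum (default the PTFE-like component peaked
#' at 1213 cm^-1) replace the tissue spectrum at random positions; centres
#' and radii are recorded in the truth metadata so detection can be scored
#' exactly.  A pixel belongs to a disc when its centre lies inside.
#'
#' @param scene a [Scene()].
#' @param component contaminant component name in `library`.
#' @param nInclusions number of discs (0 leaves the scene unchanged).
#' @param radiusPx disc radius in pixels.
#' @param seed RNG seed for the disc centres.
#' @param library a [SpectralLibrary()] containing `component`.
#' @param bandTolCm1 the contaminant's marker band must lie within this
#'   tolerance of an axis band.
#' @return The modified [Scene()]; inclusions get class label
#'   `max(classMap) + 1`, recorded as `sceneTruth()$inclusionLabel`, with a
#'   data frame `sceneTruth()$inclusions` (row, col, radiusPx).
#' @export
addInclusions <- function(scene, component = "ptfe", nInclusions = 5,
                          radiusPx = 25, seed = 1,
                          library = defaultSpectralLibrary(),
                          bandTolCm1 = 4) {
  stopifnot(is(scene, "Scene"))
  if (nInclusions == 0) return(scene)
  d <- dim(scene@absorbance)
  if (2 * radiusPx >= min(d[1:2]))
    stop("inclusion diameter exceeds the image")
  comp <- library@components[[component]]
  if (is.null(comp)) stop("unknown component: ", component)
  marker <- comp$center[which.max(comp$peak)]
  if (min(abs(scene@axis@bands - marker)) > bandTolCm1)
    stop(sprintf("no axis band within %g cm-1 of the %g cm-1 marker",
                 bandTolCm1, marker))
  spec <- evalSpectrum(library, component, scene@axis)
  withSeed(seed, {
    margin <- radiusPx + 2
    rows <- stats::runif(nInclusions, margin, d[1] - margin)
    cols <- stats::runif(nInclusions, margin, d[2] - margin)
    cls <- scene@classMap
    label <- max(cls) + 1L
    A <- scene@absorbance
    rr <- matrix(seq_len(d[1]), d[1], d[2])
    cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    inside <- matrix(FALSE, d[1], d[2])
    for (i in seq_len(nInclusions))
      inside <- inside | ((rr - rows[i])^2 + (cc - cols[i])^2 <= radiusPx^2)
    for (b in seq_len(d[3])) {
      slab <- A[, , b]; slab[inside] <- spec[b]; A[, , b] <- slab
    }
    cls[inside] <- label
    truth <- scene@truth
    truth$inclusions <- data.frame(row = rows, col = cols, radiusPx = radiusPx)
    truth$inclusionLabel <- label
    truth$inclusionComponent <- component
    Scene(A, cls, scene@axis, scene@pixelSizeUm, truth)
  })
}

#' Serial sections of a 3-D tubular phantom
#'
#' A tissue block containing `nTubes` crypt-like tubes whose centres wander
#' smoothly with depth is sliced into `nSlices` sections of `thicknessUm`.
#' Each slice receives a random rigid shift of at most `jitterPx` pixels per
#' axis, applied analytically (the shifted scene is rendered directly, not
#' resampled) and recorded in the truth metadata.
#'
#' @param nSlices number of sections, >= 1 (a single slice gets zero shift).
#' @param thicknessUm section thickness (z spacing).
#' @param jitterPx maximum absolute per-axis shift in pixels.
#' @param seed RNG seed.
#' @param imagePx image edge length in pixels.
#' @param pixelSizeUm sampling.
#' @param nTubes number of tubes.
#' @param wanderPx scale of the tubes' smooth lateral wander across the
#'   whole block depth, in pixels.  Set to 0 for straight tubes, which
#'   makes the recorded jitter the only slice-to-slice motion (the
#'   configuration used to score registration recovery; any anatomical
#'   drift is indistinguishable from jitter to a translation estimator).
#' @param library,axis spectra for tube interior (phosphate-rich) and the
#'   surrounding matrix (protein).
#' @return list of [Scene()]s; each `sceneTruth()` holds `shiftPx = c(dy, dx)`
#'   and the slice's tube centres.
#' @export
makeSerialSections <- function(nSlices = 20, thicknessUm = 5, jitterPx = 2,
                               seed = 1, imagePx = 96, pixelSizeUm = 2,
                               nTubes = 6, wanderPx = 2,
                               library = defaultSpectralLibrary(),
                               axis = SpectralAxis(c(1079, 1658))) {
  if (nSlices < 1) stop("'nSlices' must be >= 1")
  tubeSpec <- evalSpectrum(library, "phosphate_rich", axis)
  matrixSpec <- evalSpectrum(library, "protein", axis)
  withSeed(seed, {
    margin <- imagePx / 5
    baseR <- stats::runif(nTubes, margin, imagePx - margin)
    baseC <- stats::runif(nTubes, margin, imagePx - margin)
    radii <- stats::runif(nTubes, imagePx / 18, imagePx / 10)
    ampR <- stats::runif(nTubes, 0.25, 1) * wanderPx
    ampC <- stats::runif(nTubes, 0.25, 1) * wanderPx
    phR <- stats::runif(nTubes, 0, 2 * pi)
    phC <- stats::runif(nTubes, 0, 2 * pi)
    periodUm <- nSlices * thicknessUm     # one wander period over the block
    shifts <- if (nSlices == 1) matrix(0, 1, 2) else
      matrix(stats::runif(2 * nSlices, -jitterPx, jitterPx), ncol = 2)
    if (nSlices >= 1) shifts[1, ] <- 0    # first slice is the reference
    lapply(seq_len(nSlices), function(s) {
      z <- (s - 0.5) * thicknessUm
      ctrR <- baseR + ampR * sin(2 * pi * z / periodUm + phR) + shifts[s, 1]
      ctrC <- baseC + ampC * sin(2 * pi * z / periodUm + phC) + shifts[s, 2]
      rr <- matrix(seq_len(imagePx), imagePx, imagePx)
      cc <- matrix(seq_len(imagePx), imagePx, imagePx, byrow = TRUE)
      inside <- matrix(0, imagePx, imagePx)
      for (k in seq_len(nTubes)) {
        dist <- sqrt((rr - ctrR[k])^2 + (cc - ctrC[k])^2)
        # soft 1-px edge so subpixel structure is preserved
        inside <- pmax(inside, pmin(pmax(radii[k] - dist + 0.5, 0), 1))
      }
      A <- array(0, c(imagePx, imagePx, length(axis@bands)))
      for (b in seq_along(axis@bands))
        A[, , b] <- inside * tubeSpec[b] + (1 - inside) * matrixSpec[b]
      Scene(A, classMap = matrix(as.integer(inside > 0.5), imagePx, imagePx),
            axis = axis, pixelSizeUm = pixelSizeUm,
            truth = list(type = "serial_section", slice = s,
                         shiftPx = shifts[s, ], zUm = z,
                         centersPx = cbind(row = ctrR, col = ctrC),
                         radiiPx = radii, thicknessUm = thicknessUm))
    })
  })
}

#' Synthetic SU-8-like reference film spectrum
#'
#' A fixed multi-band Gaussian spectrum emulating a thin epoxy-photoresist
#' film on a reflective substrate, scaling linearly with thickness
#' (Beer-Lambert).  The band set is a synthetic stand-in chosen to lie in
#' the fingerprint region; it is not a measured reference.
#'
#' @param axis a [SpectralAxis()].
#' @param thicknessUm film thickness in micrometres (> 0; 0 is allowed and
#'   gives the all-zero spectrum).
#' @return numeric absorbance per band (a.u.).
#' @examples
#' ax <- SpectralAxis(seq(800, 1900, by = 4))
#' s5 <- makeSu8Film(ax, 5)
#' @export
makeSu8Film <- function(axis, thicknessUm) {
  stopifnot(is(axis, "SpectralAxis"))
  if (thicknessUm < 0) stop("'thicknessUm' must be >= 0")
  bandsDef <- data.frame(            # synthetic epoxy-like band set, per um
    center = c(1608, 1510, 1456, 1245, 1180, 1130),
    width = c(12, 14, 12, 16, 14, 12),
    peakPerUm = c(0.030, 0.070, 0.030, 0.050, 0.040, 0.035))
  nu <- axis@bands
  out <- numeric(length(nu))
  for (i in seq_len(nrow(bandsDef)))
    out <- out + bandsDef$peakPerUm[i] *
      exp(-(nu - bandsDef$center[i])^2 / (2 * bandsDef$width[i]^2))
  thicknessUm * out
}
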