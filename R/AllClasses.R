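#' @import methods
NULL

# ---------------------------------------------------------------- SpectralAxis

#' Wavenumber axis of a discrete-frequency measurement
#'
#' An ordered grid of mid-infrared wavenumbers (cm^-1) at which images or
#' spectra are acquired.  Values must be strictly increasing and positive.
#'
#' @param bands numeric vector of wavenumbers in cm^-1, strictly increasing.
#' @return A `SpectralAxis` object.
#' @examples
#' SpectralAxis(c(1079, 1213, 1544, 1658, 1765))
#' @export
SpectralAxis <- function(bands) {
  new("SpectralAxis", bands = as.numeric(bands))
}

#' @rdname SpectralAxis
#' @export
setClass("SpectralAxis", representation(bands = "numeric"), validity = function(object) {
  b <- object@bands
  if (length(b) < 1L) return("axis must contain at least one band")
  if (any(!is.finite(b)) || any(b <= 0)) return("wavenumbers must be finite and > 0")
  if (length(b) > 1L && any(diff(b) <= 0)) return("wavenumbers must be strictly increasing")
  TRUE
})

# ------------------------------------------------------------ InstrumentConfig

#' Optical, scan and detection parameters of one imaging configuration
#'
#' Bundles the parameters that define a point-scanning (or widefield
#' comparator) configuration: numerical aperture, sample-plane pixel size,
#' tile edge length, pixel rate, laser and raster duty cycles, detection
#' pinhole geometry, and the pupil obscuration/illumination-block fractions
#' used for all-reflective comparator objectives.
#'
#' @param name text label of the configuration.
#' @param na numerical aperture, in (0, 1].
#' @param magnification nominal magnification.
#' @param pixelSizeUm sample-plane sampling in micrometres per pixel.
#' @param tilePx tile edge length in pixels; `tilePx * pixelSizeUm` is the
#'   single-frame field-of-view edge.
#' @param pixelRateHz pixels acquired per second (one laser shot per pixel).
#' @param laserDuty laser pulse duty cycle, in (0, 1].
#' @param scanDuty raster active-scan duty cycle, in (0, 1].
#' @param pinholeDiameterUm detection pinhole diameter in micrometres
#'   (0 means no pinhole).
#' @param detectionMagnification sample-to-pinhole magnification.
#' @param obscuration central pupil obscuration ratio in [0, 1); 0 for a
#'   clear refractive aperture.
#' @param illuminationPupilFraction fraction of the pupil blocked on one side
#'   for fold-mirror illumination, in [0, 1); 0 for full-pupil illumination.
#' @param spectralRangeCm1 length-2 numeric, the tunable range in cm^-1.
#' @return An `InstrumentConfig` object.
#' @seealso [instrumentPreset()] for the built-in configurations,
#'   [loadConfig()]/[saveConfig()] for file round trips.
#' @examples
#' cfg <- instrumentPreset("lsm10x")
#' fovUm(cfg)
#' @export
InstrumentConfig <- function(name, na, magnification, pixelSizeUm, tilePx,
                             pixelRateHz, laserDuty = 1, scanDuty = 1,
                             pinholeDiameterUm = 0, detectionMagnification = 1,
                             obscuration = 0, illuminationPupilFraction = 0,
                             spectralRangeCm1 = c(777, 1904)) {
  new("InstrumentConfig", name = as.character(name), na = as.numeric(na),
      magnification = as.numeric(magnification),
      pixelSizeUm = as.numeric(pixelSizeUm), tilePx = as.integer(tilePx),
      pixelRateHz = as.numeric(pixelRateHz), laserDuty = as.numeric(laserDuty),
      scanDuty = as.numeric(scanDuty),
      pinholeDiameterUm = as.numeric(pinholeDiameterUm),
      detectionMagnification = as.numeric(detectionMagnification),
      obscuration = as.numeric(obscuration),
      illuminationPupilFraction = as.numeric(illuminationPupilFraction),
      spectralRangeCm1 = as.numeric(spectralRangeCm1))
}

#' @rdname InstrumentConfig
#' @export
setClass("InstrumentConfig", representation(
  name = "character", na = "numeric", magnification = "numeric",
  pixelSizeUm = "numeric", tilePx = "integer", pixelRateHz = "numeric",
  laserDuty = "numeric", scanDuty = "numeric", pinholeDiameterUm = "numeric",
  detectionMagnification = "numeric", obscuration = "numeric",
  illuminationPupilFraction = "numeric", spectralRangeCm1 = "numeric"),
  validity = function(object) {
    chk <- function(expr, msg) if (!isTRUE(expr)) msg else NULL
    msgs <- c(
      chk(length(object@name) == 1L && nzchar(object@name), "field 'name' must be a non-empty string"),
      chk(is.finite(object@na) && object@na > 0 && object@na <= 1, "field 'na' must be in (0, 1]"),
      chk(is.finite(object@magnification) && object@magnification > 0, "field 'magnification' must be > 0"),
      chk(is.finite(object@pixelSizeUm) && object@pixelSizeUm > 0, "field 'pixelSizeUm' must be > 0"),
      chk(!is.na(object@tilePx) && object@tilePx >= 1L, "field 'tilePx' must be >= 1"),
      chk(is.finite(object@pixelRateHz) && object@pixelRateHz > 0, "field 'pixelRateHz' must be > 0"),
      chk(is.finite(object@laserDuty) && object@laserDuty > 0 && object@laserDuty <= 1, "field 'laserDuty' must be in (0, 1]"),
      chk(is.finite(object@scanDuty) && object@scanDuty > 0 && object@scanDuty <= 1, "field 'scanDuty' must be in (0, 1]"),
      chk(is.finite(object@pinholeDiameterUm) && object@pinholeDiameterUm >= 0, "field 'pinholeDiameterUm' must be >= 0"),
      chk(is.finite(object@detectionMagnification) && object@detectionMagnification > 0, "field 'detectionMagnification' must be > 0"),
      chk(is.finite(object@obscuration) && object@obscuration >= 0 && object@obscuration < 1, "field 'obscuration' must be in [0, 1)"),
      chk(is.finite(object@illuminationPupilFraction) && object@illuminationPupilFraction >= 0 && object@illuminationPupilFraction < 1,
          "field 'illuminationPupilFraction' must be in [0, 1)"),
      chk(length(object@spectralRangeCm1) == 2L && all(is.finite(object@spectralRangeCm1)) &&
            all(object@spectralRangeCm1 > 0) && diff(object@spectralRangeCm1) > 0,
          "field 'spectralRangeCm1' must be an increasing positive pair"))
    if (length(msgs)) msgs else TRUE
  })

# ------------------------------------------------------------------- HyperCube

#' Stitched absorbance cube
#'
#' A (row, col, band) array of absorbance values (a.u.) with its wavenumber
#' axis, sample-plane sampling and free-form provenance.  Coordinates follow
#' raster order: the physical origin is the centre of pixel (1, 1), x grows
#' with column and y with row.
#'
#' @param data numeric array indexed (row, col, band); a matrix is promoted
#'   to a single-band cube.
#' @param axis a [SpectralAxis()] whose length matches `dim(data)[3]`.
#' @param pixelSizeUm sampling in micrometres per pixel.
#' @param originUm length-2 numeric, sample-plane (x, y) of pixel (1, 1).
#' @param provenance free-form named list (configuration name, coadditions,
#'   seed, ...).
#' @return A `HyperCube`.
#' @examples
#' cube <- HyperCube(array(runif(24), c(2, 4, 3)),
#'                   SpectralAxis(c(1079, 1658, 1765)), pixelSizeUm = 2)
#' dim(cubeData(cube))
#' @export
HyperCube <- function(data, axis, pixelSizeUm, originUm = c(0, 0),
                      provenance = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("HyperCube", data = data, axis = axis,
      pixelSizeUm = as.numeric(pixelSizeUm), originUm = as.numeric(originUm),
      provenance = provenance)
}

#' @rdname HyperCube
#' @export
setClass("HyperCube", representation(
  data = "array", axis = "SpectralAxis", pixelSizeUm = "numeric",
  originUm = "numeric", provenance = "list"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a (row, col, band) array")
    if (d[3] != length(object@axis@bands))
      return(sprintf("band count %d does not match axis length %d",
                     d[3], length(object@axis@bands)))
    if (d[3] < 1L) return("cube must contain at least one band")
    if (!is.finite(object@pixelSizeUm) || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be > 0")
    if (length(object@originUm) != 2L) return("originUm must have length 2")
    if (any(!is.finite(object@data))) return("cube values must all be finite")
    TRUE
  })

# -------------------------------------------------------------------- optics

#' Pupil description for diffraction calculations
#'
#' @param na numerical aperture in (0, 1].
#' @param wavenumberCm1 wavenumber in cm^-1; the wavelength is
#'   `1e4 / wavenumberCm1` micrometres.
#' @param obscuration central obscuration ratio epsilon in [0, 1)
#'   (fraction of the pupil radius blocked, as in a two-mirror reflective
#'   objective); 0 for a clear aperture.
#' @param illuminationPupilFraction fraction of the pupil area blocked by a
#'   half-plane on one side (transflection fold mirror), in [0, 1).
#' @return A `PupilSpec`.
#' @examples
#' PupilSpec(na = 0.4, wavenumberCm1 = 1658)
#' @export
PupilSpec <- function(na, wavenumberCm1, obscuration = 0,
                      illuminationPupilFraction = 0) {
  new("PupilSpec", na = as.numeric(na), wavenumberCm1 = as.numeric(wavenumberCm1),
      obscuration = as.numeric(obscuration),
      illuminationPupilFraction = as.numeric(illuminationPupilFraction))
}

#' @rdname PupilSpec
#' @export
setClass("PupilSpec", representation(
  na = "numeric", wavenumberCm1 = "numeric", obscuration = "numeric",
  illuminationPupilFraction = "numeric"),
  validity = function(object) {
    if (!is.finite(object@na) || object@na <= 0 || object@na > 1)
      return("na must be in (0, 1]")
    if (!is.finite(object@wavenumberCm1) || object@wavenumberCm1 <= 0)
      return("wavenumberCm1 must be > 0")
    if (!is.finite(object@obscuration) || object@obscuration < 0 || object@obscuration >= 1)
      return("obscuration must be in [0, 1)")
    if (!is.finite(object@illuminationPupilFraction) ||
        object@illuminationPupilFraction < 0 || object@illuminationPupilFraction >= 1)
      return("illuminationPupilFraction must be in [0, 1)")
    TRUE
  })

#' Sampled intensity point-spread function
#'
#' A nonnegative 2-D intensity grid normalized to unit sum, together with its
#' sample-plane pixel size.  Produced by [psf()] and [confocalPsf()].
#'
#' @seealso [psf()], [confocalPsf()]
#' @export
setClass("PSFKernel", representation(
  samples = "matrix", pixelSizeUm = "numeric", normalization = "character"),
  validity = function(object) {
    if (any(object@samples < -1e-12)) return("PSF samples must be nonnegative")
    if (abs(sum(object@samples) - 1) > 1e-9)
      return("PSF must be normalized to unit sum")
    if (!is.finite(object@pixelSizeUm) || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be > 0")
    TRUE
  })

#' Modulation-transfer-function curve
#'
#' Spatial frequencies (cycles per micrometre) against modulation, with
#' estimator metadata.  Modulation is normalized to 1 at zero frequency.
#'
#' @param freqCycPerUm strictly increasing nonnegative frequencies.
#' @param modulation contrast values at those frequencies.
#' @param meta named list of estimator/band/axis labels.
#' @return An `MTFCurve`.
#' @export
MTFCurve <- function(freqCycPerUm, modulation, meta = list()) {
  new("MTFCurve", freqCycPerUm = as.numeric(freqCycPerUm),
      modulation = as.numeric(modulation), meta = meta)
}

#' @rdname MTFCurve
#' @export
setClass("MTFCurve", representation(
  freqCycPerUm = "numeric", modulation = "numeric", meta = "list"),
  validity = function(object) {
    f <- object@freqCycPerUm
    if (length(f) != length(object@modulation))
      return("frequency and modulation lengths differ")
    if (any(f < 0) || (length(f) > 1L && any(diff(f) <= 0)))
      return("frequencies must be strictly increasing and >= 0")
    if (f[1] == 0 && abs(object@modulation[1] - 1) > 1e-6)
      return("modulation must be 1 at zero frequency")
    TRUE
  })

# ------------------------------------------------------------------- phantoms

#' Synthetic scene with exact ground truth
#'
#' Per-band ground-truth absorbance maps plus an integer class-label image
#' and geometry metadata.  Scenes are produced by the phantom generators
#' ([makeSiemensStar()], [makeSlantEdge()], [makeTissuePhantom()],
#' [makeSerialSections()]) and consumed by the acquisition simulator.
#'
#' @param absorbance numeric array (row, col, band), values >= 0 (a.u.).
#' @param classMap integer matrix of class labels, same spatial shape.
#' @param axis a [SpectralAxis()].
#' @param pixelSizeUm sampling in micrometres per pixel.
#' @param truth named list of exact geometry metadata.
#' @return A `Scene`.
#' @export
Scene <- function(absorbance, classMap, axis, pixelSizeUm, truth = list()) {
  if (is.matrix(absorbance)) absorbance <- array(absorbance, c(dim(absorbance), 1L))
  storage.mode(classMap) <- "integer"
  new("Scene", absorbance = absorbance, classMap = classMap, axis = axis,
      pixelSizeUm = as.numeric(pixelSizeUm), truth = truth)
}

#' @rdname Scene
#' @export
setClass("Scene", representation(
  absorbance = "array", classMap = "matrix", axis = "SpectralAxis",
  pixelSizeUm = "numeric", truth = "list"),
  validity = function(object) {
    d <- dim(object@absorbance)
    if (length(d) != 3L) return("absorbance must be a (row, col, band) array")
    if (!identical(d[1:2], dim(object@classMap)))
      return("classMap shape must match absorbance maps")
    if (d[3] != length(object@axis@bands))
      return("band count does not match axis length")
    if (any(object@absorbance < 0)) return("absorbance must be >= 0")
    if (!is.finite(object@pixelSizeUm) || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be > 0")
    TRUE
  })

#' Library of synthetic component spectra
#'
#' Each component is a sum of Gaussian absorption bands given as a data frame
#' with columns `center` (cm^-1), `width` (Gaussian sigma, cm^-1) and `peak`
#' (a.u.).  Band shapes are a modelling convention; the marker positions
#' (phosphate 1079, Amide II 1544, Amide I 1658, ester carbonyl 1765, and a
#' PTFE-like C-F band at 1213 cm^-1) are standard fingerprint assignments.
#'
#' @param components named list of data frames (`center`, `width`, `peak`).
#' @return A `SpectralLibrary`.
#' @seealso [defaultSpectralLibrary()], [evalSpectrum()]
#' @export
SpectralLibrary <- function(components) {
  new("SpectralLibrary", components = components)
}

#' @rdname SpectralLibrary
#' @export
setClass("SpectralLibrary", representation(components = "list"),
  validity = function(object) {
    if (length(object@components) < 1L) return("library must not be empty")
    if (is.null(names(object@components)) || any(!nzchar(names(object@components))))
      return("components must be named")
    for (nm in names(object@components)) {
      comp <- object@components[[nm]]
      if (!is.data.frame(comp) || !all(c("center", "width", "peak") %in% names(comp)))
        return(sprintf("component '%s' must have columns center/width/peak", nm))
      if (any(comp$peak < 0)) return(sprintf("component '%s' has negative peak", nm))
      if (any(comp$width <= 0)) return(sprintf("component '%s' has nonpositive width", nm))
    }
    TRUE
  })

# -------------------------------------------------------------------- scansim

#' Raw detector frame
#'
#' A 2-D detector intensity image at one wavenumber, with the acquisition
#' state needed for coaddition buffering.
#'
#' @param data finite numeric matrix of detector intensities.
#' @param bandCm1 wavenumber of the frame.
#' @param configName label of the acquiring configuration.
#' @param coadditions number of frames averaged into this one.
#' @param lineOffsetPx applied forward/reverse line misregistration (truth;
#'   NA when unknown).
#' @param stateToken acquisition-state fingerprint; frames are only co-added
#'   while it is unchanged.
#' @return A `Frame`.
#' @export
Frame <- function(data, bandCm1, configName = "unknown", coadditions = 1L,
                  lineOffsetPx = NA_real_, stateToken = NULL) {
  if (is.null(stateToken))
    stateToken <- paste(configName, bandCm1, nrow(data), ncol(data), sep = "|")
  new("Frame", data = data, bandCm1 = as.numeric(bandCm1),
      configName = as.character(configName), coadditions = as.integer(coadditions),
      lineOffsetPx = as.numeric(lineOffsetPx), stateToken = as.character(stateToken))
}

#' @rdname Frame
#' @export
setClass("Frame", representation(
  data = "matrix", bandCm1 = "numeric", configName = "character",
  coadditions = "integer", lineOffsetPx = "numeric", stateToken = "character"),
  validity = function(object) {
    if (any(!is.finite(object@data))) return("frame data must be finite")
    if (object@coadditions < 1L) return("coadditions must be >= 1")
    TRUE
  })

#' Band-dependent relative-noise model
#'
#' Relative intensity noise as a function of wavenumber: a flat baseline,
#' amplified toward the detector cutoff on the low-wavenumber side, with
#' localized excess at the low-power transition bands of a multi-module
#' laser, plus an additive detector-floor term.
#'
#' @param baseRelSigma baseline relative intensity noise (fraction).
#' @param cutoffCm1 detector cutoff wavenumber; below it the multiplicative
#'   noise is amplified by `cutoffScale`.
#' @param cutoffScale amplification factor at/below the cutoff (>= 1).
#' @param cutoffRolloffCm1 width over which the amplification decays back to
#'   1 above the cutoff.
#' @param transitionBandsCm1 sorted wavenumbers of laser module transitions.
#' @param transitionRelSigma excess relative noise at a transition band; it
#'   falls linearly to zero within +/- 10 cm^-1.
#' @param additiveSigma additive detector-floor noise (detector units).
#' @return A `NoiseModel`.
#' @seealso [sigmaAt()]
#' @export
NoiseModel <- function(baseRelSigma = 0.005, cutoffCm1 = 900,
                       cutoffScale = 3, cutoffRolloffCm1 = 150,
                       transitionBandsCm1 = c(1030, 1310, 1610),
                       transitionRelSigma = 0.01, additiveSigma = 0) {
  new("NoiseModel", baseRelSigma = as.numeric(baseRelSigma),
      cutoffCm1 = as.numeric(cutoffCm1), cutoffScale = as.numeric(cutoffScale),
      cutoffRolloffCm1 = as.numeric(cutoffRolloffCm1),
      transitionBandsCm1 = as.numeric(sort(transitionBandsCm1)),
      transitionRelSigma = as.numeric(transitionRelSigma),
      additiveSigma = as.numeric(additiveSigma))
}

#' @rdname NoiseModel
#' @export
setClass("NoiseModel", representation(
  baseRelSigma = "numeric", cutoffCm1 = "numeric", cutoffScale = "numeric",
  cutoffRolloffCm1 = "numeric", transitionBandsCm1 = "numeric",
  transitionRelSigma = "numeric", additiveSigma = "numeric"),
  validity = function(object) {
    if (object@baseRelSigma < 0 || object@transitionRelSigma < 0 ||
        object@additiveSigma < 0) return("noise magnitudes must be >= 0")
    if (object@cutoffScale < 1) return("cutoffScale must be >= 1")
    if (object@cutoffRolloffCm1 <= 0) return("cutoffRolloffCm1 must be > 0")
    if (is.unsorted(object@transitionBandsCm1)) return("transition list must be sorted")
    TRUE
  })

#' Circular frame-history buffer
#'
#' Holds the most recent frames sharing one acquisition state; a state change
#' flushes the buffer so frames acquired under different conditions are never
#' blurred together.  See [pushAndAverage()].
#'
#' @param capacity maximum number of stored frames.
#' @return An empty `FrameBuffer`.
#' @export
FrameBuffer <- function(capacity = 16L) {
  new("FrameBuffer", capacity = as.integer(capacity), frames = list(),
      stateToken = NA_character_)
}

#' @rdname FrameBuffer
#' @export
setClass("FrameBuffer", representation(
  capacity = "integer", frames = "list", stateToken = "character"),
  validity = function(object) {
    if (object@capacity < 1L) return("capacity must be >= 1")
    if (length(object@frames) > object@capacity)
      return("buffer holds more frames than its capacity")
    TRUE
  })

# --------------------------------------------------------------------- mosaic

#' Tile-grid plan for whole-slide mosaicking
#'
#' Tile origins (micrometres), the tile field-of-view edge, the nominal
#' overlap fraction and the grid shape.  Produced by [planTiles()]; the last
#' row/column is shifted inward so tiles never exceed the requested area.
#'
#' @export
setClass("TilePlan", representation(
  originsUm = "matrix", tileFovUm = "numeric", overlap = "numeric",
  gridShape = "integer"),
  validity = function(object) {
    if (ncol(object@originsUm) != 2L) return("originsUm must have two columns (x, y)")
    if (nrow(object@originsUm) != prod(object@gridShape))
      return("origin count must equal prod(gridShape)")
    if (object@overlap < 0 || object@overlap >= 1) return("overlap must be in [0, 1)")
    if (object@tileFovUm <= 0) return("tileFovUm must be > 0")
    TRUE
  })

# ------------------------------------------------------------------ metrics_qa

#' Slant-edge analysis result
#'
#' Estimated edge slant, the oversampled edge-spread function, the windowed
#' line-spread function, and the resulting [MTFCurve].  Produced by
#' [slantEdgeMtf()].
#'
#' @export
setClass("EdgeAnalysis", representation(
  edgeAngleDeg = "numeric", esf = "numeric", lsf = "numeric",
  mtf = "MTFCurve", oversampling = "integer"),
  validity = function(object) {
    if (object@oversampling < 4L) return("oversampling must be >= 4")
    TRUE
  })

#' Per-band noise and SNR summary
#'
#' @param bandCm1 wavenumber (cm^-1).
#' @param rms100pctLine RMS absorbance of the 100 percent line (a.u.).
#' @param spatialNoise pixelwise noise estimate (a.u.).
#' @param snr signal-to-noise ratio.
#' @param coadditions number of co-added frames.
#' @return A `NoiseReport`.
#' @export
NoiseReport <- function(bandCm1, rms100pctLine = NA_real_,
                        spatialNoise = NA_real_, snr = NA_real_,
                        coadditions = 1L) {
  new("NoiseReport", bandCm1 = as.numeric(bandCm1),
      rms100pctLine = as.numeric(rms100pctLine),
      spatialNoise = as.numeric(spatialNoise), snr = as.numeric(snr),
      coadditions = as.integer(coadditions))
}

#' @rdname NoiseReport
#' @export
setClass("NoiseReport", representation(
  bandCm1 = "numeric", rms100pctLine = "numeric", spatialNoise = "numeric",
  snr = "numeric", coadditions = "integer"),
  validity = function(object) {
    vals <- c(object@rms100pctLine, object@spatialNoise, object@snr)
    if (any(vals[!is.na(vals)] < 0)) return("noise/SNR values must be >= 0")
    TRUE
  })

# -------------------------------------------------------------- multispectral

#' Serial-section volume
#'
#' A (slice, row, col) stack of aligned absorbance images, the slice spacing,
#' and the per-slice rigid shifts that were applied during assembly.
#' Out-of-frame samples introduced by alignment are `NA`.
#'
#' @seealso [assembleVolume()], [crossSection()]
#' @export
setClass("Volume", representation(
  data = "array", zSpacingUm = "numeric", transforms = "matrix"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a (slice, row, col) array")
    if (d[1] < 1L) return("volume must contain at least one slice")
    if (!is.finite(object@zSpacingUm) || object@zSpacingUm <= 0)
      return("zSpacingUm must be > 0")
    if (nrow(object@transforms) != d[1])
      return("transforms length must equal slice count")
    TRUE
  })
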