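# Accessor generics.  Slot access outside the package should go through
# these rather than `@`.

#' Wavenumber bands of an object
#' @param x a `SpectralAxis`, `HyperCube` or `Scene`.
#' @return numeric vector of wavenumbers (cm^-1).
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))

#' @rdname bands
#' @export
setMethod("bands", "SpectralAxis", function(x) x@bands)
#' @rdname bands
#' @export
setMethod("bands", "HyperCube", function(x) x@axis@bands)
#' @rdname bands
#' @export
setMethod("bands", "Scene", function(x) x@axis@bands)

#' Sample-plane pixel size (micrometres per pixel)
#' @param x an object carrying a sampling grid.
#' @return pixel size in micrometres.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "HyperCube", function(x) x@pixelSizeUm)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Scene", function(x) x@pixelSizeUm)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "InstrumentConfig", function(x) x@pixelSizeUm)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "PSFKernel", function(x) x@pixelSizeUm)

#' Absorbance array of a cube
#' @param x a `HyperCube`.
#' @return numeric (row, col, band) array.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname cubeData
#' @export
setMethod("cubeData", "HyperCube", function(x) x@data)

#' Provenance metadata of a cube
#' @param x a `HyperCube`.
#' @return named list.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "HyperCube", function(x) x@provenance)

#' Class-label image of a scene
#' @param x a `Scene`.
#' @return integer matrix of class labels.
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))

#' @rdname classMap
#' @export
setMethod("classMap", "Scene", function(x) x@classMap)

#' Ground-truth geometry metadata of a scene
#' @param x a `Scene`.
#' @return named list recorded by the generating phantom.
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @rdname sceneTruth
#' @export
setMethod("sceneTruth", "Scene", function(x) x@truth)

#' PSF intensity samples
#' @param x a `PSFKernel`.
#' @return numeric matrix summing to 1.
#' @export
setGeneric("psfSamples", function(x) standardGeneric("psfSamples"))

#' @rdname psfSamples
#' @export
setMethod("psfSamples", "PSFKernel", function(x) x@samples)

#' Frequencies and modulation of an MTF curve
#' @param x an `MTFCurve` or `EdgeAnalysis`.
#' @return for `mtfFreq`, frequencies in cycles per micrometre; for
#'   `mtfModulation`, the contrast at those frequencies.
#' @export
setGeneric("mtfFreq", function(x) standardGeneric("mtfFreq"))

#' @rdname mtfFreq
#' @export
setGeneric("mtfModulation", function(x) standardGeneric("mtfModulation"))

#' @rdname mtfFreq
#' @export
setMethod("mtfFreq", "MTFCurve", function(x) x@freqCycPerUm)
#' @rdname mtfFreq
#' @export
setMethod("mtfModulation", "MTFCurve", function(x) x@modulation)
#' @rdname mtfFreq
#' @export
setMethod("mtfFreq", "EdgeAnalysis", function(x) x@mtf@freqCycPerUm)
#' @rdname mtfFreq
#' @export
setMethod("mtfModulation", "EdgeAnalysis", function(x) x@mtf@modulation)

#' Frame pixel data
#' @param x a `Frame`.
#' @return numeric matrix of detector intensities (or absorbance).
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))

#' @rdname frameData
#' @export
setMethod("frameData", "Frame", function(x) x@data)

#' Single-frame field of view edge length (micrometres)
#' @param cfg an `InstrumentConfig`.
#' @return `tilePx * pixelSizeUm` in micrometres.
#' @export
fovUm <- function(cfg) {
  stopifnot(is(cfg, "InstrumentConfig"))
  cfg@tilePx * cfg@pixelSizeUm
}

#' Volume data and slice spacing
#' @param x a `Volume`.
#' @return for `volumeData`, the (slice, row, col) array; for `zSpacing`,
#'   the slice spacing in micrometres; for `volumeTransforms`, the per-slice
#'   (dy, dx) shifts that were undone during assembly.
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname volumeData
#' @export
setGeneric("zSpacing", function(x) standardGeneric("zSpacing"))

#' @rdname volumeData
#' @export
setGeneric("volumeTransforms", function(x) standardGeneric("volumeTransforms"))

#' @rdname volumeData
#' @export
setMethod("volumeData", "Volume", function(x) x@data)
#' @rdname volumeData
#' @export
setMethod("zSpacing", "Volume", function(x) x@zSpacingUm)
#' @rdname volumeData
#' @export
setMethod("volumeTransforms", "Volume", function(x) x@transforms)

# ----------------------------------------------------------------- show methods

setMethod("show", "SpectralAxis", function(object) {
  b <- object@bands
  cat(sprintf("SpectralAxis: %d band(s), %.0f-%.0f cm-1\n",
              length(b), min(b), max(b)))
})

setMethod("show", "InstrumentConfig", function(object) {
  cat(sprintf("InstrumentConfig '%s': %gx/%.2f NA, %g um/px, %d px tile (FOV %g um)\n",
              object@name, object@magnification, object@na, object@pixelSizeUm,
              object@tilePx, fovUm(object)))
  cat(sprintf("  pixel rate %g Hz, scan duty %.2f, laser duty %.2f, pinhole %g um (Mdet %g)\n",
              object@pixelRateHz, object@scanDuty, object@laserDuty,
              object@pinholeDiameterUm, object@detectionMagnification))
  if (object@obscuration > 0 || object@illuminationPupilFraction > 0)
    cat(sprintf("  obscuration %.2f, illumination pupil block %.2f\n",
                object@obscuration, object@illuminationPupilFraction))
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube: %d x %d px, %d band(s), %g um/px\n",
              d[1], d[2], d[3], object@pixelSizeUm))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

setMethod("show", "Scene", function(object) {
  d <- dim(object@absorbance)
  cat(sprintf("Scene '%s': %d x %d px, %d band(s), %g um/px\n",
              if (!is.null(object@truth$type)) object@truth$type else "custom",
              d[1], d[2], d[3], object@pixelSizeUm))
})

setMethod("show", "PSFKernel", function(object) {
  cat(sprintf("PSFKernel: %d x %d samples at %g um/px (%s)\n",
              nrow(object@samples), ncol(object@samples),
              object@pixelSizeUm, object@normalization))
})

setMethod("show", "MTFCurve", function(object) {
  cat(sprintf("MTFCurve: %d frequencies up to %.4g cyc/um",
              length(object@freqCycPerUm), max(object@freqCycPerUm)))
  if (!is.null(object@meta$estimator)) cat(" [", object@meta$estimator, "]", sep = "")
  cat("\n")
})

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame: %d x %d px at %g cm-1, %d coaddition(s) [%s]\n",
              nrow(object@data), ncol(object@data), object@bandCm1,
              object@coadditions, object@configName))
})

setMethod("show", "FrameBuffer", function(object) {
  cat(sprintf("FrameBuffer: %d/%d frame(s), state '%s'\n",
              length(object@frames), object@capacity, object@stateToken))
})

setMethod("show", "TilePlan", function(object) {
  cat(sprintf("TilePlan: %d x %d grid (%d tiles), tile FOV %g um, overlap %.2f\n",
              object@gridShape[1], object@gridShape[2], nrow(object@originsUm),
              object@tileFovUm, object@overlap))
})

setMethod("show", "EdgeAnalysis", function(object) {
  cat(sprintf("EdgeAnalysis: slant %.2f deg, %dx oversampled ESF (%d bins)\n",
              object@edgeAngleDeg, object@oversampling, length(object@esf)))
})

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume: %d slice(s) of %d x %d px, z spacing %g um (extent %g um)\n",
              d[1], d[2], d[3], object@zSpacingUm, d[1] * object@zSpacingUm))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: base sigma %.4g, cutoff %g cm-1 (x%.2g), %d transition band(s)\n",
              object@baseRelSigma, object@cutoffCm1, object@cutoffScale,
              length(object@transitionBandsCm1)))
})

setMethod("show", "NoiseReport", function(object) {
  cat(sprintf("NoiseReport @ %g cm-1: 100%%-line RMS %.4g, spatial %.4g, SNR %.4g (n=%d)\n",
              object@bandCm1, object@rms100pctLine, object@spatialNoise,
              object@snr, object@coadditions))
})

#' Ground-truth absorbance map of a scene at one band
#' @param x a `Scene`.
#' @param bandCm1 wavenumber; must match a scene band within `tolCm1`.
#' @param tolCm1 nearest-band matching tolerance in cm^-1.
#' @return numeric matrix of absorbance (a.u.).
#' @export
setGeneric("sceneMap", function(x, bandCm1, tolCm1 = 4) standardGeneric("sceneMap"))

#' @rdname sceneMap
#' @export
setMethod("sceneMap", "Scene", function(x, bandCm1, tolCm1 = 4) {
  i <- which.min(abs(x@axis@bands - bandCm1))
  if (abs(x@axis@bands[i] - bandCm1) > tolCm1)
    stop(sprintf("no scene band within %g cm-1 of %g (nearest: %g)",
                 tolCm1, bandCm1, x@axis@bands[i]))
  x@absorbance[, , i]
})
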