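# Configuration presets, config-file round trips, hyperspectral cube I/O and
# throughput/FOV planning calculators.

#' Built-in instrument configurations
#'
#' Three presets: the two point-scanning configurations (`"lsm10x"`:
#' 10x/0.4 NA at 2 um/px, and `"lsm20x"`: 20x/0.8 NA at 1 um/px, both
#' 500 px tiles at a 1 MHz pixel rate with ~93 % scan duty and a 100 um
#' detection pinhole) and a widefield FT-IR comparator (`"ftir"`:
#' 15x/0.62 NA Schwarzschild-style reflective objective, 1.1 um/px,
#' 128 px focal-plane-array tile, with a central obscuration and a
#' fold-mirror illumination block).
#'
#' The comparator's obscuration ratio (0.3) and illumination half-plane
#' fraction (0.3) are free modelling parameters of the reflective objective,
#' not measured values; both can be overridden by building an
#' [InstrumentConfig()] directly.
#'
#' @param name one of `"lsm10x"`, `"lsm20x"`, `"ftir"`.
#' @return An [InstrumentConfig()].
#' @examples
#' instrumentPreset("lsm10x")
#' @export
instrumentPreset <- function(name = c("lsm10x", "lsm20x", "ftir")) {
  name <- match.arg(name)
  switch(name,
    lsm10x = InstrumentConfig(
      name = "lsm10x", na = 0.4, magnification = 10, pixelSizeUm = 2,
      tilePx = 500L, pixelRateHz = 1e6, laserDuty = 0.04, scanDuty = 0.93,
      pinholeDiameterUm = 100, detectionMagnification = 5,
      spectralRangeCm1 = c(777, 1904)),
    lsm20x = InstrumentConfig(
      name = "lsm20x", na = 0.8, magnification = 20, pixelSizeUm = 1,
      tilePx = 500L, pixelRateHz = 1e6, laserDuty = 0.04, scanDuty = 0.93,
      pinholeDiameterUm = 100, detectionMagnification = 10,
      spectralRangeCm1 = c(777, 1904)),
    ftir = InstrumentConfig(
      name = "ftir", na = 0.62, magnification = 15, pixelSizeUm = 1.1,
      tilePx = 128L, pixelRateHz = 1e5, laserDuty = 1, scanDuty = 1,
      pinholeDiameterUm = 0, detectionMagnification = 1,
      obscuration = 0.3, illuminationPupilFraction = 0.3,
      spectralRangeCm1 = c(800, 3950)))
}

# field names used in YAML config files (snake_case on disk)
.cfgFields <- c(
  name = "name", na = "na", magnification = "magnification",
  pixel_size_um = "pixelSizeUm", tile_px = "tilePx",
  pixel_rate_hz = "pixelRateHz", laser_duty = "laserDuty",
  scan_duty = "scanDuty", pinhole_diameter_um = "pinholeDiameterUm",
  detection_magnification = "detectionMagnification",
  obscuration = "obscuration",
  illumination_pupil_fraction = "illuminationPupilFraction",
  spectral_range_cm1 = "spectralRangeCm1")

#' Read or write an instrument configuration file
#'
#' Configurations are stored as flat YAML with snake_case keys.  Loading
#' validates every field and names the offending field on error;
#' `loadConfig(saveConfig(cfg))` reproduces the configuration field by field.
#'
#' @param path file path of the YAML configuration.
#' @param cfg an [InstrumentConfig()] to write.
#' @return `loadConfig` returns a validated [InstrumentConfig()];
#'   `saveConfig` invisibly returns `path`.
#' @examples
#' p <- tempfile(fileext = ".yml")
#' saveConfig(instrumentPreset("lsm10x"), p)
#' loadConfig(p)
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  missing <- setdiff(names(.cfgFields), names(vals))
  if (length(missing))
    stop("missing config field(s): ", paste(missing, collapse = ", "))
  args <- lapply(names(.cfgFields), function(f) vals[[f]])
  names(args) <- unname(.cfgFields)
  tryCatch(do.call(InstrumentConfig, args),
           error = function(e) stop("invalid config: ", conditionMessage(e)))
}

#' @rdname loadConfig
#' @export
saveConfig <- function(cfg, path) {
  stopifnot(is(cfg, "InstrumentConfig"))
  vals <- lapply(unname(.cfgFields), function(s) slot(cfg, s))
  names(vals) <- names(.cfgFields)
  vals$tile_px <- as.integer(vals$tile_px)
  yaml::write_yaml(vals, path)
  invisible(path)
}

# ------------------------------------------------------------------ cube I/O

# ENVI data type 4 = 32-bit float, band sequential, little endian.
.enviHeader <- function(cube, datFile) {
  d <- dim(cube@data)
  c("ENVI",
    sprintf("description = {%s}",
            jsonlite::toJSON(cube@provenance, auto_unbox = TRUE)),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = wavenumber (cm-1)",
    sprintf("pixel size = {%.10g, %.10g}", cube@pixelSizeUm, cube@pixelSizeUm),
    sprintf("origin um = {%.10g, %.10g}", cube@originUm[1], cube@originUm[2]),
    sprintf("wavelength = {%s}", paste(format(cube@axis@bands, digits = 10),
                                       collapse = ", ")))
}

#' Write and read hyperspectral absorbance cubes
#'
#' Two on-disk representations are supported.  `"envi"` writes a text header
#' (`<path>.hdr`) plus a band-sequential 32-bit IEEE-float binary
#' (`<path>.dat`) with the wavelength list recorded in cm^-1; this
#' round-trips bit-exactly at 32-bit float width.  `"tiff"` writes one
#' 32-bit page per band together with a JSON sidecar (`<path>.json`)
#' holding the band list and the power-of-two scale used to map the data
#' into the page range.  TIFF pages are stored as 32-bit fixed point over
#' `[offset, offset + scale]` (the sample format this TIFF backend
#' provides), so a round trip reproduces every value within one 32-bit
#' quantization step (`scale * 2^-32`) of the original.
#'
#' Non-finite pixels encountered on ingestion are replaced by the band
#' median and reported via a message (deterministic, auditable repair).
#'
#' @param cube a [HyperCube()].
#' @param path destination path; extensions are added per format.
#' @param format `"envi"` or `"tiff"`.
#' @return `writeCube` invisibly returns the files written; `readCube`
#'   returns a [HyperCube()].
#' @examples
#' cube <- HyperCube(array(runif(12), c(2, 2, 3)),
#'                   SpectralAxis(c(1079, 1658, 1765)), pixelSizeUm = 2)
#' p <- tempfile()
#' writeCube(cube, p, "envi")
#' all.equal(cubeData(readCube(p, "envi")), cubeData(cube), tolerance = 1e-7)
#' @export
writeCube <- function(cube, path, format = c("envi", "tiff")) {
  stopifnot(is(cube, "HyperCube"))
  format <- match.arg(format)
  d <- dim(cube@data)
  if (format == "envi") {
    hdr <- paste0(path, ".hdr"); dat <- paste0(path, ".dat")
    writeLines(.enviHeader(cube, dat), hdr)
    con <- file(dat, "wb")
    on.exit(close(con))
    # BSQ: per band, lines of samples in row-major order
    for (b in seq_len(d[3]))
      writeBin(as.numeric(t(cube@data[, , b])), con, size = 4L,
               endian = "little")
    invisible(c(hdr, dat))
  } else {
    tf <- paste0(path, ".tif"); side <- paste0(path, ".json")
    lo <- min(cube@data); hi <- max(cube@data)
    offset <- if (lo < 0) lo else 0
    span <- max(hi - offset, .Machine$double.xmin)
    scale <- 2^ceiling(log2(span))       # power of two: exact in binary FP
    pages <- lapply(seq_len(d[3]), function(b)
      (cube@data[, , b] - offset) / scale)
    suppressWarnings(
      tiff::writeTIFF(pages, tf, bits.per.sample = 32L, compression = "none",
                      reduce = FALSE))
    meta <- list(bands_cm1 = cube@axis@bands, pixel_size_um = cube@pixelSizeUm,
                 origin_um = cube@originUm, scale = scale, offset = offset,
                 provenance = cube@provenance)
    jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
    invisible(c(tf, side))
  }
}

#' @rdname writeCube
#' @export
readCube <- function(path, format = c("envi", "tiff")) {
  format <- match.arg(format)
  if (format == "envi") {
    hdr <- paste0(path, ".hdr"); dat <- paste0(path, ".dat")
    if (!file.exists(hdr)) stop("header not found: ", hdr)
    lines <- readLines(hdr, warn = FALSE)
    getNum <- function(key) {
      m <- grep(sprintf("^%s *=", key), lines, value = TRUE)
      if (!length(m)) stop("ENVI header misses '", key, "'")
      as.numeric(sub(".*= *", "", m[1]))
    }
    getList <- function(key) {
      txt <- paste(lines, collapse = "\n")
      m <- regmatches(txt, regexpr(sprintf("%s *= *\\{[^}]*\\}", key), txt))
      if (!length(m)) stop("ENVI header misses '", key, "'")
      as.numeric(strsplit(gsub(".*\\{|\\}", "", m), ",")[[1]])
    }
    ns <- getNum("samples"); nl <- getNum("lines"); nb <- getNum("bands")
    wl <- getList("wavelength")
    px <- getList("pixel size")[1]
    org <- tryCatch(getList("origin um"), error = function(e) c(0, 0))
    prov <- list()
    dm <- grep("^description *=", lines, value = TRUE)
    if (length(dm))
      prov <- tryCatch(
        jsonlite::fromJSON(gsub("^description *= *\\{|\\}$", "", dm[1])),
        error = function(e) list())
    con <- file(dat, "rb")
    on.exit(close(con))
    raw <- readBin(con, "numeric", n = ns * nl * nb, size = 4L,
                   endian = "little")
    arr <- array(NA_real_, c(nl, ns, nb))
    for (b in seq_len(nb))
      arr[, , b] <- matrix(raw[(b - 1) * ns * nl + seq_len(ns * nl)],
                           nl, ns, byrow = TRUE)
  } else {
    tf <- paste0(path, ".tif"); side <- paste0(path, ".json")
    if (!file.exists(side)) stop("TIFF sidecar not found: ", side)
    meta <- jsonlite::fromJSON(side)
    pages <- tiff::readTIFF(tf, all = TRUE)
    arr <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
    for (b in seq_along(pages))
      arr[, , b] <- pages[[b]] * meta$scale + meta$offset
    wl <- meta$bands_cm1; px <- meta$pixel_size_um; org <- meta$origin_um
    prov <- if (is.null(meta$provenance)) list() else as.list(meta$provenance)
  }
  # deterministic repair of non-finite pixels
  for (b in seq_len(dim(arr)[3])) {
    bad <- !is.finite(arr[, , b])
    if (any(bad)) {
      med <- stats::median(arr[, , b][!bad])
      slab <- arr[, , b]; slab[bad] <- med; arr[, , b] <- slab
      message(sprintf("band %g cm-1: %d non-finite pixel(s) filled with band median",
                      wl[b], sum(bad)))
    }
  }
  HyperCube(arr, SpectralAxis(wl), pixelSizeUm = px, originUm = org,
            provenance = as.list(prov))
}

# ------------------------------------------------------- planning calculators

#' Field-of-view area fold-change between two configurations
#'
#' The ratio of single-frame field-of-view areas,
#' `(tilePx_a * pixelSize_a)^2 / (tilePx_b * pixelSize_b)^2`.
#'
#' @param cfgA,cfgB [InstrumentConfig()] objects.
#' @return dimensionless fold-change.
#' @examples
#' fovAreaRatio(instrumentPreset("lsm10x"), instrumentPreset("ftir"))
#' @export
fovAreaRatio <- function(cfgA, cfgB) {
  stopifnot(is(cfgA, "InstrumentConfig"), is(cfgB, "InstrumentConfig"))
  a <- fovUm(cfgA)^2; b <- fovUm(cfgB)^2
  if (a == 0 || b == 0) stop("zero-area configuration")
  a / b
}

#' Seconds per displayed tile
#'
#' `coadditions * tilePx^2 / (pixelRateHz * scanDuty)`: one laser shot per
#' pixel, slowed by the raster duty cycle and multiplied by the number of
#' co-added frames.
#'
#' @param cfg an [InstrumentConfig()].
#' @param coadditions number of co-added frames, >= 1.
#' @return time in seconds for one displayed tile.
#' @examples
#' frameTime(instrumentPreset("lsm10x"))       # ~0.27 s -> ~3.7 Hz
#' @export
frameTime <- function(cfg, coadditions = 1) {
  stopifnot(is(cfg, "InstrumentConfig"))
  if (coadditions < 1) stop("'coadditions' must be >= 1")
  coadditions * as.numeric(cfg@tilePx)^2 / (cfg@pixelRateHz * cfg@scanDuty)
}

#' Predicted whole-slide scan time
#'
#' Number of tiles from [planTiles()] times per-tile time (frame time plus a
#' per-tile overhead) times the number of spectral bands.  The default
#' overhead is zero, which makes the prediction a lower bound: real systems
#' add stage-settling and laser-tuning time per tile that is not published,
#' so it is surfaced as a parameter rather than silently calibrated.
#'
#' @param cfg an [InstrumentConfig()].
#' @param areaMm length-2 numeric, scan area (width, height) in millimetres.
#' @param overlap tile overlap fraction in [0, 1).
#' @param coadditions co-added frames per tile.
#' @param nBands number of discrete bands acquired.
#' @param perTileOverheadS extra seconds per tile (stage move, settling).
#' @return predicted total seconds.
#' @examples
#' scanTime(instrumentPreset("lsm10x"), c(15, 15)) / 60   # minutes per band
#' @export
scanTime <- function(cfg, areaMm, overlap = 0.1, coadditions = 2,
                     nBands = 1, perTileOverheadS = 0) {
  stopifnot(is(cfg, "InstrumentConfig"))
  if (overlap >= 1 || overlap < 0) stop("'overlap' must be in [0, 1)")
  if (nBands < 1) stop("'nBands' must be >= 1")
  plan <- planTiles(areaMm, cfg, overlap)
  nTiles <- nrow(plan@originsUm)
  nTiles * (frameTime(cfg, coadditions) + perTileOverheadS) * nBands
}

#' Wavelength bandwidth of a wavenumber range
#'
#' Converts a tunable range in cm^-1 to its wavelength extent in
#' micrometres, `1e4/min - 1e4/max`.  Useful for comparing the mid-infrared
#' fingerprint bandwidth against the visible spectrum.
#'
#' @param rangeCm1 length-2 positive numeric (cm^-1).
#' @return bandwidth in micrometres.
#' @examples
#' wavelengthBandwidthUm(c(690, 4000))   # mid-IR, ~12 um
#' @export
wavelengthBandwidthUm <- function(rangeCm1) {
  if (length(rangeCm1) != 2L || any(rangeCm1 <= 0))
    stop("'rangeCm1' must be two positive wavenumbers")
  abs(1e4 / min(rangeCm1) - 1e4 / max(rangeCm1))
}
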