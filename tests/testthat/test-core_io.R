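# Configurations, cube I/O and throughput/FOV calculators.

test_that("presets carry the instrument geometries and invalid fields are named", {
  l10 <- instrumentPreset("lsm10x")
  expect_equal(l10@na, 0.4)
  expect_equal(pixelSize(l10), 2)
  expect_equal(l10@tilePx, 500L)
  expect_equal(fovUm(l10), 1000)                 # 1 x 1 mm tile
  ft <- instrumentPreset("ftir")
  expect_equal(ft@na, 0.62)
  expect_equal(pixelSize(ft), 1.1)
  expect_equal(ft@tilePx, 128L)
  expect_gt(ft@obscuration, 0)
  expect_gt(ft@illuminationPupilFraction, 0)
  expect_error(InstrumentConfig("bad", na = 1.5, magnification = 10,
                                pixelSizeUm = 2, tilePx = 500L,
                                pixelRateHz = 1e6), "na")
  expect_error(InstrumentConfig("bad", na = 0.4, magnification = 10,
                                pixelSizeUm = 2, tilePx = 500L,
                                pixelRateHz = 1e6, scanDuty = 0), "scanDuty")
})

test_that("config files round trip field by field and report missing fields", {
  p <- tempfile(fileext = ".yml")
  for (nm in c("lsm10x", "lsm20x", "ftir")) {
    cfg <- instrumentPreset(nm)
    saveConfig(cfg, p)
    expect_true(isTRUE(all.equal(loadConfig(p), cfg)))
  }
  vals <- yaml::read_yaml(p)
  vals$na <- NULL
  yaml::write_yaml(vals, p)
  expect_error(loadConfig(p), "na")
  expect_error(loadConfig(tempfile()), "not found")
})

test_that("ENVI cubes round trip bit-exactly at 32-bit float width", {
  ax <- SpectralAxis(c(1079, 1658, 1765))
  set.seed(11)
  cube <- HyperCube(array(runif(2 * 2 * 3, 0, 2), c(2, 2, 3)), ax, 2,
                    originUm = c(10, 20),
                    provenance = list(config = "lsm10x", seed = 11))
  p <- file.path(tempdir(), "cube_envi")
  writeCube(cube, p, "envi")
  back <- readCube(p, "envi")
  expect_identical(as.vector(cubeData(back)), f32(as.vector(cubeData(cube))))
  expect_equal(bands(back), bands(cube))
  expect_equal(pixelSize(back), 2)
  expect_equal(back@originUm, c(10, 20))
  expect_equal(provenance(back)$config, "lsm10x")
})

test_that("TIFF cubes round trip within one 32-bit quantization step", {
  ax <- SpectralAxis(c(1079, 1658, 1765))
  set.seed(12)
  cube <- HyperCube(array(runif(2 * 2 * 3, 0, 2), c(2, 2, 3)), ax, 2)
  p <- file.path(tempdir(), "cube_tiff")
  writeCube(cube, p, "tiff")
  back <- readCube(p, "tiff")
  meta <- jsonlite::fromJSON(paste0(p, ".json"))
  expect_lte(max(abs(cubeData(back) - cubeData(cube))), meta$scale * 2^-32)
  expect_equal(bands(back), bands(cube))
})

test_that("degenerate cubes are rejected and non-finite pixels repaired on read", {
  expect_error(HyperCube(array(0, c(2, 2, 0)), SpectralAxis(1658), 2))
  expect_error(writeCube(matrix(0, 2, 2), tempfile(), "envi"))
  # corrupt one pixel to NaN on disk, expect median fill + message
  ax <- SpectralAxis(c(1079, 1658))
  cube <- HyperCube(array(seq_len(8) / 4, c(2, 2, 2)), ax, 2)
  p <- file.path(tempdir(), "cube_nan")
  writeCube(cube, p, "envi")
  con <- file(paste0(p, ".dat"), "r+b")
  writeBin(NaN, con, size = 4L, endian = "little")
  close(con)
  expect_message(back <- readCube(p, "envi"), "non-finite")
  expect_true(all(is.finite(cubeData(back))))
})

test_that("FOV area ratios follow the printed tile geometries", {
  # 20x: 0.5 x 0.5 mm tile against the printed 141 um comparator tile
  mk <- function(tile, px) InstrumentConfig("t", 0.62, 15, px, tile, 1e5)
  l20 <- instrumentPreset("lsm20x")
  ftPrinted <- mk(141L, 1)
  expect_equal(fovAreaRatio(l20, ftPrinted), 250000 / 19881, tolerance = 1e-12)
  l10 <- instrumentPreset("lsm10x")
  expect_equal(fovAreaRatio(l10, ftPrinted), 1e6 / 19881, tolerance = 1e-12)
  expect_equal(fovAreaRatio(l10, l10), 1)
  # inverse-product property
  ft <- instrumentPreset("ftir")
  expect_equal(fovAreaRatio(l10, ft) * fovAreaRatio(ft, l10), 1,
               tolerance = 1e-14)
})

test_that("frame time follows the pixel rate and duty cycle", {
  l10 <- instrumentPreset("lsm10x")
  expect_equal(frameTime(l10, 1), 500^2 / (1e6 * 0.93), tolerance = 1e-12)
  expect_equal(1 / frameTime(l10, 1), 3.72, tolerance = 1e-12)  # ~4 Hz
  expect_equal(frameTime(l10, 2), 2 * frameTime(l10, 1))
  tiny <- InstrumentConfig("t", 0.4, 10, 2, 1L, 1e6, scanDuty = 1)
  expect_equal(frameTime(tiny, 1), 1e-6)
  expect_error(frameTime(l10, 0), "coadditions")
})

test_that("scan time composes tiles, coadditions and bands", {
  l10 <- instrumentPreset("lsm10x")
  t1 <- scanTime(l10, c(15, 15), overlap = 0.1, coadditions = 2, nBands = 1)
  expect_equal(t1, 289 * 2 * 500^2 / (1e6 * 0.93), tolerance = 1e-12)  # 155.4 s
  # single-FOV area
  expect_equal(scanTime(l10, c(1, 1), 0.1, 1, 3), 3 * frameTime(l10, 1))
  # linear in bands, monotone in area/coadds/overlap
  expect_equal(scanTime(l10, c(15, 15), 0.1, 2, 10), 10 * t1)
  expect_gte(scanTime(l10, c(20, 15), 0.1, 2, 1), t1)
  expect_gte(scanTime(l10, c(15, 15), 0.2, 2, 1), t1)
  expect_gte(scanTime(l10, c(15, 15), 0.1, 4, 1), t1)
  expect_error(scanTime(l10, c(15, 15), overlap = 1), "overlap")
})

test_that("wavelength bandwidth converts wavenumber ranges", {
  expect_equal(wavelengthBandwidthUm(c(1000, 2000)), 5)
  expect_equal(wavelengthBandwidthUm(c(690, 4000)), 1e4 / 690 - 1e4 / 4000)
  expect_error(wavelengthBandwidthUm(c(-1, 10)))
})
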