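# irlsm

A desk-scale digital twin of a discrete-frequency mid-infrared
laser-scanning confocal microscope (IR-LSM), together with the
image-quality and chemical-imaging analyses used to characterize such
instruments.

Mid-IR chemical imaging reads molecular contrast directly from vibrational
absorption — no stains, no labels — but historically at speeds and image
quality far below visible-light microscopy.  Point-scanning a tunable
quantum-cascade laser through refractive, full-aperture IR optics changes
that trade-off: diffraction-limited resolution, speckle-free images and
whole-slide coverage in minutes per wavenumber.  This package models that
acquisition chain end to end and implements the evaluation machinery
around it, for instrument builders who want to reason about design
choices (pinhole size, pupil obscuration, tile overlap, coadditions) and
for analysts who want estimators scored against exact ground truth.

The package covers, as S4 classes and camelCase functions:

* **Optics** — intensity PSFs and MTFs for clear, centrally obscured and
  half-blocked pupils; confocal detection through a finite pinhole.
  For a clear pupil the MTF is the pupil autocorrelation
  `(2/pi)(acos s - s sqrt(1 - s^2))` with cutoff `2 NA / lambda`,
  `lambda = 1e4 / nu` um; the first Airy null sits at `0.61 lambda / NA`.
* **Phantoms** — Siemens stars, slanted edges, tissue-like multispectral
  phantoms built from Gaussian bands at the standard fingerprint markers
  (phosphate 1079, Amide II 1544, Amide I 1658, ester 1765, PTFE 1213
  cm^-1), contaminant inclusions, serial-section blocks and a synthetic
  reference film — all pure functions of (parameters, seed) with exact
  truth metadata.
* **Scan simulation** — bidirectional raster acquisition with
  band-dependent multiplicative + additive noise, misregistered reverse
  lines and their image-domain correction, a state-aware coaddition
  buffer (noise falls as `1/sqrt(n)`), blank-substrate referencing
  (`A = -log10(S/B)`), and a widefield coherent comparator that produces
  fully developed speckle (contrast ~ 1) where the point-scan image shows
  only its noise floor.
* **Mosaicking** — tile planning with run-time overlap adjustment,
  feather-blended lossless stitching, tilt flattening.
* **QA metrics** — 100% lines (`RMS = sqrt(2) sigma / ln 10` for relative
  noise `sigma`), spatial noise, SNR, ISO 12233 slant-edge MTF,
  Siemens-star limiting resolution at the ~25% Rayleigh threshold,
  speckle contrast.
* **Multispectral analysis** — false-color composites (1079/1658/1765
  cm^-1 by default), robust median/MAD contaminant masking at 1213 cm^-1,
  phase-correlation serial-section registration and 3-D volume assembly.

## Worked example

Plan a whole-slide scan at the 10x/0.4 NA configuration, then measure the
resolution of the 20x/0.8 NA configuration on a simulated Siemens-star
acquisition:

```r
library(irlsm)

cfg <- instrumentPreset("lsm10x")
planTiles(c(15, 15), cfg, overlap = 0.1)
#> TilePlan: 17 x 17 grid (289 tiles), tile FOV 1000 um, overlap 0.10
frameTime(cfg)                     # 0.2688 s per tile, i.e. 3.72 Hz
scanTime(cfg, c(15, 15), 0.1, 2, 1) / 60
#> [1] 2.589606                     # minutes per band, zero overhead

star <- makeSiemensStar(72, 400, 1, amplitude = 0.1)
frame <- acquireFrame(star, 1658, instrumentPreset("lsm20x"),
                      psf(PupilSpec(0.8, 1658), 1))
A <- -log10(frameData(frame))      # referenced against a unit background
starResolution(A, star, threshold = 0.25, pixelSizeUm = 1)$limitFreqCycPerUm
#> [1] 0.1663071
mtfCrossing(mtf(PupilSpec(0.8, 1658)), 0.25)
#> [1] 0.1675527
```

The star read-out (0.166 cycles/um) lands within 1% of the diffraction
model's own 25%-modulation frequency (0.168 cycles/um): the simulated
instrument resolves what its pupil says it should.  The 17 x 17 plan, the
3.72 Hz frame rate and the 2.59 min/band prediction are the package's
zero-overhead throughput model; a per-tile overhead of ~44 ms (exposed as
a parameter, not baked in) brings the latter to 2.8 min/band.

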