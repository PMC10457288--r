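---
title: "Models and methods behind irlsm"
author: "irlsm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind irlsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irlsm)
```

# What the package models

`irlsm` is a desk-scale digital twin of a discrete-frequency mid-infrared
laser-scanning confocal microscope (IR-LSM): a tunable quantum-cascade-laser
source raster-scanned over the sample by galvanometer mirrors, a detection
pinhole conjugate to the focal spot, and a single-element detector recording
one pixel per laser shot.  Images are acquired one wavenumber at a time;
whole slides are covered by stitching overlapping tiles; absorbance is
obtained by referencing each frame against a blank-substrate background.
Alongside the forward simulation, the package implements the
image-quality and chemical-imaging analyses used to characterize such
instruments: 100%-line and spatial-noise metrics, slant-edge MTF
(an ISO 12233 dialect), Siemens-star resolution, speckle contrast,
false-color band compositing, robust contaminant masking, and
serial-section 3-D reconstruction.

Everything is driven by synthetic scenes with exact ground truth, so every
estimator in the package can be scored against what was actually rendered.

# Image formation

## Diffraction model

The point-scan path is modeled with scalar Fourier optics.  For a pupil of
numerical aperture $\mathrm{NA}$ at wavenumber $\nu$ (wavelength
$\lambda = 10^4/\nu$ µm), the focal amplitude of a clear or centrally
obscured (annular, obscuration ratio $\epsilon$) pupil has the closed
Bessel form given by the difference of two disc transforms; the intensity
PSF is its squared modulus, and the incoherent MTF is the normalized pupil
autocorrelation with cutoff $2\,\mathrm{NA}/\lambda$.  At half cutoff the
clear-pupil value is the textbook
$\frac{2}{\pi}(\arccos s - s\sqrt{1-s^2}) \approx 0.391$.

A transflection fold mirror that claims part of the pupil for illumination
is modeled as a half-plane block of a stated area fraction.  The system
MTF with a blocked illumination pupil is taken as the product of the full
collection-pupil MTF and the blocked-pupil MTF, which yields the
direction-dependent (horizontal vs. vertical) curves characteristic of
reflective-objective transflection measurements.  This product form is a
modeling convention, not a partially-coherent transfer calculation; it
reproduces the qualitative split and the mid-frequency depression caused
by the central obscuration.

Confocal detection through a pinhole of diameter $D$ at sample-to-pinhole
magnification $M$ multiplies the illumination PSF by the detection PSF
convolved with the back-projected pinhole disc ($D/M$).  The limits behave
as expected: a closed pinhole gives the product of the two single-path
PSFs (FWHM ratio to widefield $\approx 0.72$ for an Airy profile), an open
pinhole returns the widefield PSF.

Numerical choices: radially symmetric pupils use the closed-form
amplitude (machine-precision agreement with the Airy oracle); asymmetric
pupils use a direct Fourier transform of an anti-aliased pupil mask
(400-point grid by default).  MTFs come from the FFT autocorrelation of a
1024-point anti-aliased mask, accurate to about $10^{-3}$ against the
analytic clear-pupil curve.  PSF supports default to $\pm 18$ first-zero
radii — the Airy tail decays slowly, and this is what it takes to capture
99% of the energy, which the constructor verifies against the Parseval
(pupil-area) total and reports the required support when violated.
Because any finite support truncates algebraic tails, the internal
consistency between `mtf()` and the DFT of `psf()` is about $4\times
10^{-3}$, not machine precision; tests assert 1%.

## Acquisition chain

A `Scene` carries per-band ground-truth absorbance $A$.  Acquisition
converts to reflectance $R = 10^{-A}$ (the transflection double pass is
absorbed into $A$; no separate path factor), convolves with the effective
PSF, samples the raster grid, and applies two noise terms per pixel:
multiplicative $\mathcal N(1, \sigma(\nu))$ for laser/shot noise and
additive $\mathcal N(0, \sigma_a)$ for the detector floor.  Pulse-level
timing (duty cycle, sampling delay) is not simulated: one laser shot is
one noisy pixel.  The band-dependent $\sigma(\nu)$ has a flat baseline,
amplification toward the detector cutoff on the low-wavenumber side
(quadratic roll-off over 150 cm⁻¹ by default, exactly baseline beyond
it), and triangular excess within ±10 cm⁻¹ of each laser module-transition
band (defaults 1030/1310/1610 cm⁻¹ for a four-module source spanning
777–1904 cm⁻¹).

The raster is bidirectional: odd lines (0-based) are acquired on the
return sweep and can carry a forward/reverse misregistration.
`alignBidirectional()` estimates that offset from the image itself:
integer lag by cross-correlating each reverse line against the mean of its
adjacent forward lines, then subpixel refinement by maximizing the
normalized correlation with the lag split symmetrically across both
signals and applied with a unitary Fourier shift.  Two design points
matter here.  First, a parabolic fit to the correlation peak (the common
shortcut) shows pixel locking of order 0.1 px; continuous optimization
avoids it.  Second, shifting with an interpolating kernel attenuates
spectra by an amount that depends on the fractional lag, which rewards or
punishes half-sample lags and can create false maxima; the unitary Fourier
shift has a flat magnitude response and removes that artifact.  On
textured phantoms the estimator recovers integer offsets to better than
0.03 px and 0.4-px offsets to ≲0.03 px at SNR 100.  A featureless frame
returns offset 0 with a low-confidence flag.

Coaddition uses a circular frame buffer keyed by an acquisition-state
token (configuration, band, shape); any state change flushes the buffer,
so frames from different conditions are never averaged.  Averaging $n$
frames reduces noise by $1/\sqrt n$ (verified by Monte Carlo at 5%).
Absorbance conversion floors the sample/background ratio at $10^{-6}$
and counts floored pixels; fixed-pattern gain present in both frames
cancels exactly.

## Widefield coherent comparator

The speckle comparator propagates a coherent field: amplitude
$\sqrt R$, per-pixel phase $4\pi h/\lambda$ from Gaussian surface
heights $h$ with RMS roughness 10 µm by default (many wavelengths, i.e.
fully developed speckle), low-pass filtered by the coherent pupil
($\mathrm{NA}/\lambda$), intensity $|E|^2$.  On a uniform rough scene the
speckle contrast $\sigma/\mu$ is 1 within sampling error; with zero
roughness it collapses to 0; the point-scan image of the same scene has
contrast equal to its relative noise floor (~0.01).  This is the
operational content of the claim that point scanning is not susceptible
to speckle: one detector pixel integrates a single focal spot, so phase
randomness across the field never interferes on the detector.

# Phantoms: what the generator emulates

The generators stand in for physical chrome-on-glass calibration targets
and tissue sections, with reflective-substrate polarity (background
reflective, features absorbing) and exact truth metadata:

* **Siemens star** — binary radial square wave, `nSpokes` cycles per
  revolution; local frequency $n/(2\pi r)$ cycles/µm is part of the truth.
* **Slant edge** — straight two-level edge at a stated angle (ISO
  recommends 2–10°; outside that a warning is issued).  Truth stores the
  exact line.  Rasterized truth uses pixel-centre membership; an
  anti-aliased (pixel-coverage) rendering is available where estimators
  need area-integrating pixels.
* **Tissue phantom** — thresholded smoothed Gaussian random fields, one
  per class, argmax labeling; spectra are sums of Gaussian bands at the
  standard fingerprint markers (phosphate 1079, Amide II 1544, Amide I
  1658, ester carbonyl 1765, PTFE-like C–F 1213 cm⁻¹, widths ~15–30 cm⁻¹).
  Band positions are standard assignments; shapes and amplitudes are
  synthetic.  Optional boundary mixing blurs the one-hot class weights,
  giving exactly linear spectral mixtures.
* **Contaminant inclusions** — discs of the PTFE-like spectrum, default
  radius 25 px (50 µm at 1 µm/px, representative of PTFE microplastic
  particles); centres and radii recorded.
* **Serial sections** — a block of tubes ("crypts") sliced at a stated
  thickness; each slice gets a rigid jitter recorded in truth and is
  rendered analytically at the shifted coordinates (no resampling).  The
  tubes' lateral wander across the block is a parameter (`wanderPx`);
  setting it to 0 gives straight tubes, the configuration used to score
  registration, because anatomical drift is indistinguishable from stage
  jitter to any translation estimator.
* **Reference film** — a fixed multi-band spectrum emulating a thin
  epoxy-photoresist film, linear in thickness (Beer–Lambert).  It is a
  synthetic stand-in, not a measured reference.

All generators are pure functions of their parameters and seed.  What
passing tests on these phantoms do *not* show: real tissue scattering and
dispersion artifacts, section rotation or tearing, stage drift within a
tile, focus errors, or real contaminant spectra — none of which are
modeled.

# Estimators

**Slant-edge MTF.**  Centroid edge detection per row, straight-line fit
for the slant (estimates outside ~1–14° are rejected with a diagnostic),
projection of all pixels onto the edge normal into a 4×-oversampled ESF,
two-tap derivative, Hamming window centred on the LSF centroid but
stretched to twice the record length (the standard-length window
multiplies a compact LSF by a measurably curved profile and biases the
MTF upward by several percent; stretching keeps the taper while making
the window nearly flat over the LSF), DFT magnitude normalized at zero
frequency, and compensation of the known bin-box and derivative responses
(division by $\mathrm{sinc}^2$, floored at 0.2).  Near-horizontal edges
are transposed first, making the estimate 90°-rotation invariant.
Against oracles: $2/\pi$ at Nyquist for a pixel-aperture edge (within
2%), a $\sigma = 2$ px Gaussian ESF (within 2% where the MTF exceeds
0.1), and the package's own diffraction MTF after blurring an edge with
`psf()` (3% RMS to 0.8× cutoff).

**Siemens-star resolution.**  Concentric rings sampled by bilinear
interpolation at 720 angles; the modulation at the known spoke frequency
is the fundamental Fourier coefficient of the ring profile normalized by
$\pi/4$ times the ring mean, so an unblurred star reads 1 and a blurred
star reads the MTF at the ring frequency (square-wave fundamental).  The
limiting frequency interpolates the first threshold crossing walking
inward; 25% approximates the Rayleigh criterion.  Rings are capped at the
sampling Nyquist.  Star and slant-edge estimates of the 25% frequency
agree within 5% across blur levels.

**Noise metrics.**  The 100% line is $-\log_{10}$ of the ratio of two
background shots; for i.i.d. relative noise $\sigma$ its RMS is
$\sqrt2\,\sigma/\ln 10$ (delta method, verified by Monte Carlo).  The RMS
window defaults to 1300–1700 cm⁻¹, away from the cutoff and transition
structure.  Spatial noise is the standard deviation of a blank frame
difference divided by $\sqrt 2$.  The SNR convention is peak reference-film
absorbance divided by the 100%-line RMS at the same band — the exact
formula used by instrument reports varies, so the function takes whichever
noise estimate the caller prefers and keeps the ratio plain.

**Contaminant mask.**  A pixel is flagged when its marker-band absorbance
(default 1213 cm⁻¹) is more than $k$ robust sigmas (median/MAD, $k = 5$)
above the band median *and* exceeds the same pixel's reference-band
absorbance (default Amide I).  The robust threshold makes the mask
invariant to global gain; the reference condition pins the boundary near
the 50% mixing point of the blur, which is what limits accuracy: for
50 µm inclusions imaged at 0.8 NA the overlap with truth (Jaccard) is
0.95–0.98 at SNR ~100, convolution-limited rather than noise-limited
(24 µm inclusions plateau near 0.94 regardless of SNR).

**Registration and volumes.**  Consecutive sections are registered by
phase correlation — Hann-windowed (shifts are not circular), spectrum
whitened with a small regularizer — with subpixel refinement by local
Fourier upsampling (×50) around the integer peak.  Per consecutive pair
the injected jitter is recovered to ≤0.1 px; chaining to the first slice
accumulates per-step errors as a random walk, which is why accuracy is
stated per step.  Registration is translation-only; section rotation is a
known limitation.  Volumes stack the back-shifted slices (bilinear, NA
outside) and expose orthogonal cross-sections; alignment quality is
summarized by the mean adjacent-slice correlation, which alignment must
increase.

# Mosaicking and throughput

Tile grids use $n = 1 + \lceil (L - F)/(F(1-v)) \rceil$ tiles per axis
for extent $L$, tile FOV $F$ and overlap $v$, with the last row/column
shifted inward so no tile exceeds the area (a 15 mm span at 1 mm FOV and
10% overlap gives 17×17 = 289 tiles).  Stitching blends with separable
tent weights normalized to sum to exactly one everywhere, so consistent
tiles reassemble losslessly ($<10^{-10}$); tiles are placed by plan
coordinates only (dead-reckoned stage), and correlation-based tile
registration is deliberately out of scope.  Tilt flattening removes a
least-squares plane while preserving the mean.

The throughput model is deliberately overhead-free:
$t = n_\text{tiles}\,(n_\text{coadd}\,N_\text{px}^2/(r\,d) +
t_\text{overhead})\,n_\text{bands}$ with pixel rate $r$ and scan duty
$d$.  At the 10× configuration (500² px, 1 MHz, 93% duty) a frame takes
0.269 s (3.72 Hz) and a 15×15 mm² slide at 2 coadditions predicts
2.59 min/band with zero overhead.  Practical per-tile overhead (stage
moves, settling, retuning) is real but unpublished, so it is exposed as a
parameter rather than silently calibrated: ~44 ms/tile brings the
prediction to 2.8 min/band.

# File formats

ENVI-style cubes are a text header plus band-sequential 32-bit IEEE
float binary, with wavelengths recorded in cm⁻¹; the round trip is
bit-exact at that width.  The TIFF alternative writes one 32-bit page per
band through the available TIFF backend, which stores 32-bit *fixed
point* over [0, 1]; the writer therefore rescales by a power-of-two
recorded in a JSON sidecar, and a round trip reproduces values within one
quantization step (scale × 2⁻³²).  Non-finite pixels found on ingestion
are replaced by the band median and reported — a deterministic,
auditable repair.

# Problem sizes used by the tests

The test-suite and the acceptance script run the full chains at reduced
scale chosen for quick, deterministic iteration: 128–400 px phantoms,
8–12 serial sections of 48–96 px, 10⁴-sample Monte Carlo checks of the
noise-scaling laws, and three-seed repetitions of the stochastic
properties.  The underlying models are size-free; the instrument-scale
constants (500 px tiles, 289-tile slides, 100-slice blocks) enter through
the planning calculators, which are exact arithmetic at any scale.

# Known limitations

No aberrations, vectorial high-NA corrections, polarization or depth
response in the optics; no galvo dynamics, preamplifier bandwidth or
pulse-level timing in the scanner; no partially coherent transfer theory
for the widefield comparator (one random phasor per pixel, product-MTF
convention for the blocked pupil); translation-only section registration;
no stage-error tile registration or nonlinear distortion fields; phantom
spectra and the reference film are synthetic stand-ins.
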