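# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation calls do not perturb the
# session RNG stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# sin(pi x)/(pi x) with the removable singularity filled.
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Pad a matrix with zeros to size n = c(rows, cols), content at the top left.
padZero <- function(m, n) {
  out <- matrix(0, n[1], n[2])
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# Replicate-pad a matrix by (pr, pc) on every side.
padReplicate <- function(m, pr, pc) {
  ri <- c(rep(1L, pr), seq_len(nrow(m)), rep(nrow(m), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(m)), rep(ncol(m), pc))
  m[ri, ci, drop = FALSE]
}

# 2-D "same" convolution with an odd-sized kernel; image edges are
# replicate-padded so blur does not darken borders.  FFT-based.
convolve2d <- function(img, kern) {
  kd <- dim(kern)
  if (any(kd %% 2L == 0L)) stop("convolution kernel must have odd dimensions")
  h <- kd %/% 2L
  imp <- padReplicate(img, h[1], h[2])
  full <- dim(imp) + kd - 1L
  nf <- c(stats::nextn(full[1], c(2, 3, 5)), stats::nextn(full[2], c(2, 3, 5)))
  Fi <- stats::fft(padZero(imp, nf))
  Fk <- stats::fft(padZero(kern, nf))
  conv <- Re(stats::fft(Fi * Fk, inverse = TRUE)) / prod(nf)
  conv[2L * h[1] + seq_len(nrow(img)), 2L * h[2] + seq_len(ncol(img)),
       drop = FALSE]
}

# Shift a vector by a (possibly fractional) number of samples with linear
# interpolation; values beyond the ends are replicated.
shiftVector <- function(v, shift) {
  n <- length(v)
  x <- seq_len(n) - shift
  x <- pmin(pmax(x, 1), n)
  i0 <- floor(x)
  fr <- x - i0
  i1 <- pmin(i0 + 1L, n)
  v[i0] * (1 - fr) + v[i1] * fr
}

# Rigidly translate an image by (dy, dx) pixels using bilinear interpolation;
# samples falling outside the source are NA.
shiftImage <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  r <- matrix(seq_len(nr), nr, nc) - dy
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  bilinearSample(img, r, c_)
}

# Bilinear interpolation at fractional (row, col) coordinates; NA outside.
bilinearSample <- function(img, r, c_) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c_ >= 1 & c_ <= nc & is.finite(r) & is.finite(c_)
  r0 <- pmin(floor(r[ok]), nr - 1L); c0 <- pmin(floor(c_[ok]), nc - 1L)
  fr <- r[ok] - r0; fc <- c_[ok] - c0
  v00 <- img[cbind(r0, c0)];     v01 <- img[cbind(r0, c0 + 1)]
  v10 <- img[cbind(r0 + 1, c0)]; v11 <- img[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
  if (is.matrix(r)) out <- matrix(out, nrow(r), ncol(r))
  out
}

# Isotropic Gaussian smoothing (sigma in pixels) via convolve2d.
gaussianSmooth <- function(img, sigmaPx) {
  if (sigmaPx <= 0) return(img)
  h <- max(1L, ceiling(3 * sigmaPx))
  x <- -h:h
  k1 <- exp(-x^2 / (2 * sigmaPx^2))
  k <- outer(k1, k1)
  convolve2d(img, k / sum(k))
}

# lambda (um) from wavenumber (1/cm)
wavenumberToWavelengthUm <- function(cm1) 1e4 / cm1

stopifnotScalar <- function(x, name, lower = -Inf, upper = Inf,
                            openLower = FALSE, openUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  bad <- if (openLower) x <= lower else x < lower
  bad <- bad || (if (openUpper) x >= upper else x > upper)
  if (bad)
    stop(sprintf("'%s' = %g is out of range %s%g, %g%s", name, x,
                 if (openLower) "(" else "[", lower, upper,
                 if (openUpper) ")" else "]"))
  invisible(x)
}

# Unitary (Fourier) shift of a vector by a fractional number of samples.
# The magnitude response is 1 at every frequency, so the shift introduces no
# resampling attenuation; the signal is treated as periodic.
fourierShiftVector <- function(v, shift) {
  n <- length(v)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  Re(stats::fft(stats::fft(v) * exp(-2i * pi * k * shift / n),
                inverse = TRUE)) / n
}
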