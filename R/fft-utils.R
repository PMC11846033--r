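# FFT helpers shared by all stages.
#
# Conventions (used everywhere in the package):
#  * "natural" layout: DC at index [1,1(,1)], as returned by fft().
#  * "centered" layout: DC at index [floor(n/2)+1, ...], obtained with
#    fftShift(); OTFModel stores its transfer function centered.
#  * forward transforms are unnormalized, inverse transforms divide by the
#    number of elements (so ifftn(fftn(x)) == x).

.asComplexArray <- function(x) {
  if (is.complex(x)) return(x)
  array(as.complex(x), dim(x))
}

fftn <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 1L) return(fftwtools::fftw_c2c(as.complex(x)))
  if (length(d) == 2L) return(fftwtools::fftw_c2c_2d(.asComplexArray(x)))
  if (length(d) == 3L) return(fftwtools::fftw_c2c_3d(.asComplexArray(x)))
  stats::fft(x)
}

ifftn <- function(x) {
  d <- dim(x)
  n <- length(x)
  if (is.null(d) || length(d) == 1L)
    return(fftwtools::fftw_c2c(as.complex(x), inverse = 1) / n)
  if (length(d) == 2L)
    return(fftwtools::fftw_c2c_2d(.asComplexArray(x), inverse = 1) / n)
  if (length(d) == 3L)
    return(fftwtools::fftw_c2c_3d(.asComplexArray(x), inverse = 1) / n)
  stats::fft(x, inverse = TRUE) / n
}

#' Frequency sample coordinates of an unshifted FFT axis
#'
#' Returns the signed frequencies (cycles per sample) associated with each
#' bin of an n-point unnormalized DFT in natural layout.
#'
#' @param n axis length.
#' @return numeric vector of length `n` in `[-1/2, 1/2)`.
#' @keywords internal
fftFreq <- function(n) {
  k <- 0:(n - 1L)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

shiftIndex <- function(n) {
  # permutation taking natural layout to centered layout (DC at floor(n/2)+1)
  ((seq_len(n) - 1L + ceiling(n / 2)) %% n) + 1L
}

fftShift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(x[shiftIndex(length(x))])
  if (length(d) == 2L) return(x[shiftIndex(d[1]), shiftIndex(d[2]), drop = FALSE])
  if (length(d) == 3L) return(x[shiftIndex(d[1]), shiftIndex(d[2]), shiftIndex(d[3]), drop = FALSE])
  stop("fftShift supports 1-3 dimensions")
}

ifftShiftIndex <- function(n) ((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L

ifftShift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(x[ifftShiftIndex(length(x))])
  if (length(d) == 2L) return(x[ifftShiftIndex(d[1]), ifftShiftIndex(d[2]), drop = FALSE])
  if (length(d) == 3L) return(x[ifftShiftIndex(d[1]), ifftShiftIndex(d[2]), ifftShiftIndex(d[3]), drop = FALSE])
  stop("ifftShift supports 1-3 dimensions")
}

#' Exact 2x lateral Fourier upsampling of a real image
#'
#' Trigonometric interpolation onto a grid with half the pixel pitch:
#' the spectrum is zero-padded symmetrically, with the Nyquist row/column
#' split between +N/2 and -N/2 so that the result of the inverse transform
#' is exactly real and agrees with the input at the original sample
#' positions.
#'
#' @param x real matrix with even dimensions.
#' @return real matrix of dimension `2*dim(x)`.
#' @keywords internal
fourierUpsample2x <- function(x) {
  d <- dim(x)
  ny <- d[1]; nx <- d[2]
  if (ny %% 2L != 0L || nx %% 2L != 0L) stop("even dimensions required")
  X <- fftn(x)
  Y <- padSpectrum2x(X)
  out <- Re(ifftn(Y)) * 4
  out
}

# Zero-pad an unshifted 2D spectrum from (ny, nx) to (2ny, 2nx) with proper
# Nyquist splitting; linear, so applies to complex band images as well.
padSpectrum2x <- function(X) {
  d <- dim(X)
  ny <- d[1]; nx <- d[2]
  hy <- ny %/% 2L; hx <- nx %/% 2L
  Xs <- fftShift(X)            # freqs -hy .. hy-1 (row), -hx .. hx-1 (col)
  # split the Nyquist (index 1 in shifted layout corresponds to -h)
  Xs[1, ] <- Xs[1, ] / 2
  Xs[, 1] <- Xs[, 1] / 2
  Y <- matrix(0i, 2L * ny, 2L * nx)
  # shifted layout of Y: freqs -ny .. ny-1 rows; center block holds -hy..hy-1
  ry <- (ny - hy + 1L):(ny + hy)
  rx <- (nx - hx + 1L):(nx + hx)
  Y[ry, rx] <- Xs
  # mirror the halved Nyquist lines to +h
  Y[ny + hy + 1L, rx] <- Xs[1L, ]
  Y[ry, nx + hx + 1L] <- Xs[, 1L]
  Y[ny + hy + 1L, nx + hx + 1L] <- Xs[1L, 1L]
  ifftShift(Y)
}

#' Upsample a volume 2x laterally by Fourier interpolation
#'
#' Applies [fourierUpsample2x()] plane by plane; the axial grid is
#' unchanged. Accepts real or complex input (complex input is upsampled
#' without the reality constraint, which the Nyquist split preserves for
#' conjugate-symmetric spectra).
#'
#' @param vol 3D array (y, x, z) or a matrix.
#' @return array with doubled lateral extents.
#' @keywords internal
upsampleLateral2x <- function(vol) {
  if (is.matrix(vol)) vol <- array(vol, c(dim(vol), 1L))
  d <- dim(vol)
  cplx <- is.complex(vol)
  out <- array(if (cplx) 0i else 0, c(2L * d[1], 2L * d[2], d[3]))
  for (z in seq_len(d[3])) {
    if (cplx) {
      out[, , z] <- ifftn(padSpectrum2x(fftn(vol[, , z]))) * 4
    } else {
      out[, , z] <- fourierUpsample2x(vol[, , z])
    }
  }
  out
}

# Chunked 3D transforms for large volumes: 2D FFT per z plane, then the
# axial transform on blocks of y rows. Identical results to fftn/ifftn
# but with peak memory bounded by one complex copy of the volume.

.CHUNK_LIMIT <- 2^25      # elements; above this the chunked path is used

fftnLarge <- function(x) {
  d <- dim(x)
  if (length(d) != 3L || prod(d) <= .CHUNK_LIMIT) return(fftn(x))
  out <- array(0i, d)
  for (z in seq_len(d[3])) out[, , z] <- fftn(x[, , z])
  # z transform inlined so `out` keeps a reference count of one and the
  # block assignments stay in place
  block <- max(1L, (2^22) %/% (d[2] * d[3]))
  for (start in seq(1L, d[1], by = block)) {
    rows <- start:min(start + block - 1L, d[1])
    m <- matrix(aperm(out[rows, , , drop = FALSE], c(3L, 1L, 2L)), d[3])
    m <- fftwtools::mvfftw_c2c(m, inverse = 0L)
    out[rows, , ] <- aperm(array(m, c(d[3], length(rows), d[2])), c(2L, 3L, 1L))
  }
  out
}

ifftnLarge <- function(x, realPart = FALSE) {
  d <- dim(x)
  if (length(d) != 3L || prod(d) <= .CHUNK_LIMIT) {
    out <- ifftn(x)
    return(if (realPart) Re(out) else out)
  }
  x <- .fftZInPlace(x, inverse = TRUE)
  out <- if (realPart) array(0, d) else array(0i, d)
  for (z in seq_len(d[3])) {
    pl <- ifftn(x[, , z])
    out[, , z] <- if (realPart) Re(pl) else pl
  }
  out
}

# axial FFT over blocks of y rows; modifies a fresh copy of `x`
.fftZInPlace <- function(x, inverse) {
  d <- dim(x)
  if (d[3] == 1L) return(x)
  block <- max(1L, (2^22) %/% (d[2] * d[3]))
  ys <- seq_len(d[1])
  for (start in seq(1L, d[1], by = block)) {
    rows <- ys[start:min(start + block - 1L, d[1])]
    sl <- x[rows, , , drop = FALSE]                     # nb x nx x nz
    m <- matrix(aperm(sl, c(3L, 1L, 2L)), d[3])          # nz x (nb*nx)
    m <- fftwtools::mvfftw_c2c(m, inverse = as.integer(inverse))
    if (inverse) m <- m / d[3]
    x[rows, , ] <- aperm(array(m, c(d[3], length(rows), d[2])), c(2L, 3L, 1L))
  }
  x
}

# radial lateral frequency map (cycles/pixel), natural layout
lateralFreqRadius <- function(ny, nx) {
  fy <- fftFreq(ny); fx <- fftFreq(nx)
  sqrt(outer(fy^2, fx^2, `+`))
}

# centered lateral coordinates in raw-pixel units. All pattern carriers
# are referenced to the grid center (index floor(n/2), the DC
# convention), so a small wavevector error does not masquerade as a
# large starting-phase error at the field corner.
# step = 1 for the raw grid, 1/2 for the 2x fine grid (pass the raw ny).
gridCoords <- function(ny, nx, step = 1) {
  cy <- floor(ny * step / 2); cx <- floor(nx * step / 2)
  yy <- matrix((0:(ny - 1L)) * step - cy, ny, nx)
  xx <- matrix((0:(nx - 1L)) * step - cx, ny, nx, byrow = TRUE)
  list(yy = yy, xx = xx)
}
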