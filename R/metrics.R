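# Quantitative evaluation: signal-to-background ratio, signal-to-noise
# ratio, and image-decorrelation resolution.

.normalize01 <- function(image) {
  rng <- range(image)
  if (rng[2] == rng[1]) stop("constant image cannot be normalized")
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Signal-to-background ratio in dB
#'
#' The image is min-max normalized, then
#' `SBR = 10 * log10(mean(signal region) / mean(background region))`.
#' The same masks should be used across algorithms being compared.
#'
#' @param image 2D or 3D numeric array.
#' @param signalMask,backgroundMask logical arrays of the same shape;
#'   non-empty and disjoint.
#' @return SBR in dB.
#' @export
sbrDb <- function(image, signalMask, backgroundMask) {
  if (!any(signalMask) || !any(backgroundMask)) stop("empty mask")
  if (any(signalMask & backgroundMask)) stop("masks must be disjoint")
  im <- .normalize01(image)
  bg <- mean(im[backgroundMask])
  if (bg <= 0) stop("zero background mean: SBR undefined")
  10 * log10(mean(im[signalMask]) / bg)
}

#' Signal-to-noise ratio in dB
#'
#' `SNR = 10 * log10((mean(signal) - mean(noise)) / sd(noise))` over the
#' given regions. A non-positive numerator has no real logarithm and is
#' reported as an undefined-SNR error rather than a complex value.
#'
#' @param image 2D or 3D numeric array.
#' @param signalMask,noiseMask logical arrays of the same shape.
#' @return SNR in dB.
#' @export
snrDb <- function(image, signalMask, noiseMask) {
  if (!any(signalMask) || !any(noiseMask)) stop("empty mask")
  ms <- mean(image[signalMask])
  mn <- mean(image[noiseMask])
  sn <- stats::sd(image[noiseMask])
  if (sn <= 0) stop("zero noise standard deviation: SNR undefined")
  if (ms <= mn) stop("undefined SNR: signal mean does not exceed noise mean")
  10 * log10((ms - mn) / sn)
}

#' Image-decorrelation resolution estimate
#'
#' Parameter-free resolution estimation from a single noisy image: the
#' cross-correlation between the image spectrum and its phase-only
#' (unit-magnitude) version is evaluated over a sweep of low-pass mask
#' radii; the correlation first grows with admitted signal and then
#' decays once only noise is added, producing a peak at the highest
#' self-consistent frequency. The sweep is repeated on Gaussian
#' high-pass filtered spectra, and the highest peak frequency across
#' all curves is taken as the cutoff `kc` (in units of the Nyquist
#' frequency), giving `resolution = 2 * pixel / kc`.
#'
#' @param image 2D numeric matrix (single plane or MIP); must contain
#'   noise — a noise-free band-limited image decorrelates at its support
#'   edge instead.
#' @param lateralPixelNm pixel size of `image` in nm.
#' @param nRadii number of mask radii in the sweep.
#' @param nHighpass number of Gaussian high-pass widths.
#' @param details return the decorrelation curves as well.
#' @return resolution in nm (or a list when `details = TRUE`).
#' @export
decorrelationResolution <- function(image, lateralPixelNm,
                                    nRadii = 50, nHighpass = 10,
                                    details = FALSE) {
  if (!is.matrix(image)) stop("a single 2D plane is required")
  ny <- nrow(image); nx <- ncol(image)
  Ik <- fftShift(fftn(image - mean(image)))
  # normalized radial frequency: 1 at Nyquist
  fy <- fftShift(fftFreq(ny)) * 2
  fx <- fftShift(fftFreq(nx)) * 2
  r <- sqrt(outer(fy^2, fx^2, `+`))
  keep <- r <= 1
  Ik[!keep] <- 0i
  mag <- Mod(Ik)
  In <- Ik
  In[mag > 0] <- Ik[mag > 0] / mag[mag > 0]

  ord <- order(r[keep])
  rs <- r[keep][ord]
  radii <- seq(1 / nRadii, 1, length.out = nRadii)
  cuts <- findInterval(radii, rs)

  # Gaussian high-pass widths, log-spaced over the band (sigma in r units);
  # first entry = no high-pass
  sigmas <- c(Inf, exp(seq(log(0.12), log(1), length.out = nHighpass)))
  kcs <- numeric(0)
  curves <- vector("list", length(sigmas))
  for (j in seq_along(sigmas)) {
    w <- if (is.finite(sigmas[j])) 1 - exp(-r^2 / (2 * sigmas[j]^2)) else NULL
    Ikw <- if (is.null(w)) Ik else Ik * w
    a <- Mod(Ikw[keep])[ord]               # |I_k| within the mask
    totalEnergy <- sum(a^2)
    csAbs <- cumsum(a)
    csCount <- seq_along(a)
    d <- csAbs[cuts] / sqrt(totalEnergy * csCount[cuts])
    d[cuts == 0] <- 0
    curves[[j]] <- d
    pk <- .lastLocalMax(d, radii)
    if (!is.na(pk)) kcs <- c(kcs, pk)
  }
  if (!length(kcs)) stop("resolution undefined: no decorrelation peak found")
  kc <- max(kcs)
  res <- 2 * lateralPixelNm / kc
  if (details)
    return(list(resolutionNm = res, kc = kc, radii = radii, curves = curves))
  res
}

# highest-frequency local maximum of a decorrelation curve; a peak must
# drop by a minimal prominence afterwards (or be an interior maximum
# followed by decline) to count. Returns NA for monotone curves.
.lastLocalMax <- function(d, radii, minProm = 0.01) {
  n <- length(d)
  best <- NA_real_
  i <- 2L
  while (i < n) {
    if (d[i] >= d[i - 1L] && d[i] > d[i + 1L]) {
      # prominence: drop after the peak before the curve rises again
      j <- i + 1L
      minAfter <- d[j]
      while (j < n && d[j + 1L] <= d[j]) { j <- j + 1L; minAfter <- min(minAfter, d[j]) }
      if (d[i] - minAfter >= minProm) best <- radii[i]
    }
    i <- i + 1L
  }
  best
}

#' Read an 8-bit mask TIFF as a logical matrix
#'
#' @param path TIFF file with values 0 / 255 (or 0 / 1).
#' @return logical matrix, `TRUE` inside the mask.
#' @export
readMask <- function(path) {
  m <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
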