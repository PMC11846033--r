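# Synthetic 3D-SIM acquisition simulator.
#
# Default optics: NA 1.4 oil objective (immersion index 1.518), emission
# 525 nm, 62.5 nm lateral pixels, 125 nm axial steps; illumination pattern
# at 0.8x the widefield cutoff with modulation depths a1 = 0.9, a2 = 0.45.
# Noise model: Poisson shot noise at a peak photon budget, then additive
# Gaussian read noise, then quantization to integer camera counts.

#' Test phantom with ground truth
#'
#' Generates a fluorophore-density volume containing pairs of
#' sub-diffraction structures (points, lines, or a circle) at known
#' separations, with the exact generated geometry recorded as truth
#' metadata for recovery tests.
#'
#' * `"point"`: a lattice of point pairs separated by `spacingNm`,
#'   alternating x-, y-, and (when `nz > 1`) z-oriented pairs across the
#'   field.
#' * `"line"`: pairs of parallel vertical lines in the focal plane
#'   separated by `spacingNm` (`spacingNm = 0` degenerates to single
#'   lines, recorded as merged).
#' * `"circle"`: an anti-aliased ring of radius `radiusVox` voxels in the
#'   focal plane whose integrated density equals
#'   `2*pi*radiusVox*amplitude`.
#' * `"custom"`: `volume` is used as supplied.
#'
#' @param kind `"point"`, `"line"`, `"circle"`, or `"custom"`.
#' @param gridShape integer(3) `(ny, nx, nz)` matching a RawStack
#'   geometry.
#' @param spacingNm separation between paired structures (nm).
#' @param lateralPixelNm,axialStepNm voxel pitch (nm).
#' @param amplitude peak density per structure voxel.
#' @param pitchVox lattice pitch of the point-pair lattice, in voxels.
#' @param pointSigmaNm Gaussian radius of each point marker (nm).
#'   Fluorescent markers have finite size; 0 gives single-voxel deltas,
#'   whose perfectly flat spectrum is not representative of real
#'   point-like samples. The default is part of the simulator
#'   calibration (see the package vignette).
#' @param radiusVox circle radius in voxels.
#' @param volume density volume for `kind = "custom"`.
#' @param rngSeed seed for the random jitter applied to structure
#'   positions (pair separations stay exact). Real specimens are
#'   aperiodic; an unjittered lattice would add coherent harmonics of
#'   its own to the spectrum.
#' @return a list with elements `volume` (3D array, density >= 0),
#'   `kind`, and `truth` (data.frame of generated structure centers and
#'   separations in nm).
#' @export
makePhantom <- function(kind = c("point", "line", "circle", "custom"),
                        gridShape, spacingNm = 150,
                        lateralPixelNm = 62.5, axialStepNm = 125,
                        amplitude = 1, pitchVox = 64, radiusVox = 40,
                        volume = NULL, rngSeed = 7L, pointSigmaNm = 41) {
  kind <- match.arg(kind)
  set.seed(as.integer(rngSeed))
  ny <- gridShape[1]; nx <- gridShape[2]; nz <- gridShape[3]
  vol <- array(0, c(ny, nx, nz))
  zc <- nz %/% 2L + 1L
  truth <- NULL
  if (kind != "custom" && spacingNm > 0 && spacingNm < lateralPixelNm)
    stop("spacingNm below one voxel")

  if (kind == "point") {
    sepL <- round(spacingNm / lateralPixelNm)       # lateral, voxels
    sepZ <- if (nz > 1) max(1L, round(spacingNm / axialStepNm)) else 0L
    # uniformly random pair centers (rejection-sampled for a minimum
    # spacing of pitchVox/2): aperiodic, like a real sparse specimen
    nPairs <- max(1L, (ny %/% pitchVox) * (nx %/% pitchVox))
    margin <- max(sepL + 2L, 8L)
    centers <- matrix(0L, 0L, 2L)
    tries <- 0L
    while (nrow(centers) < nPairs && tries < 200L * nPairs) {
      cand <- c(sample(margin:(ny - margin), 1L),
                sample(margin:(nx - margin), 1L))
      if (nrow(centers) == 0L ||
          min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
            (pitchVox / 2)^2)
        centers <- rbind(centers, cand)
      tries <- tries + 1L
    }
    rows <- list()
    addSpot <- function(vol, p) {
      if (pointSigmaNm <= 0) {
        vol[p[1], p[2], p[3]] <- vol[p[1], p[2], p[3]] + amplitude
        return(vol)
      }
      sl <- pointSigmaNm / lateralPixelNm         # voxels
      sz <- pointSigmaNm / axialStepNm
      ry <- max(1L, p[1] - 4L):min(ny, p[1] + 4L)
      rx <- max(1L, p[2] - 4L):min(nx, p[2] + 4L)
      rz <- max(1L, p[3] - 2L):min(nz, p[3] + 2L)
      for (z in rz) {
        g <- exp(-(outer((ry - p[1])^2, (rx - p[2])^2, `+`) / (2 * sl^2) +
                     (z - p[3])^2 / (2 * sz^2)))
        vol[ry, rx, z] <- vol[ry, rx, z] + amplitude * g
      }
      vol
    }
    for (k in seq_len(nrow(centers))) {
      ori <- switch((k - 1L) %% 3L + 1L, "x", "y", if (nz > 1L) "z" else "x")
      d <- switch(ori,
                  x = c(0L, sepL, 0L), y = c(sepL, 0L, 0L), z = c(0L, 0L, sepZ))
      p1 <- c(centers[k, ], zc)
      p2 <- p1 + d
      if (p2[1] > ny || p2[2] > nx || p2[3] > nz || p2[3] < 1L) next
      vol <- addSpot(vol, p1)
      vol <- addSpot(vol, p2)
      sepNm <- if (ori == "z") d[3] * axialStepNm else sepL * lateralPixelNm
      rows[[length(rows) + 1L]] <- data.frame(
        y1 = p1[1], x1 = p1[2], z1 = p1[3],
        y2 = p2[1], x2 = p2[2], z2 = p2[3],
        orientation = ori, separationNm = sepNm)
    }
    truth <- do.call(rbind, rows)
  } else if (kind == "line") {
    sepL <- round(spacingNm / lateralPixelNm)
    xs <- seq(nx %/% 4L, 3L * nx %/% 4L, by = max(2L * sepL + 8L, 16L))
    xs <- xs + sample(-3:3, length(xs), replace = TRUE)
    rows <- list()
    for (x in xs) {
      vol[, x, zc] <- vol[, x, zc] + amplitude
      if (sepL > 0L && x + sepL <= nx) {
        vol[, x + sepL, zc] <- vol[, x + sepL, zc] + amplitude
        rows[[length(rows) + 1L]] <- data.frame(
          x1 = x, x2 = x + sepL, z = zc, merged = FALSE,
          separationNm = sepL * lateralPixelNm)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          x1 = x, x2 = x, z = zc, merged = TRUE, separationNm = 0)
      }
    }
    truth <- do.call(rbind, rows)
  } else if (kind == "circle") {
    cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
    yy <- matrix(seq_len(ny), ny, nx) - cy
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
    r <- sqrt(yy^2 + xx^2)
    # tent profile of unit radial integral -> total density = circumference
    vol[, , zc] <- amplitude * pmax(0, 1 - abs(r - radiusVox))
    truth <- data.frame(cy = cy, cx = cx, radiusVox = radiusVox,
                        radiusNm = radiusVox * lateralPixelNm)
  } else {
    if (is.null(volume)) stop("kind = 'custom' requires a volume")
    if (!all(dim(volume) == c(ny, nx, nz))) stop("volume does not match gridShape")
    if (any(volume < 0)) stop("density must be >= 0")
    vol <- volume
    truth <- data.frame(note = "custom volume")
  }
  list(volume = vol, kind = kind, truth = truth,
       lateralPixelNm = lateralPixelNm, axialStepNm = axialStepNm)
}

#' Scalar-diffraction 3D OTF/PSF model
#'
#' Builds the widefield detection transfer by pupil propagation: a
#' uniform circular pupil of radius NA/lambda is defocused plane by plane
#' with the angular-spectrum phase `exp(2i*pi*z*sqrt((n/lambda)^2 - k^2))`,
#' the amplitude PSF is the inverse transform of each defocused pupil,
#' and the intensity PSF is its squared modulus. The OTF is the 3D
#' transform of the sum-normalized PSF, giving the standard toroidal
#' support with the missing cone along the axial frequency axis and a
#' hard lateral cutoff at `2 NA / lambda`.
#'
#' @param na numerical aperture in (0, 1.52].
#' @param wavelengthEmNm emission wavelength (nm).
#' @param lateralPixelNm,axialStepNm grid pitch (nm).
#' @param gridShape integer(3) `(ny, nx, nz)`.
#' @param refractiveIndex immersion index (default 1.518, oil).
#' @param storePsf keep the real-space PSF in the model (default). The
#'   frequency-optimization stages only need the transfer function;
#'   dropping the PSF halves the footprint of large fine-grid models.
#' @return an [OTFModel-class].
#' @export
makeOTF3D <- function(na, wavelengthEmNm, lateralPixelNm, axialStepNm,
                      gridShape, refractiveIndex = 1.518,
                      storePsf = TRUE) {
  if (na <= 0 || na > 1.52) stop("na must lie in (0, 1.52]")
  if (wavelengthEmNm <= 0) stop("wavelength must be positive")
  if (na > refractiveIndex) stop("na cannot exceed the immersion index")
  ny <- gridShape[1]; nx <- gridShape[2]; nz <- gridShape[3]
  fwhm <- 0.51 * wavelengthEmNm / na
  if (ny * lateralPixelNm < 8 * fwhm || nx * lateralPixelNm < 8 * fwhm)
    stop("grid too small to contain the PSF support")
  fy <- fftFreq(ny) / lateralPixelNm            # cycles/nm
  fx <- fftFreq(nx) / lateralPixelNm
  k2 <- outer(fy^2, fx^2, `+`)
  pupil <- k2 <= (na / wavelengthEmNm)^2
  kzmap <- sqrt(pmax((refractiveIndex / wavelengthEmNm)^2 - k2, 0))
  # natural layout throughout (z index 1 = focal plane, lateral DC at
  # [1,1]); shifted to centered only for the stored slots
  zsNat <- fftFreq(nz) * nz * axialStepNm
  psfNat <- array(0, c(ny, nx, nz))
  for (iz in seq_len(nz)) {
    amp <- ifftn(pupil * exp(2i * pi * kzmap * zsNat[iz]))
    psfNat[, , iz] <- Mod(amp)^2
  }
  psfNat <- psfNat / sum(psfNat)
  otf <- fftnLarge(psfNat)
  psf <- if (storePsf) fftShift(psfNat) else array(0, c(0L, 0L, 0L))
  rm(psfNat)
  otf <- Re(otf)                   # symmetric pupil: transfer is real
  otf <- fftShift(otf)
  otf <- otf / otf[ny %/% 2L + 1L, nx %/% 2L + 1L, nz %/% 2L + 1L]
  new("OTFModel", otf = otf, psf = psf,
      cutoffLateral = 2 * na / wavelengthEmNm,
      cutoffAxial = (refractiveIndex -
                       sqrt(refractiveIndex^2 - na^2)) / wavelengthEmNm,
      lateralPixelNm = lateralPixelNm, axialStepNm = axialStepNm,
      wavelengthEmNm = wavelengthEmNm, na = na)
}

#' Default illumination parameters for simulation
#'
#' Three pattern angles at 0, 60 and 120 degrees with |p| at a fixed
#' fraction of the widefield cutoff (default 0.8, typical of linear SIM
#' illuminating near the pupil edge), equally spaced phase steps, and
#' modulation depths a1 = 0.9, a2 = 0.45.
#'
#' @param na,wavelengthEmNm,lateralPixelNm optics defining the cutoff.
#' @param patternFraction |p| as a fraction of the lateral cutoff.
#' @param phase0 starting phases (radians, recycled to 3).
#' @param a1,a2,I0 modulation depths and intensity scale.
#' @return an [IlluminationParams-class].
#' @export
defaultIllumination <- function(na = 1.4, wavelengthEmNm = 525,
                                lateralPixelNm = 62.5,
                                patternFraction = 0.8,
                                phase0 = c(0.3, 1.1, 2.2),
                                a1 = 0.9, a2 = 0.45, I0 = 1) {
  pmag <- patternFraction * 2 * na / wavelengthEmNm * lateralPixelNm  # cyc/px
  ang <- c(0, pi / 3, 2 * pi / 3)
  wv <- cbind(pmag * sin(ang), pmag * cos(ang))
  IlluminationParams(wv, phase0 = phase0, a1 = a1, a2 = a2, I0 = I0)
}

#' Simulate a 3D-SIM acquisition
#'
#' For each angle and phase the excitation pattern
#' `I0 * (1 + a1*cos(Omega + phi_i) + a2*cos(2*Omega + 2*phi_i))` with
#' `Omega = 2*pi*(p . (r - r_center)) + phi0` (the starting phase is
#' referenced at the grid center) multiplies the fluorophore density; the
#' product is blurred by the 3D PSF (FFT convolution, periodic
#' boundaries). A defocused background — the density blurred by a
#' heavily widened PSF and scaled by `backgroundStrength` — is added
#' identically to every phase. With noise enabled, intensities are
#' scaled so the brightest clean voxel equals `photonBudget`, Poisson
#' shot noise and Gaussian read noise are applied, and the result is
#' quantized to non-negative integer camera counts. Noise-free
#' simulations (`noise = NULL`) stay continuous.
#'
#' @param phantom result of [makePhantom()].
#' @param params an [IlluminationParams-class].
#' @param otf an [OTFModel-class] on the phantom grid.
#' @param backgroundStrength relative strength of the defocused
#'   background term (0 disables).
#' @param noise `NULL`, or `list(photonBudget = , readSigma = )`.
#' @param rngSeed integer seed; identical seeds give bit-identical
#'   stacks.
#' @return a [RawStack-class].
#' @export
simulateAcquisition <- function(phantom, params, otf,
                                backgroundStrength = 0,
                                noise = list(photonBudget = 500, readSigma = 2),
                                rngSeed = 1L) {
  rho <- phantom$volume
  d <- dim(rho)
  if (!all(dim(otf@otf) == d)) stop("phantom and otf grids are incompatible")
  if (!is.null(noise) && noise$photonBudget <= 0) stop("photonBudget must be > 0")
  H <- ifftShift(otf@otf)                       # natural layout
  R0 <- fftn(rho)
  V0 <- Re(ifftn(R0 * H))                       # widefield blur of the density

  bg <- 0
  if (backgroundStrength > 0) {
    # heavily widened psf: Gaussian with sigma = 2 um lateral, 4 planes
    # axial (strong defocus spreads light over micrometres)
    sl <- 2000 / phantom$lateralPixelNm
    gy <- exp(-2 * pi^2 * sl^2 * fftFreq(d[1])^2)
    gx <- exp(-2 * pi^2 * sl^2 * fftFreq(d[2])^2)
    gz <- exp(-2 * pi^2 * 4^2 * fftFreq(d[3])^2)
    G <- outer(outer(gy, gx), gz)
    bg <- backgroundStrength * Re(ifftn(R0 * G)) * mean(V0) / max(mean(rho), .Machine$double.eps)
    bg <- pmax(bg, 0)
  }

  gc <- gridCoords(d[1], d[2])
  cleanImage <- function(a, i, V0, V1, V2) {
    ph <- params@phaseSteps[i]
    img <- params@I0[a] * (V0 +
      params@a1[a] * Re(exp(1i * ph) * V1) +
      params@a2[a] * Re(exp(2i * ph) * V2))
    pmax(img, 0) + bg
  }
  bandsOfAngle <- function(a) {
    p <- params@wavevectors[a, ]
    omega <- 2 * pi * (p[1] * gc$yy + p[2] * gc$xx) + params@phase0[a]
    E1 <- exp(1i * omega)
    V1 <- ifftn(fftn(rho * as.vector(E1)) * H)  # lateral ramp, all z alike
    V2 <- ifftn(fftn(rho * as.vector(E1^2)) * H)
    list(V1 = V1, V2 = V2)
  }

  if (is.null(noise)) {
    data <- array(0, c(d[1], d[2], d[3], 5L, 3L))
    for (a in 1:3) {
      V <- bandsOfAngle(a)
      for (i in 1:5) data[, , , i, a] <- cleanImage(a, i, V0, V$V1, V$V2)
    }
  } else {
    # noisy acquisitions are quantized to integer camera counts on the
    # fly; the clean maximum (for the photon-budget scaling) comes from
    # a first pass so the full-precision stack is never materialized
    maxI <- 0
    for (a in 1:3) {
      V <- bandsOfAngle(a)
      for (i in 1:5) maxI <- max(maxI, max(cleanImage(a, i, V0, V$V1, V$V2)))
    }
    scale <- noise$photonBudget / maxI
    set.seed(as.integer(rngSeed))
    data <- array(0L, c(d[1], d[2], d[3], 5L, 3L))
    for (a in 1:3) {
      V <- bandsOfAngle(a)
      for (i in 1:5) {
        img <- cleanImage(a, i, V0, V$V1, V$V2) * scale
        counts <- stats::rpois(length(img), lambda = img) +
          stats::rnorm(length(img), sd = noise$readSigma)
        data[, , , i, a] <- array(as.integer(pmax(round(counts), 0)),
                                  dim(img))
      }
    }
  }
  rm(V0, R0, H)
  RawStack(data, lateralPixelNm = phantom$lateralPixelNm,
           axialStepNm = phantom$axialStepNm,
           wavelengthEmNm = otf@wavelengthEmNm, na = otf@na)
}
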