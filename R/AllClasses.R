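#' @import methods
NULL

#' Raw 3D-SIM acquisition
#'
#' Container for one raw 3D structured-illumination acquisition: for every
#' z plane, 15 images (3 illumination angles x 5 phase steps) in
#' photon-count units, plus the optical metadata needed downstream.
#'
#' The canonical index semantics are (angle, phase, z, y, x). In
#' column-major R this is stored as an array with
#' `dim = c(ny, nx, nz, 5 phases, 3 angles)`, so that a single raw image
#' `rawImage(stack, angle, phase, z)` is a contiguous y-by-x matrix.
#' Readers translate instrument page orders into this layout
#' (see [readRawStack()]).
#'
#' @slot data 5D numeric array, `dim = c(ny, nx, nz, 5, 3)`; finite,
#'   non-negative intensities.
#' @slot lateralPixelNm lateral pixel size in nm.
#' @slot axialStepNm axial step between z planes in nm.
#' @slot wavelengthEmNm emission wavelength in nm.
#' @slot na numerical aperture of the detection objective.
#' @seealso [validateStack()], [simulateAcquisition()], [widefield()]
#' @export
setClass("RawStack",
  representation(
    data = "array",
    lateralPixelNm = "numeric",
    axialStepNm = "numeric",
    wavelengthEmNm = "numeric",
    na = "numeric"
  )
)

setValidity("RawStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 5L)
    return(sprintf("data must be 5D (y, x, z, phase, angle); got %d dims", length(d)))
  if (d[5] != 3L || d[4] != 5L)
    return(sprintf("exactly 3 angles and 5 phases required; got %d angles, %d phases",
                   d[5], d[4]))
  if (d[3] < 1L) return("at least one z layer required")
  if (d[1] != d[2] || d[1] %% 2L != 0L)
    return(sprintf("y and x extents must be equal and even; got %d x %d", d[1], d[2]))
  rng <- suppressWarnings(range(object@data, na.rm = FALSE))
  if (!all(is.finite(rng)) || rng[1] < 0) {
    bad <- which(!is.finite(object@data) | object@data < 0)  # only on failure
    idx <- arrayInd(bad[1], d)
    return(sprintf(
      "non-finite or negative intensity at (y=%d, x=%d, z=%d, phase=%d, angle=%d)",
      idx[1], idx[2], idx[3], idx[4], idx[5]))
  }
  for (s in c("lateralPixelNm", "axialStepNm", "wavelengthEmNm", "na")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("%s must be a single positive number", s))
  }
  TRUE
})

#' Illumination pattern parameters
#'
#' Per-angle sinusoidal pattern description: lateral wavevector (cycles
#' per raw pixel, ordered (y, x) to match array indexing), starting phase,
#' the five phase-step offsets shared by all angles, and the modulation
#' depths of the first and second harmonic.
#'
#' @slot wavevectors 3x2 numeric matrix; row theta holds the pattern
#'   wavevector `(p_y, p_x)` in cycles/pixel.
#' @slot phase0 numeric(3), starting phase per angle (radians).
#' @slot phaseSteps numeric(5), phase offsets (radians); default
#'   `2*pi*(0:4)/5`.
#' @slot a1 numeric(3), first-order modulation depth in \[0, 1\].
#' @slot a2 numeric(3), second-order modulation depth, `a2 <= a1`.
#' @slot I0 numeric(3), illumination intensity scale.
#' @export
setClass("IlluminationParams",
  representation(
    wavevectors = "matrix",
    phase0 = "numeric",
    phaseSteps = "numeric",
    a1 = "numeric",
    a2 = "numeric",
    I0 = "numeric"
  ),
  prototype(
    phaseSteps = 2 * pi * (0:4) / 5,
    I0 = rep(1, 3)
  )
)

setValidity("IlluminationParams", function(object) {
  if (!identical(dim(object@wavevectors), c(3L, 2L)))
    return("wavevectors must be a 3x2 matrix (rows = angles, cols = (p_y, p_x))")
  if (length(object@phase0) != 3L) return("phase0 must have length 3")
  if (length(object@phaseSteps) != 5L) return("phaseSteps must have length 5")
  if (anyDuplicated(round(object@phaseSteps %% (2 * pi), 12)))
    return("phaseSteps must be distinct modulo 2*pi")
  for (s in c("a1", "a2", "I0"))
    if (length(slot(object, s)) != 3L)
      return(sprintf("%s must have length 3 (one value per angle)", s))
  if (any(object@a1 < 0 | object@a1 > 1) || any(object@a2 < 0 | object@a2 > 1))
    return("modulation depths a1, a2 must lie in [0, 1]")
  if (any(object@a2 > object@a1 + 1e-12))
    return("second-order depth a2 must not exceed a1")
  pmag <- sqrt(rowSums(object@wavevectors^2))
  if (any(pmag <= 0)) return("every |p_theta| must be > 0")
  if (any(pmag >= 0.5)) return("|p_theta| must be below the Nyquist frequency (0.5 cycles/pixel)")
  TRUE
})

#' 3D optical transfer function / point spread function pair
#'
#' Scalar-diffraction widefield transfer model. The OTF is stored DC
#' centered and normalized to 1 at DC; the PSF is stored centered at the
#' middle voxel and sums to 1. Both live on the same (y, x, z) grid.
#'
#' @slot otf complex 3D array, DC-centered frequency layout.
#' @slot psf real 3D array, centered, sum-normalized.
#' @slot cutoffLateral lateral support limit `2 NA / lambda` (cycles/nm).
#' @slot cutoffAxial axial support limit (cycles/nm).
#' @slot lateralPixelNm,axialStepNm,wavelengthEmNm,na grid and optics
#'   metadata.
#' @seealso [makeOTF3D()]
#' @export
setClass("OTFModel",
  representation(
    otf = "array",
    psf = "array",
    cutoffLateral = "numeric",
    cutoffAxial = "numeric",
    lateralPixelNm = "numeric",
    axialStepNm = "numeric",
    wavelengthEmNm = "numeric",
    na = "numeric"
  )
)

setValidity("OTFModel", function(object) {
  if (length(dim(object@otf)) != 3L) return("otf must be 3D")
  if (length(object@psf) > 0) {        # psf may be dropped on large grids
    if (!identical(dim(object@otf), dim(object@psf)))
      return("otf and psf must share a grid")
    if (any(object@psf < -1e-12)) return("psf must be non-negative")
    if (abs(sum(object@psf) - 1) > 1e-6) return("psf must sum to 1")
  }
  d <- dim(object@otf)
  dc <- Mod(object@otf[d[1] %/% 2L + 1L, d[2] %/% 2L + 1L, d[3] %/% 2L + 1L])
  if (abs(dc - 1) > 1e-6) return("otf must be 1 at DC after normalization")
  if (max(Mod(object@otf)) > 1 + 1e-6) return("|otf| must not exceed 1")
  TRUE
})

.srStages <- c("SR0_minus", "SR1", "OS", "SR2", "WF", "SR_ref")

#' Reconstructed volume with provenance stage
#'
#' A 3D image (y, x, z) produced by one of the reconstruction stages, at
#' 2x lateral upsampling relative to the raw grid (the z grid is
#' unchanged). The `stage` tag records provenance: `SR0_minus`
#' (zero-order-removed spatial recombination), `SR1` (after frequency
#' optimization), `OS` (HiLo optical section), `SR2` (final fusion,
#' clamped non-negative), `WF` (widefield reference), `SR_ref` (classical
#' frequency-domain reconstruction).
#'
#' @slot data real 3D array (y, x, z).
#' @slot stage one of `"SR0_minus"`, `"SR1"`, `"OS"`, `"SR2"`, `"WF"`,
#'   `"SR_ref"`.
#' @slot lateralPixelNm,axialStepNm pixel metadata (already halved
#'   laterally relative to the raw stack for the upsampled stages).
#' @export
setClass("SRVolume",
  representation(
    data = "array",
    stage = "character",
    lateralPixelNm = "numeric",
    axialStepNm = "numeric"
  )
)

setValidity("SRVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be 3D (y, x, z)")
  if (length(object@stage) != 1L || !object@stage %in% .srStages)
    return(sprintf("stage must be one of %s", paste(.srStages, collapse = ", ")))
  if (object@stage == "SR2" && min(object@data) < 0)
    return("SR2 volumes must be clamped >= 0")
  if (any(!is.finite(object@data))) return("data must be finite")
  TRUE
})

#' Frequency-domain filter parameters
#'
#' Holds every tunable of the frequency-optimization and HiLo stages:
#' the Gaussian low-pass cutoff of the complementary Lo/Hi pair, the
#' notch geometry at residual illumination peaks, the apodization
#' cutoff, the Wiener regularization constant, and the strengths of the
#' two noise-suppression passes. All frequencies are in cycles per raw
#' pixel; `NA_real_` for `loSigma` means "derive from the pattern
#' frequency" (|p|/4).
#'
#' @slot loSigma Gaussian cutoff of Lo (cycles/raw pixel); Hi = 1 - Lo.
#' @slot notchWidth Gaussian width of each notch (cycles/raw pixel).
#' @slot notchDepth notch depth in \[0, 1\] (0 disables).
#' @slot apodizationCutoff lateral cutoff of the triangular spectrum
#'   window as a multiple of the widefield cutoff.
#' @slot wienerW Wiener regularization constant of noise-suppression
#'   pass 1 (0 disables the two-step filter).
#' @slot twostepParams numeric(2): out-of-band suppression strength and
#'   high-frequency rolloff strength of pass 2.
#' @seealso [defaultFilterBank()], [optimizeVolume()]
#' @export
setClass("FilterBank",
  representation(
    loSigma = "numeric",
    notchWidth = "numeric",
    notchDepth = "numeric",
    apodizationCutoff = "numeric",
    wienerW = "numeric",
    twostepParams = "numeric"
  )
)

setValidity("FilterBank", function(object) {
  if (!is.na(object@loSigma) && object@loSigma <= 0)
    return("loSigma must be positive (or NA to derive from the pattern frequency)")
  if (object@notchWidth <= 0) return("notchWidth must be positive")
  if (object@notchDepth < 0 || object@notchDepth > 1)
    return("notchDepth must lie in [0, 1]")
  if (object@apodizationCutoff < 1 && is.finite(object@apodizationCutoff))
    return("apodizationCutoff must be >= 1 (multiple of the widefield cutoff)")
  if (object@wienerW < 0) return("wienerW must be >= 0")
  if (length(object@twostepParams) != 2L || any(object@twostepParams < 0))
    return("twostepParams must be two non-negative strengths")
  TRUE
})
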