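# Constructors, accessors and show methods for the core types.

#' Construct a RawStack
#'
#' @param data 5D array with `dim = c(ny, nx, nz, 5 phases, 3 angles)`
#'   (canonical (angle, phase, z, y, x) semantics, column-major storage).
#' @param lateralPixelNm,axialStepNm,wavelengthEmNm,na optical metadata.
#' @return a validated [RawStack-class] object.
#' @examples
#' d <- array(1, c(8, 8, 2, 5, 3))
#' s <- RawStack(d, 62.5, 125, 525, 1.4)
#' dim(rawData(s))
#' @export
RawStack <- function(data, lateralPixelNm, axialStepNm, wavelengthEmNm, na) {
  obj <- new("RawStack", data = data, lateralPixelNm = lateralPixelNm,
             axialStepNm = axialStepNm, wavelengthEmNm = wavelengthEmNm,
             na = na)
  validObject(obj)
  obj
}

#' Construct IlluminationParams
#'
#' @param wavevectors 3x2 matrix of per-angle wavevectors `(p_y, p_x)` in
#'   cycles/raw pixel.
#' @param phase0 starting phase per angle (radians; recycled to length 3).
#' @param phaseSteps the five phase offsets (radians).
#' @param a1,a2 modulation depths (recycled to length 3).
#' @param I0 intensity scale (recycled to length 3).
#' @export
IlluminationParams <- function(wavevectors, phase0 = 0,
                               phaseSteps = 2 * pi * (0:4) / 5,
                               a1 = 0.9, a2 = 0.45, I0 = 1) {
  obj <- new("IlluminationParams",
             wavevectors = wavevectors,
             phase0 = rep_len(phase0, 3L),
             phaseSteps = phaseSteps,
             a1 = rep_len(a1, 3L), a2 = rep_len(a2, 3L),
             I0 = rep_len(I0, 3L))
  validObject(obj)
  obj
}

#' Construct an SRVolume
#' @param data real 3D array (y, x, z).
#' @param stage provenance tag; see [SRVolume-class].
#' @param lateralPixelNm,axialStepNm pixel metadata of this volume.
#' @export
SRVolume <- function(data, stage, lateralPixelNm, axialStepNm) {
  obj <- new("SRVolume", data = data, stage = stage,
             lateralPixelNm = lateralPixelNm, axialStepNm = axialStepNm)
  validObject(obj)
  obj
}

#' Validate a raw acquisition
#'
#' Checks the full set of RawStack invariants (3 angles, 5 phases, at
#' least one z layer, equal and even lateral extents, finite non-negative
#' intensities) and returns the stack unchanged if all hold.
#'
#' @param stack a [RawStack-class].
#' @return `stack`, unchanged.
#' @export
validateStack <- function(stack) {
  if (!is(stack, "RawStack")) stop("validateStack expects a RawStack")
  validObject(stack)
  stack
}

#' @rdname accessors
#' @export
setGeneric("rawData", function(x) standardGeneric("rawData"))
#' Accessors for the core classes
#'
#' `rawData()` returns the underlying array; `lateralPixelNm()`,
#' `axialStepNm()` return grid metadata; `srStage()` the provenance tag
#' of a reconstructed volume; `srData()` its array.
#'
#' @param x a SpatialSIM object.
#' @name accessors
#' @export
setMethod("rawData", "RawStack", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("lateralPixelNm", function(x) standardGeneric("lateralPixelNm"))
#' @rdname accessors
setMethod("lateralPixelNm", "RawStack", function(x) x@lateralPixelNm)
#' @rdname accessors
setMethod("lateralPixelNm", "SRVolume", function(x) x@lateralPixelNm)
#' @rdname accessors
setMethod("lateralPixelNm", "OTFModel", function(x) x@lateralPixelNm)

#' @rdname accessors
#' @export
setGeneric("axialStepNm", function(x) standardGeneric("axialStepNm"))
#' @rdname accessors
setMethod("axialStepNm", "RawStack", function(x) x@axialStepNm)
#' @rdname accessors
setMethod("axialStepNm", "SRVolume", function(x) x@axialStepNm)
#' @rdname accessors
setMethod("axialStepNm", "OTFModel", function(x) x@axialStepNm)

#' @rdname accessors
#' @export
setGeneric("srStage", function(x) standardGeneric("srStage"))
#' @rdname accessors
setMethod("srStage", "SRVolume", function(x) x@stage)

#' @rdname accessors
#' @export
setGeneric("srData", function(x) standardGeneric("srData"))
#' @rdname accessors
setMethod("srData", "SRVolume", function(x) x@data)

#' One raw image plane
#'
#' @param stack a [RawStack-class].
#' @param angle angle index in 1..3.
#' @param phase phase index in 1..5.
#' @param z z index.
#' @return y-by-x matrix.
#' @export
rawImage <- function(stack, angle, phase, z) {
  stack@data[, , z, phase, angle]
}

#' Widefield volume of an acquisition
#'
#' The mean over all angles and phases: the unmodulated (zero-order)
#' image, equivalent to a conventional widefield acquisition and the
#' carrier of the defocused background.
#'
#' @param stack a [RawStack-class].
#' @param upsample if `TRUE`, Fourier-upsample 2x laterally onto the SR
#'   grid and return an [SRVolume-class] with stage `"WF"`; otherwise
#'   return the raw-grid 3D array.
#' @return 3D array or SRVolume.
#' @export
widefield <- function(stack, upsample = FALSE) {
  d <- dim(stack@data)
  wf <- array(0, d[1:3])
  for (a in 1:3) for (p in 1:5) wf <- wf + stack@data[, , , p, a]
  wf <- wf / 15
  if (!upsample) return(wf)
  SRVolume(upsampleLateral2x(wf), "WF", stack@lateralPixelNm / 2, stack@axialStepNm)
}

setMethod("show", "RawStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("RawStack: %d x %d x %d (y, x, z), 3 angles x 5 phases\n",
              d[1], d[2], d[3]))
  cat(sprintf("  pixel %.4g nm lateral, %.4g nm axial; lambda_em %.4g nm, NA %.3g\n",
              object@lateralPixelNm, object@axialStepNm,
              object@wavelengthEmNm, object@na))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(object@data), max(object@data)))
})

setMethod("show", "IlluminationParams", function(object) {
  cat("IlluminationParams (3 angles x 5 phases)\n")
  for (a in 1:3) {
    p <- object@wavevectors[a, ]
    cat(sprintf(
      "  angle %d: p = (%.5f, %.5f) cyc/px (|p| = %.5f), phi0 = %.4f rad, a1 = %.3f, a2 = %.3f, I0 = %.3g\n",
      a, p[1], p[2], sqrt(sum(p^2)), object@phase0[a],
      object@a1[a], object@a2[a], object@I0[a]))
  }
  cat(sprintf("  phase steps: %s rad\n",
              paste(sprintf("%.4f", object@phaseSteps), collapse = ", ")))
})

setMethod("show", "OTFModel", function(object) {
  d <- dim(object@otf)
  cat(sprintf("OTFModel: %d x %d x %d grid, pixel %.4g x %.4g nm\n",
              d[1], d[2], d[3], object@lateralPixelNm, object@axialStepNm))
  cat(sprintf("  lambda_em %.4g nm, NA %.3g; cutoff %.4g (lateral), %.4g (axial) cycles/nm\n",
              object@wavelengthEmNm, object@na,
              object@cutoffLateral, object@cutoffAxial))
})

setMethod("show", "SRVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("SRVolume [%s]: %d x %d x %d, pixel %.4g nm lateral, %.4g nm axial\n",
              object@stage, d[1], d[2], d[3],
              object@lateralPixelNm, object@axialStepNm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(object@data), max(object@data)))
})

setMethod("show", "FilterBank", function(object) {
  cat("FilterBank:\n")
  cat(sprintf("  loSigma        %s cycles/px\n",
              ifelse(is.na(object@loSigma), "|p|/4 (auto)",
                     format(object@loSigma))))
  cat(sprintf("  notch          width %.4g cycles/px, depth %.3g\n",
              object@notchWidth, object@notchDepth))
  cat(sprintf("  apodization    %.3g x widefield cutoff (triangle)\n",
              object@apodizationCutoff))
  cat(sprintf("  two-step       wienerW %.4g, out-of-band %.3g, rolloff %.3g\n",
              object@wienerW, object@twostepParams[1], object@twostepParams[2]))
})

#' Default frequency-optimization filter settings
#'
#' @param loSigma HiLo low-pass cutoff (cycles/raw pixel); `NA` derives
#'   |p|/4 from the estimated pattern at run time.
#' @param notchWidth,notchDepth notch geometry at residual illumination
#'   peaks.
#' @param apodizationCutoff lateral apodization cutoff as a multiple of
#'   the widefield cutoff (covers the ~2x extended support with margin).
#' @param wienerW Wiener constant of the first noise-suppression pass.
#' @param twostepParams strengths of the second pass: out-of-band
#'   suppression (1 = hard zeroing) and Gaussian high-frequency rolloff.
#' @return a [FilterBank-class].
#' @export
defaultFilterBank <- function(loSigma = NA_real_, notchWidth = 0.01,
                              notchDepth = 0.95, apodizationCutoff = 2.4,
                              wienerW = 0.05, twostepParams = c(1, 0.5)) {
  obj <- new("FilterBank", loSigma = loSigma, notchWidth = notchWidth,
             notchDepth = notchDepth, apodizationCutoff = apodizationCutoff,
             wienerW = wienerW, twostepParams = twostepParams)
  validObject(obj)
  obj
}

#' Identity filter settings
#'
#' A configuration under which the frequency-optimization stage
#' reproduces its input to machine precision: notch depth 0, no
#' apodization, two-step filter disabled.
#' @return a [FilterBank-class].
#' @export
identityFilterBank <- function() {
  new("FilterBank", loSigma = NA_real_, notchWidth = 0.01, notchDepth = 0,
      apodizationCutoff = Inf, wienerW = 0, twostepParams = c(0, 0))
}
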