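# Final fusion: optimized super-resolution detail plus the HiLo optical
# section, clamped non-negative.

#' Fuse the optimized recombination with the optical section
#'
#' `SR2 = SR1 + osWeight * OS`, clamped at zero after the sum (never
#' before). The two inputs come from differently scaled pipelines, so an
#' explicit weight is exposed; the default re-scales the optical section
#' so that its total (DC) intensity matches the zero-order energy that
#' was removed before recombination, making the fusion ratio independent
#' of FFT normalization choices.
#'
#' @param sr1 an [SRVolume-class] with stage `"SR1"`.
#' @param os an [SRVolume-class] with stage `"OS"` on the same grid.
#' @param osWeight numeric weight, or `"dc"` (default) for zero-order
#'   energy matching; requires `zeroOrderEnergy`.
#' @param zeroOrderEnergy total intensity of the removed zero order on
#'   the SR grid (see [zeroOrderEnergy()]); only used for
#'   `osWeight = "dc"`.
#' @return an [SRVolume-class] with stage `"SR2"`, non-negative
#'   everywhere.
#' @export
fuseVolumes <- function(sr1, os, osWeight = "dc", zeroOrderEnergy = NULL) {
  if (srStage(sr1) != "SR1" || srStage(os) != "OS")
    stop("fuseVolumes expects stages SR1 and OS")
  if (!all(dim(sr1@data) == dim(os@data)))
    stop(sprintf("grid mismatch: SR1 is %s, OS is %s",
                 paste(dim(sr1@data), collapse = "x"),
                 paste(dim(os@data), collapse = "x")))
  if (abs(sr1@lateralPixelNm - os@lateralPixelNm) > 1e-9 ||
      abs(sr1@axialStepNm - os@axialStepNm) > 1e-9)
    stop("grid mismatch: pixel metadata differs between SR1 and OS")
  w <- osWeight
  if (identical(osWeight, "dc")) {
    if (is.null(zeroOrderEnergy))
      stop("osWeight = 'dc' requires zeroOrderEnergy")
    osSum <- sum(os@data)
    w <- if (osSum > 0) zeroOrderEnergy / osSum else 0
  }
  out <- pmax(sr1@data + w * os@data, 0)
  SRVolume(out, "SR2", sr1@lateralPixelNm, sr1@axialStepNm)
}

#' Total intensity of the removed zero order on the SR grid
#'
#' The widefield (zero-order) volume integrates to `sum(WF)` on the raw
#' grid; on the 2x lateral grid the same physical intensity corresponds
#' to four times that sum. Used for the default DC-matching fusion
#' weight.
#'
#' @param stack a [RawStack-class].
#' @return scalar.
#' @export
zeroOrderEnergy <- function(stack) {
  4 * sum(widefield(stack))
}
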