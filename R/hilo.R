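# HiLo optical sectioning from the raw data. The zero-order subtraction
# discards the in-focus low-frequency content together with the
# defocused background; the HiLo section restores the former: low-pass
# of a structured image (whose low frequencies are inherently sectioned
# by the pattern) plus high-pass of the widefield average (whose high
# frequencies are sectioned by the OTF itself).

#' Complementary Lo/Hi filter pair
#'
#' Gaussian low-pass `Lo(k) = exp(-|k|^2 / (2 sigma^2))` and its exact
#' complement `Hi(k) = 1 - Lo(k)` on a 2D lateral frequency grid, in
#' natural (unshifted) layout. `Lo + Hi = 1` at every frequency by
#' construction, so applying both and summing returns any image exactly.
#'
#' @param gridShape integer(2) lateral grid size (raw grid).
#' @param loSigma Gaussian cutoff in cycles/pixel (> 0).
#' @return list with real matrices `lo` and `hi`.
#' @export
makeLoHiPair <- function(gridShape, loSigma) {
  if (loSigma <= 0) stop("loSigma must be > 0")
  r2 <- lateralFreqRadius(gridShape[1], gridShape[2])^2
  lo <- exp(-r2 / (2 * loSigma^2))
  list(lo = lo, hi = 1 - lo)
}

#' HiLo optical section of an acquisition
#'
#' For each angle: low-pass of the first-phase structured image plus
#' high-pass of the five-phase average (the widefield image), filtered
#' per z plane in 2D; the three angles are averaged to cancel
#' illumination-intensity differences between angles. The result is
#' Fourier-upsampled 2x laterally onto the SR grid.
#'
#' With unmodulated input (all phases equal) the complementary pair
#' collapses to the identity and the section equals the widefield image
#' exactly.
#'
#' @param stack a [RawStack-class].
#' @param loSigma Gaussian low-pass cutoff (cycles/raw pixel). The
#'   conventional crossover is a quarter of the pattern frequency; pass
#'   `params` instead to derive it.
#' @param params optional [IlluminationParams-class]; when given and
#'   `loSigma` is `NA`, `loSigma = mean(|p|) / 4`.
#' @param upsample return on the 2x SR grid (default) or the raw grid.
#' @return an [SRVolume-class] with stage `"OS"`.
#' @export
opticalSection <- function(stack, loSigma = NA_real_, params = NULL,
                           upsample = TRUE) {
  if (is.na(loSigma)) {
    if (is.null(params))
      stop("either loSigma or params must be supplied")
    loSigma <- mean(sqrt(rowSums(params@wavevectors^2))) / 4
  }
  d <- dim(stack@data)
  filt <- makeLoHiPair(d[1:2], loSigma)
  os <- array(0, d[1:3])
  for (a in 1:3) {
    for (z in seq_len(d[3])) {
      wfz <- rowMeans(matrix(stack@data[, , z, , a], d[1] * d[2], 5L))
      dim(wfz) <- d[1:2]
      str1 <- stack@data[, , z, 1L, a]
      os[, , z] <- os[, , z] +
        Re(ifftn(fftn(str1) * filt$lo + fftn(wfz) * filt$hi))
    }
  }
  os <- os / 3
  if (!upsample)
    return(SRVolume(os, "OS", stack@lateralPixelNm, stack@axialStepNm))
  SRVolume(upsampleLateral2x(os), "OS", stack@lateralPixelNm / 2,
           stack@axialStepNm)
}
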