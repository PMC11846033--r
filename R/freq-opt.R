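# Frequency-domain optimization of the recombined volume: notch filters
# at residual illumination peaks, two-step noise suppression, and
# spectrum apodization. All filters are built symmetric about DC so the
# optimized volume stays real.
#
# The public operations take DC-centered spectra; the pipeline path
# fuses all windows into one pass over the natural-layout spectrum to
# avoid shifting multi-gigabyte arrays.

# ---- window builders (shared by the public ops and the fused path) ----

.freqAxes <- function(dims2, natural) {
  # lateral fine-grid frequencies in cycles per raw pixel
  fy <- fftFreq(dims2[1]) * 2
  fx <- fftFreq(dims2[2]) * 2
  if (!natural) {
    fy <- fftShift(fy); fx <- fftShift(fx)
  }
  list(fy = fy, fx = fx)
}

.notchWin2d <- function(dims2, params, notchWidth, notchDepth, natural) {
  ax <- .freqAxes(dims2, natural)
  win <- matrix(1, dims2[1], dims2[2])
  for (a in 1:3) for (m in c(-2, -1, 1, 2)) {
    pk <- m * params@wavevectors[a, ]
    d2 <- outer((ax$fy - pk[1])^2, (ax$fx - pk[2])^2, `+`)
    win <- win * (1 - notchDepth * exp(-d2 / (2 * notchWidth^2)))
  }
  win
}

.apodLat2d <- function(dims2, cutoffRawPx, natural) {
  ax <- .freqAxes(dims2, natural)
  pmax(1 - sqrt(outer(ax$fy^2, ax$fx^2, `+`)) / cutoffRawPx, 0)
}

.apodAx <- function(nz, cutoffAx, natural) {
  fz <- fftFreq(nz)
  if (!natural) fz <- fftShift(fz)
  pmax(1 - abs(fz) / cutoffAx, 0)
}

.oobRoll2d <- function(dims2, cutExt, twostepParams, natural) {
  ax <- .freqAxes(dims2, natural)
  rad <- sqrt(outer(ax$fy^2, ax$fx^2, `+`))
  (1 - twostepParams[1] * (rad > cutExt)) *
    exp(-twostepParams[2] * (rad / cutExt)^2)
}

# ---- public operations (DC-centered, as in the module contracts) ----

#' Notch filter at residual illumination peaks
#'
#' Multiplies a DC-centered 3D spectrum by
#' `1 - depth * exp(-d^2 / (2 w^2))` around each residual illumination
#' peak: lateral positions `+/-p_theta` and `+/-2 p_theta` for the three
#' angles, extended over all axial frequencies (the peaks are lateral
#' carriers). DC itself is untouched — the zero order was removed before
#' this stage.
#'
#' @param spectrum DC-centered complex 3D spectrum on the fine grid.
#' @param params an [IlluminationParams-class]; peak positions come from
#'   its wavevectors (cycles per raw pixel).
#' @param notchWidth Gaussian width (cycles per raw pixel).
#' @param notchDepth depth in \[0, 1\].
#' @return filtered spectrum.
#' @export
notchFilter <- function(spectrum, params, notchWidth = 0.01,
                        notchDepth = 0.95) {
  if (notchDepth < 0 || notchDepth > 1) stop("notchDepth must lie in [0, 1]")
  if (notchDepth == 0) return(spectrum)
  d <- dim(spectrum)
  win <- .notchWin2d(d[1:2], params, notchWidth, notchDepth, natural = FALSE)
  for (z in seq_len(d[3])) spectrum[, , z] <- spectrum[, , z] * win
  spectrum
}

#' Spectrum apodization
#'
#' Multiplies a DC-centered spectrum by a radially decreasing triangle
#' window: 1 at DC, 0 at `cutoffExtended` laterally, combined with a
#' triangle to twice the axial cutoff along kz. Suppresses ringing from
#' the hard edge of the extended support.
#'
#' @param spectrum DC-centered complex 3D spectrum on the fine grid.
#' @param cutoffExtended lateral cutoff in cycles per raw pixel (must be
#'   at least the widefield cutoff); `Inf` disables.
#' @param cutoffAxial axial cutoff in cycles per z step (`Inf` disables
#'   the axial factor).
#' @return apodized spectrum.
#' @export
apodize <- function(spectrum, cutoffExtended, cutoffAxial = Inf) {
  if (!is.finite(cutoffExtended) && !is.finite(cutoffAxial)) return(spectrum)
  d <- dim(spectrum)
  latWin <- if (is.finite(cutoffExtended))
    .apodLat2d(d[1:2], cutoffExtended, natural = FALSE)
  else matrix(1, d[1], d[2])
  axWin <- if (is.finite(cutoffAxial)) .apodAx(d[3], cutoffAxial, natural = FALSE)
           else rep(1, d[3])
  for (z in seq_len(d[3]))
    spectrum[, , z] <- spectrum[, , z] * (latWin * axWin[z])
  spectrum
}

#' Effective (coverage-summed) transfer magnitude
#'
#' Sum of |OTF| over all band placements (zero order at DC, first and
#' second orders at `+/-p`, `+/-2p` laterally for each angle), on the
#' fine grid. Peaks are placed at the nearest frequency bin — adequate
#' for a noise-suppression gain.
#'
#' @param otfFine an [OTFModel-class] built on the fine (2x lateral)
#'   grid.
#' @param params an [IlluminationParams-class].
#' @param natural return natural (DC at \[1,1,1\]) instead of centered
#'   layout.
#' @return real 3D array, normalized to 1 at its maximum.
#' @keywords internal
effectiveTransfer <- function(otfFine, params, natural = FALSE) {
  H <- Mod(otfFine@otf)
  if (natural) H <- ifftShift(H)
  d <- dim(H)
  eff <- H
  for (a in 1:3) for (m in c(-2, -1, 1, 2)) {
    sy <- round(m * params@wavevectors[a, 1] / 2 * d[1])
    sx <- round(m * params@wavevectors[a, 2] / 2 * d[2])
    iy <- ((seq_len(d[1]) - 1L - sy) %% d[1]) + 1L
    ix <- ((seq_len(d[2]) - 1L - sx) %% d[2]) + 1L
    eff <- eff + H[iy, ix, , drop = FALSE]
  }
  eff / max(eff)
}

#' Two-step low-SNR noise suppression
#'
#' Pass 1 applies a Wiener-style gain `|H| / (|H|^2 + w)` against the
#' effective coverage-summed transfer (scaled so its maximum gain is 1);
#' pass 2 suppresses out-of-band noise — frequencies beyond the extended
#' lateral support are attenuated by `1 - strength`, and a mild Gaussian
#' high-frequency rolloff of the given strength is applied inside the
#' band. The output magnitude is non-increasing in `w` at every
#' frequency.
#'
#' @param spectrum DC-centered complex 3D spectrum on the fine grid.
#' @param otfFine an [OTFModel-class] on the fine grid.
#' @param params an [IlluminationParams-class].
#' @param wienerW Wiener regularization constant (> 0).
#' @param twostepParams numeric(2): out-of-band suppression strength in
#'   \[0, 1\] and rolloff strength.
#' @return filtered spectrum.
#' @export
twoStepDenoise <- function(spectrum, otfFine, params, wienerW,
                           twostepParams = c(1, 0.5)) {
  if (wienerW <= 0) stop("wienerW must be > 0")
  d <- dim(spectrum)
  eff <- effectiveTransfer(otfFine, params)
  gain <- eff / (eff^2 + wienerW)
  gain <- gain / max(gain)
  pmagMax <- 2 * max(sqrt(rowSums(params@wavevectors^2)))
  cutWF <- otfFine@cutoffLateral * otfFine@lateralPixelNm * 2  # cyc/raw px
  win <- .oobRoll2d(d[1:2], cutWF + pmagMax, twostepParams, natural = FALSE)
  for (z in seq_len(d[3]))
    spectrum[, , z] <- spectrum[, , z] * (gain[, , z] * win)
  spectrum
}

#' Frequency-domain optimization of the recombined volume
#'
#' FFT of the zero-order-removed recombination, then notch filtering at
#' the residual illumination peaks, two-step noise suppression, and
#' apodization, then inverse FFT (real part). With
#' [identityFilterBank()] the input is reproduced to machine precision.
#' All enabled windows are fused into a single pass over the spectrum.
#'
#' Short stacks are padded axially before the FFT (edge-mirrored by 8
#' planes when `nz >= 8`, zero-padded otherwise) to suppress wrap-around
#' along z; the padding is removed afterwards.
#'
#' @param sr0minus an [SRVolume-class] with stage `"SR0_minus"`.
#' @param params an [IlluminationParams-class].
#' @param otfFine an [OTFModel-class] on the fine grid, ideally at the
#'   padded depth (`nz + 2*min(8, nz)`); rebuilt at that depth when it
#'   does not match. Needed when the two-step filter or apodization is
#'   enabled; may be `NULL` otherwise.
#' @param filters a [FilterBank-class].
#' @return an [SRVolume-class] with stage `"SR1"`.
#' @export
optimizeVolume <- function(sr0minus, params, otfFine = NULL,
                           filters = defaultFilterBank()) {
  if (srStage(sr0minus) != "SR0_minus")
    stop("optimizeVolume expects a stage SR0_minus volume")
  nz <- dim(sr0minus@data)[3]
  d <- c(dim(sr0minus@data)[1:2], .paddedNz(nz))

  wantTwoStep <- filters@wienerW > 0
  wantApod <- is.finite(filters@apodizationCutoff)
  wantNotch <- filters@notchDepth > 0
  if ((wantTwoStep || wantApod) && is.null(otfFine))
    stop("the two-step filter and apodization require otfFine")
  # the Wiener gain is smooth in frequency, so its transfer model may be
  # sampled on a coarser lateral grid (same pixel pitch, hence the same
  # frequency range) and interpolated onto the spectrum plane by plane
  gainGrid <- c(pmin(d[1:2], 512L), d[3])
  if (wantTwoStep && !all(dim(otfFine@otf)[c(1, 2)] <= d[1:2] &
                            dim(otfFine@otf)[3] == d[3])) {
    otfFine <- makeOTF3D(otfFine@na, otfFine@wavelengthEmNm,
                         otfFine@lateralPixelNm, otfFine@axialStepNm,
                         gainGrid, storePsf = FALSE)
  }

  # all windows are built before the forward transform so their
  # construction temporaries never coexist with the large spectrum
  latWin <- NULL; axWin <- rep(1, d[3]); gain <- NULL
  if (wantNotch || wantTwoStep || wantApod) {
    latWin <- matrix(1, d[1], d[2])
    if (wantNotch)
      latWin <- latWin * .notchWin2d(d[1:2], params, filters@notchWidth,
                                     filters@notchDepth, natural = TRUE)
    if (wantTwoStep) {
      gain <- effectiveTransfer(otfFine, params, natural = TRUE)
      gain <- gain / (gain^2 + filters@wienerW)
      gain <- gain / max(gain)
      pmagMax <- 2 * max(sqrt(rowSums(params@wavevectors^2)))
      cutWFts <- otfFine@cutoffLateral * otfFine@lateralPixelNm * 2
      latWin <- latWin * .oobRoll2d(d[1:2], cutWFts + pmagMax,
                                    filters@twostepParams, natural = TRUE)
    }
    if (wantApod) {
      rawPixelNm <- 2 * sr0minus@lateralPixelNm
      cutWF <- otfFine@cutoffLateral * rawPixelNm
      latWin <- latWin * .apodLat2d(d[1:2], filters@apodizationCutoff * cutWF,
                                    natural = TRUE)
      axWin <- .apodAx(d[3], 2 * otfFine@cutoffAxial * otfFine@axialStepNm,
                       natural = TRUE)
    }
  }

  padded <- .padAxial(sr0minus@data)
  spec <- fftnLarge(padded$x)                  # natural layout
  padded <- NULL
  if (!is.null(latWin)) {
    fyF <- fftFreq(d[1]); fxF <- fftFreq(d[2])
    sameGrid <- !is.null(gain) && all(dim(gain)[1:2] == d[1:2])
    for (z in seq_len(d[3])) {
      w <- latWin * axWin[z]
      if (!is.null(gain)) {
        gz <- if (sameGrid) gain[, , z]
              else .bilinearShift(gain[, , z], 0, 0, fyF, fxF)
        w <- w * gz
      }
      spec[, , z] <- spec[, , z] * w
    }
    rm(gain, latWin)
  }
  # inverse transform with the axial loop inlined: `spec` keeps a
  # reference count of one, so no second full-size complex copy appears
  if (d[3] > 1L) {
    block <- max(1L, (2^22) %/% (d[2] * d[3]))
    for (start in seq(1L, d[1], by = block)) {
      rows <- start:min(start + block - 1L, d[1])
      m <- matrix(aperm(spec[rows, , , drop = FALSE], c(3L, 1L, 2L)), d[3])
      m <- fftwtools::mvfftw_c2c(m, inverse = 1L) / d[3]
      spec[rows, , ] <- aperm(array(m, c(d[3], length(rows), d[2])),
                              c(2L, 3L, 1L))
    }
  }
  out <- array(0, d)
  for (z in seq_len(d[3])) out[, , z] <- Re(ifftn(spec[, , z]))
  rm(spec)
  out <- out[, , .padAxialKeep(nz, d[3]), drop = FALSE]
  SRVolume(out, "SR1", sr0minus@lateralPixelNm, sr0minus@axialStepNm)
}

.paddedNz <- function(nz) if (nz == 1L) 1L else nz + 2L * min(8L, nz)

# axial padding: mirror 8 planes when nz >= 8, zero-pad min(nz, 8) otherwise
.padAxial <- function(x) {
  nz <- dim(x)[3]
  if (nz == 1L) return(list(x = x, pad = 0L))
  pad <- min(8L, nz)
  d <- dim(x)
  out <- array(0, c(d[1], d[2], nz + 2L * pad))
  out[, , pad + seq_len(nz)] <- x
  if (nz >= 8L) {
    for (j in seq_len(pad)) {
      out[, , pad + 1L - j] <- x[, , j + 1L]
      out[, , pad + nz + j] <- x[, , nz - j]
    }
  }
  list(x = out, pad = pad)
}

.padAxialKeep <- function(nz, nzPadded) {
  pad <- (nzPadded - nz) %/% 2L
  pad + seq_len(nz)
}
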