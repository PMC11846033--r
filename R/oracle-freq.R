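# Classical frequency-domain 3D-SIM reconstruction: phase separation,
# band shifting, generalized Wiener combination. It exists as the
# correctness oracle for the spatial-domain core (the two must produce
# the same spectrum when run with matching weights) and as the
# "traditional" comparator.

#' Shift a band spectrum laterally
#'
#' Applies a lateral (possibly sub-pixel) shift to a DC-centered band
#' spectrum by multiplying the band with a linear phase ramp in real
#' space — exact for any sub-pixel shift, and identical to an array
#' roll for integer shifts.
#'
#' @param bandSpectrum DC-centered complex matrix or 3D array.
#' @param shiftVector numeric(2): shift in frequency bins along (ky, kx).
#' @return shifted spectrum, same layout.
#' @export
shiftBand <- function(bandSpectrum, shiftVector) {
  d <- dim(bandSpectrum)
  ny <- d[1]; nx <- d[2]
  band <- ifftn(ifftShift(bandSpectrum))
  yy <- matrix(0:(ny - 1L), ny, nx)
  xx <- matrix(0:(nx - 1L), ny, nx, byrow = TRUE)
  ramp <- exp(2i * pi * (shiftVector[1] * yy / ny + shiftVector[2] * xx / nx))
  if (length(d) == 3L) {
    for (z in seq_len(d[3])) band[, , z] <- band[, , z] * ramp
  } else {
    band <- band * ramp
  }
  fftShift(fftn(band))
}

#' Classical frequency-domain reconstruction
#'
#' Per angle, the five harmonic bands are separated with the phase
#' matrix, Fourier-upsampled onto the 2x lateral grid, demodulated
#' (divided by the starting-phase factor and the floored modulation
#' depth, exactly as the spatial core weights its harmonics), and
#' shifted to their true frequency positions by real-space phase ramps.
#' The shifted bands are then combined:
#'
#' * `combine = "wiener"`: generalized Wiener
#'   `sum_b Conj(H_b) S_b / (sum_b |H_b|^2 + w)` with the laterally
#'   shifted OTF as each band transfer, followed by triangular
#'   apodization.
#' * `combine = "plain"`: unit-weight band sum with no transfer
#'   weighting and no apodization — the configuration whose magnitude
#'   spectrum the spatial-domain recombination must reproduce.
#'
#' @param stack a [RawStack-class].
#' @param params an [IlluminationParams-class].
#' @param otfFine an [OTFModel-class] on the fine (2x lateral) grid;
#'   required for `combine = "wiener"`.
#' @param wienerW Wiener regularization constant.
#' @param includeZeroOrder keep the m = 0 band (classical
#'   reconstruction) or drop it (the comparison target for the
#'   zero-order-removed spatial core).
#' @param combine `"wiener"` or `"plain"`.
#' @param apodizationCutoff lateral apodization cutoff as a multiple of
#'   the widefield cutoff (wiener mode only).
#' @param depthFloor floor applied to a1, a2 before dividing.
#' @return an [SRVolume-class] with stage `"SR_ref"`.
#' @export
reconstructReference <- function(stack, params, otfFine = NULL,
                                 wienerW = 0.05, includeZeroOrder = TRUE,
                                 combine = c("wiener", "plain"),
                                 apodizationCutoff = 2.4,
                                 depthFloor = 0.05) {
  combine <- match.arg(combine)
  d <- dim(stack@data)
  fine <- c(2L * d[1], 2L * d[2], d[3])
  gc <- gridCoords(fine[1], fine[2], step = 0.5)
  yy <- gc$yy; xx <- gc$xx

  if (combine == "plain") {
    out <- array(0, fine)
    for (a in 1:3) {
      bands <- separateBands(stack, a, params@phaseSteps)
      ms <- c(-2:-1, 1:2)
      if (includeZeroOrder) ms <- -2:2
      for (m in ms) {
        bandFine <- upsampleLateral2x(bands[[.bandName(m)]])
        out <- out + Re(.demodRamp(bandFine, params, a, m, yy, xx, depthFloor))
      }
    }
    return(SRVolume(out, "SR_ref", stack@lateralPixelNm / 2,
                    stack@axialStepNm))
  }

  if (is.null(otfFine)) stop("combine = 'wiener' requires otfFine")
  if (dim(otfFine@otf)[3] != fine[3] ||
      abs(otfFine@lateralPixelNm - stack@lateralPixelNm / 2) > 1e-9)
    stop("otfFine must have the stack's z depth and the fine (2x) lateral pitch")
  # Everything below works plane-by-plane in natural frequency layout.
  # Only m = 0, +1, +2 are transformed; the conjugate bands are added by
  # Hermitian reflection of each term, which halves the work and memory.
  # Band transfers are evaluated by bilinear interpolation of the |OTF|
  # at the exact (sub-bin) shifted frequencies, so the OTF model may be
  # sampled on a coarser lateral grid with the same pixel pitch.
  Hnat <- ifftShift(Mod(otfFine@otf))
  fyF <- fftFreq(fine[1]); fxF <- fftFreq(fine[2])
  num <- array(0i, fine)
  den <- array(0, fine)
  reflY <- c(1L, fine[1]:2L); reflX <- c(1L, fine[2]:2L)
  reflZ <- c(1L, fine[3]:2L)[seq_len(fine[3])]
  for (a in 1:3) {
    ms <- if (includeZeroOrder) 0:2 else 1:2
    bands <- separateBands(stack, a, params@phaseSteps, harmonics = ms)
    for (m in ms) {
      bz <- .fftZInPlace(bands[[.bandName(m)]], inverse = FALSE)
      p <- params@wavevectors[a, ]
      amp <- switch(as.character(m), "0" = 1,
                    "1" = max(params@a1[a], depthFloor),
                    "2" = max(params@a2[a], depthFloor))
      ramp <- if (m == 0) 1 else
        exp(-1i * m * (2 * pi * (p[1] * yy + p[2] * xx)) -
              1i * m * params@phase0[a]) / amp
      for (j in seq_len(fine[3])) {
        b2 <- ifftn(padSpectrum2x(fftn(bz[, , j]))) * 4
        S2 <- fftn(b2 * ramp)
        # the demodulated band rho(k) H(k + m p) sits under the
        # laterally shifted transfer H(k + m p); p is in cycles/raw
        # pixel = 2x cycles/fine pixel
        Hb2 <- .bilinearShift(Hnat[, , j], m * p[1] / 2, m * p[2] / 2,
                              fyF, fxF)
        term <- Hb2 * S2
        num[, , j] <- num[, , j] + term
        den[, , j] <- den[, , j] + Hb2^2
        if (m > 0) {
          jr <- reflZ[j]
          num[, , jr] <- num[, , jr] + Conj(term[reflY, reflX])
          den[, , jr] <- den[, , jr] + Hb2[reflY, reflX]^2
        }
      }
      bands[[.bandName(m)]] <- NULL
      rm(bz)
    }
    rm(bands)
  }
  # per-plane Wiener division, apodization, and lateral inverse
  rawPixelNm <- stack@lateralPixelNm
  latWin <- .apodLat2d(fine[1:2],
                       apodizationCutoff * otfFine@cutoffLateral * rawPixelNm,
                       natural = TRUE)
  axWin <- .apodAx(fine[3], 2 * otfFine@cutoffAxial * stack@axialStepNm,
                   natural = TRUE)
  for (j in seq_len(fine[3])) {
    num[, , j] <- ifftn(num[, , j] / (den[, , j] + wienerW) *
                          (latWin * axWin[j]))
  }
  den <- NULL
  # axial inverse inlined so `num` is modified in place (one copy total)
  if (fine[3] > 1L) {
    block <- max(1L, (2^22) %/% (fine[2] * fine[3]))
    for (start in seq(1L, fine[1], by = block)) {
      rows <- start:min(start + block - 1L, fine[1])
      m <- matrix(aperm(num[rows, , , drop = FALSE], c(3L, 1L, 2L)), fine[3])
      m <- fftwtools::mvfftw_c2c(m, inverse = 1L) / fine[3]
      num[rows, , ] <- aperm(array(m, c(fine[3], length(rows), fine[2])),
                             c(2L, 3L, 1L))
    }
  }
  out <- array(0, fine)
  for (j in seq_len(fine[3])) out[, , j] <- Re(num[, , j])
  SRVolume(out, "SR_ref", stack@lateralPixelNm / 2, stack@axialStepNm)
}

.bandName <- function(m) if (m == 0L) "m0" else sprintf("m%+d", m)

# demodulate band m of one angle on the fine grid: divide by the
# starting-phase factor and floored depth, and apply the lateral ramp
# that moves its content to the true frequency position. Division is by
# a_m (the full depth, not a_m/2) so that each +/-m conjugate pair sums
# to the same weight the spatial core gives its harmonics.
.demodRamp <- function(bandFine, params, angle, m, yy, xx, depthFloor) {
  p <- params@wavevectors[angle, ]
  amp <- switch(as.character(abs(m)),
                "0" = 1,
                "1" = max(params@a1[angle], depthFloor),
                "2" = max(params@a2[angle], depthFloor))
  ramp <- exp(-1i * m * (2 * pi * (p[1] * yy + p[2] * xx)) -
                1i * m * params@phase0[angle]) / amp
  for (z in seq_len(dim(bandFine)[3])) bandFine[, , z] <- bandFine[, , z] * ramp
  bandFine
}

# integer-bin lateral roll of a centered 3D magnitude array by a shift
# given in cycles per raw pixel
.rollLateral <- function(H, pRaw, fine) {
  sy <- round(pRaw[1] / 2 * fine[1])
  sx <- round(pRaw[2] / 2 * fine[2])
  iy <- ((seq_len(fine[1]) - 1L - sy) %% fine[1]) + 1L
  ix <- ((seq_len(fine[2]) - 1L - sx) %% fine[2]) + 1L
  H[iy, ix, , drop = FALSE]
}
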