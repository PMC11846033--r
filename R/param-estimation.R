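# Illumination-parameter estimation by cross-correlation (the classical
# correlation method, run once per dataset as prior knowledge).

#' Separate harmonic bands of one angle
#'
#' Inverts the 5x5 phase matrix `E[i, m] = exp(1i * m * phi_i)`
#' (m = -2..+2) per pixel, turning the five phase-stepped images into the
#' five harmonic band images: m = 0 is the unmodulated (widefield)
#' component, m = +/-1 and +/-2 the sample spectrum shifted by -/+ p and
#' -/+ 2p.
#'
#' @param stack a [RawStack-class].
#' @param angle angle index in 1..3.
#' @param phaseSteps the five phase offsets (radians).
#' @param harmonics which m to return (subset of -2:2); computing only
#'   the needed bands keeps memory bounded on large stacks.
#' @return named list (`m-2`, `m-1`, `m0`, `m+1`, `m+2`, as requested)
#'   of complex 3D arrays on the raw grid.
#' @export
separateBands <- function(stack, angle, phaseSteps = 2 * pi * (0:4) / 5,
                          harmonics = -2:2) {
  if (length(phaseSteps) != 5L) stop("five phase steps required")
  E <- outer(phaseSteps, -2:2, function(ph, m) exp(1i * m * ph))
  sv <- svd(E)$d
  if (min(sv) < 1e-8 * max(sv))
    stop("singular phase matrix: duplicate phase steps")
  Einv <- solve(E)
  d <- dim(stack@data)
  npl <- d[1] * d[2]
  out <- lapply(harmonics, function(m) array(0i, d[1:3]))
  names(out) <- vapply(harmonics, .bandName, "")
  for (z in seq_len(d[3])) {
    flat <- matrix(as.numeric(stack@data[, , z, , angle]), npl, 5L)
    for (j in seq_along(harmonics)) {
      m <- harmonics[j]
      out[[j]][, , z] <- flat %*% Einv[m + 3L, ]
    }
  }
  out
}

#' Estimate the pattern wavevector of one angle
#'
#' Cross-correlates the m = +1 band against the m = 0 band: the product
#' `conj(m0) * m1`, averaged over z, carries a strong Fourier component
#' at the pattern frequency. The integer-bin peak of its 2D spectrum is
#' refined to sub-pixel precision by the phase-gradient of the
#' demodulated correlation (the slope of its complex phase), which is
#' deterministic and needs no search grid.
#'
#' @param stack a [RawStack-class].
#' @param angle angle index in 1..3.
#' @param phaseSteps phase offsets used for band separation.
#' @param minFreq smallest admissible |p| (cycles/pixel), excludes the
#'   low-frequency autocorrelation lobe.
#' @param significance required ratio of the correlation peak to its
#'   locally smoothed background; below it a "pattern not detected"
#'   error is raised.
#' @return list with `p` (numeric(2), cycles/pixel, (y, x) order) and
#'   `score` (peak sharpness ratio).
#' @export
estimateWavevector <- function(stack, angle,
                               phaseSteps = 2 * pi * (0:4) / 5,
                               minFreq = 0.1, significance = 4) {
  bands <- separateBands(stack, angle, phaseSteps, harmonics = c(0L, 1L))
  d <- dim(stack@data)
  if (sum(Mod(bands$`m+1`)^2) < 1e-10 * sum(Mod(bands$m0)^2))
    stop("pattern not detected: first-order band carries no energy")
  nz <- d[3]
  # phase correlation: whiten both band spectra so the correlation peak
  # reflects spectral alignment, not the sample's own envelope
  whiten <- function(img) {
    S <- fftn(img)
    m <- Mod(S)
    floor <- stats::quantile(m, 0.5)
    w <- m > floor
    S[w] <- S[w] / m[w]
    S[!w] <- 0i
    ifftn(S)
  }
  Q <- matrix(0i, d[1], d[2])
  for (z in seq_len(nz)) {
    n0 <- whiten(bands$m0[, , z])
    n1 <- whiten(bands$`m+1`[, , z])
    Q <- Q + Conj(n0) * n1
  }
  # 2x zero-padded spectrum for the coarse peak: halves the scalloping
  # loss when the pattern frequency falls between bins. The peak score
  # is the magnitude relative to a locally smoothed background, so the
  # sharp carrier peak stands out from any smooth correlation halo of
  # the sample structure itself.
  Qp <- matrix(0i, 2L * d[1], 2L * d[2])
  Qp[seq_len(d[1]), seq_len(d[2])] <- Q
  Qhp <- fftn(Qp)
  mag <- Mod(Qhp)
  g <- exp(-2 * pi^2 * 36 * outer(fftFreq(2L * d[1])^2,
                                  fftFreq(2L * d[2])^2, `+`))
  bgLocal <- Re(ifftn(fftn(mag) * g))
  sharp <- mag / (bgLocal + .Machine$double.eps)
  radP <- lateralFreqRadius(2L * d[1], 2L * d[2])
  sharp[radP < minFreq] <- 0
  peak <- which.max(sharp)
  score <- sharp[peak]
  if (score < significance)
    stop("pattern not detected: correlation peak below significance threshold")
  idx <- arrayInd(peak, 2L * d[1:2]) - 1L
  k0 <- c(idx[1], idx[2])
  k0[1] <- if (k0[1] >= d[1]) k0[1] - 2L * d[1] else k0[1]
  k0[2] <- if (k0[2] >= d[2]) k0[2] - 2L * d[2] else k0[2]
  k0 <- k0 / 2                                  # back to original-bin units
  Qh <- fftn(Q)
  # sub-pixel refinement: phase slope of the demodulated correlation,
  # band-limited to the neighborhood of the integer peak so unrelated
  # spectral content cannot bias the slope
  by <- fftFreq(d[1]) * d[1]; bx <- fftFreq(d[2]) * d[2]
  near <- outer((by - k0[1])^2, (bx - k0[2])^2, `+`) <= 16
  Qh[!near] <- 0i
  Qloc <- ifftn(Qh)
  yy <- matrix(0:(d[1] - 1L), d[1], d[2])
  xx <- matrix(0:(d[2] - 1L), d[1], d[2], byrow = TRUE)
  q <- Qloc * exp(-2i * pi * (k0[1] / d[1] * yy + k0[2] / d[2] * xx))
  sy <- sum(Conj(q[-d[1], ]) * q[-1, ])
  sx <- sum(Conj(q[, -d[2]]) * q[, -1])
  p <- c(k0[1] / d[1] + Arg(sy) / (2 * pi),
         k0[2] / d[2] + Arg(sx) / (2 * pi))
  # final polish: maximize the continuous-frequency correlation
  # magnitude around the current estimate (deterministic simplex)
  obj <- function(pp)
    -Mod(sum(Q * exp(-2i * pi * (pp[1] * yy + pp[2] * xx))))
  opt <- stats::optim(p, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
  # canonical sign: the m=+1 band peaks at +p by construction; keep as found
  list(p = opt$par, score = unname(score))
}

#' Estimate starting phase and modulation depths of one angle
#'
#' With the wavevector known, the m = +1 band is demodulated at +p and
#' the starting phase is recovered from a magnitude-weighted plane fit
#' of its complex phase: the intercept at the grid center is phi0
#' (the package references all carriers there), and the fitted slope
#' corrects any residual wavevector error (`pRefined`). The modulation
#' depths a1 and a2 come from a least-squares complex cross-ratio of
#' the demodulated first/second-order band spectra against the
#' zero-order band over the OTF-supported overlap region, with the
#' transfer ratio `H(k + m p) / H(k)` (from the scalar OTF model built
#' from the stack's own optics metadata) dividing out the differing
#' band attenuations.
#'
#' @param stack a [RawStack-class].
#' @param angle angle index.
#' @param p pattern wavevector (cycles/pixel, (y, x)).
#' @param phaseSteps phase offsets used for band separation.
#' @param otf optional [OTFModel-class] on the raw grid; built from the
#'   stack metadata when `NULL`.
#' @return list with `phase0` (radians, referenced at the grid center),
#'   `a1`, `a2`, and `pRefined` (slope-corrected wavevector).
#' @export
estimatePhaseAndDepths <- function(stack, angle, p,
                                   phaseSteps = 2 * pi * (0:4) / 5,
                                   otf = NULL) {
  bands <- separateBands(stack, angle, phaseSteps, harmonics = 0:2)
  d <- dim(stack@data)
  gc <- gridCoords(d[1], d[2])
  demod1 <- bands$`m+1` *
    as.vector(exp(-2i * pi * (p[1] * gc$yy + p[2] * gc$xx)))
  demod2 <- bands$`m+2` *
    as.vector(exp(-4i * pi * (p[1] * gc$yy + p[2] * gc$xx)))
  Wz <- demod1[, , 1]
  if (d[3] > 1L) for (z in 2:d[3]) Wz <- Wz + demod1[, , z]
  center <- Arg(sum(Wz))
  psi <- Arg(Wz * exp(-1i * center))
  wgt <- Mod(Wz)^2
  # the fit is dominated by the brightest pixels; restricting to them
  # keeps the solve cheap on large fields
  keep <- which(wgt >= stats::quantile(wgt, 1 - min(1, 2e5 / length(wgt))))
  X <- cbind(1, gc$yy[keep], gc$xx[keep])
  fit <- stats::lm.wfit(X, psi[keep], wgt[keep])
  phase0 <- .wrapPi(center + fit$coefficients[1])
  pRefined <- p + c(fit$coefficients[2], fit$coefficients[3]) / (2 * pi)
  if (is.null(otf))
    otf <- makeOTF3D(stack@na, stack@wavelengthEmNm, stack@lateralPixelNm,
                     stack@axialStepNm, d[1:3])
  H <- ifftShift(Re(otf@otf))                    # natural layout
  a1 <- 2 * .depthCross(bands$m0, demod1, pRefined, 1L, H, d)
  a2 <- 2 * .depthCross(bands$m0, demod2, pRefined, 2L, H, d)
  list(phase0 = unname(phase0), a1 = a1, a2 = a2, pRefined = unname(pRefined))
}

.wrapPi <- function(x) ((x + pi) %% (2 * pi)) - pi

# least-squares complex cross-ratio of the demodulated band against the
# zero-order band over the OTF-supported overlap region: the
# demodulated band spectrum is rho(k) H(k + m p) a_m / 2, the zero
# order rho(k) H(k), so regressing the former on B0 * H(k+mp)/H(k)
# gives a_m / 2 with noise averaging out of the cross term
.depthCross <- function(b0, bd, p, m, H, d) {
  B0 <- fftn(b0)
  Bd <- fftn(bd)
  fy <- fftFreq(d[1]); fx <- fftFreq(d[2])
  rad <- lateralFreqRadius(d[1], d[2])
  oob <- rad > 0.47                 # near-Nyquist corners: noise only
  num <- 0i; den <- 0
  for (z in seq_len(d[3])) {
    Hz <- H[, , z]
    Hs <- .bilinearShift(Hz, m * p[1], m * p[2], fy, fx)
    thr <- 0.05 * max(Hz)           # per-plane: 3D OTF bin values scale
    if (thr <= 0) next              # with the axial sampling density
    om <- Hz > thr & Hs > thr
    if (!any(om)) next
    ratio <- Hs[om] / Hz[om]
    X <- B0[, , z][om] * ratio
    num <- num + sum(Conj(X) * Bd[, , z][om])
    # the noise in B0 enters |X|^2 and would bias the ratio downward;
    # subtract its expected power, estimated out-of-band per plane
    nf <- if (any(oob)) stats::median(Mod(B0[, , z][oob])^2) else 0
    den <- den + sum(pmax(Mod(X)^2 - nf * ratio^2, 0))
  }
  if (den <= 0) stop("overlap region empty")
  Mod(num) / den
}

# bilinear interpolation of a natural-layout real 2D frequency map at
# frequencies (fy + py, fx + px). The map's own grid spacing comes from
# its dimensions, so `fy`/`fx` may sample a finer (or equal) grid than
# H2 itself — used both for shifted-OTF lookups and for evaluating
# coarsely sampled transfer maps on a fine spectrum grid.
.bilinearShift <- function(H2, py, px, fy, fx) {
  n1 <- nrow(H2); n2 <- ncol(H2)
  yi <- ((fy + py) %% 1) * n1
  xi <- ((fx + px) %% 1) * n2
  y0 <- floor(yi) %% n1; x0 <- floor(xi) %% n2
  wy <- yi - floor(yi); wx <- xi - floor(xi)
  y1 <- (y0 + 1L) %% n1; x1 <- (x0 + 1L) %% n2
  A <- H2[y0 + 1L, x0 + 1L]; B <- H2[y1 + 1L, x0 + 1L]
  C <- H2[y0 + 1L, x1 + 1L]; D <- H2[y1 + 1L, x1 + 1L]
  ((1 - wy) %o% (1 - wx)) * A + (wy %o% (1 - wx)) * B +
    ((1 - wy) %o% wx) * C + (wy %o% wx) * D
}

#' Estimate all illumination parameters of an acquisition
#'
#' Runs [estimateWavevector()] and [estimatePhaseAndDepths()] for the
#' three angles and assembles an [IlluminationParams-class]. Intended to
#' run once per dataset and be cached as prior knowledge (see
#' [writeIlluminationParams()]).
#'
#' @param stack a [RawStack-class].
#' @param phaseSteps assumed phase offsets.
#' @param zWindow pool at most this many central z planes. The pattern
#'   parameters are constant over depth, so a central window carries
#'   essentially all the information at a fraction of the cost.
#' @return an [IlluminationParams-class] with estimated wavevectors,
#'   starting phases and depths.
#' @export
estimateIllumination <- function(stack, phaseSteps = 2 * pi * (0:4) / 5,
                                 zWindow = 9L) {
  d <- dim(stack@data)
  if (d[3] > zWindow) {
    zc <- d[3] %/% 2L + 1L
    half <- zWindow %/% 2L
    sel <- max(1L, zc - half):min(d[3], zc + half)
    stack <- RawStack(stack@data[, , sel, , , drop = FALSE],
                      stack@lateralPixelNm, stack@axialStepNm,
                      stack@wavelengthEmNm, stack@na)
    d <- dim(stack@data)
  }
  wv <- matrix(0, 3, 2)
  ph <- numeric(3); a1 <- numeric(3); a2 <- numeric(3)
  otf <- makeOTF3D(stack@na, stack@wavelengthEmNm, stack@lateralPixelNm,
                   stack@axialStepNm, d[1:3])
  for (a in 1:3) {
    est <- estimateWavevector(stack, a, phaseSteps)
    pad <- estimatePhaseAndDepths(stack, a, est$p, phaseSteps, otf)
    wv[a, ] <- pad$pRefined
    ph[a] <- pad$phase0
    a1[a] <- min(pad$a1, 1)
    a2[a] <- min(pad$a2, a1[a])
  }
  IlluminationParams(wv, phase0 = ph, phaseSteps = phaseSteps,
                     a1 = a1, a2 = a2, I0 = 1)
}

#' Write / read illumination parameters as plain text
#'
#' Serializes one block per angle (`p_y`, `p_x`, `phase0`, `a1`, `a2`,
#' `I0`) plus the shared phase steps, in a flat `key = value` format
#' consumed by the reconstruction entry points.
#'
#' @param params an [IlluminationParams-class].
#' @param path file path.
#' @return `writeIlluminationParams` returns `path` invisibly;
#'   `readIlluminationParams` returns an [IlluminationParams-class].
#' @export
writeIlluminationParams <- function(params, path) {
  lines <- c("# illumination parameters",
             sprintf("phase_steps = %s",
                     paste(format(params@phaseSteps, digits = 17), collapse = " ")))
  for (a in 1:3) {
    lines <- c(lines, sprintf("[angle%d]", a),
      sprintf("p_y = %s", format(params@wavevectors[a, 1], digits = 17)),
      sprintf("p_x = %s", format(params@wavevectors[a, 2], digits = 17)),
      sprintf("phase0 = %s", format(params@phase0[a], digits = 17)),
      sprintf("a1 = %s", format(params@a1[a], digits = 17)),
      sprintf("a2 = %s", format(params@a2[a], digits = 17)),
      sprintf("I0 = %s", format(params@I0[a], digits = 17)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeIlluminationParams
#' @export
readIlluminationParams <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cur <- 0L
  steps <- NULL
  wv <- matrix(0, 3, 2); ph <- numeric(3)
  a1 <- numeric(3); a2 <- numeric(3); I0 <- rep(1, 3)
  for (ln in lines) {
    if (grepl("^\\[angle[123]\\]$", ln)) {
      cur <- as.integer(sub("^\\[angle([123])\\]$", "\\1", ln))
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed parameter line: ", ln)
    key <- trimws(kv[1]); val <- as.numeric(strsplit(trimws(kv[2]), "\\s+")[[1]])
    if (key == "phase_steps") { steps <- val; next }
    if (cur == 0L) stop("parameter outside an [angleN] block: ", ln)
    switch(key,
           p_y = wv[cur, 1] <- val, p_x = wv[cur, 2] <- val,
           phase0 = ph[cur] <- val, a1 = a1[cur] <- val,
           a2 = a2[cur] <- val, I0 = I0[cur] <- val,
           stop("unknown parameter key: ", key))
  }
  if (is.null(steps)) steps <- 2 * pi * (0:4) / 5
  IlluminationParams(wv, phase0 = ph, phaseSteps = steps,
                     a1 = a1, a2 = a2, I0 = I0)
}
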