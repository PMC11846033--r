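test_that("point phantom records exact pair geometry at the requested separation", {
  ph <- makePhantom("point", c(128, 128, 9), spacingNm = 150, pitchVox = 32)
  expect_true(all(ph$volume >= 0))
  expect_gt(nrow(ph$truth), 4)
  lat <- ph$truth[ph$truth$orientation %in% c("x", "y"), ]
  expect_true(all(lat$separationNm == round(150 / 62.5) * 62.5))
  # truth rows point at actual density maxima
  for (k in seq_len(min(4, nrow(ph$truth)))) {
    r <- ph$truth[k, ]
    expect_gt(ph$volume[r$y1, r$x1, r$z1], 0)
    expect_gt(ph$volume[r$y2, r$x2, r$z2], 0)
  }
  expect_error(makePhantom("point", c(64, 64, 5), spacingNm = 10), "voxel")
})

test_that("zero-separation line phantom degenerates to single lines", {
  ph <- makePhantom("line", c(64, 64, 5), spacingNm = 0)
  expect_true(all(ph$truth$merged))
  ph2 <- makePhantom("line", c(64, 64, 5), spacingNm = 250)
  expect_false(any(ph2$truth$merged))
  expect_true(all(ph2$truth$separationNm == round(250 / 62.5) * 62.5))
})

test_that("circle phantom integrates to the analytic circumference", {
  r <- 20
  amp <- 2.5
  ph <- makePhantom("circle", c(128, 128, 5), radiusVox = r, amplitude = amp)
  # analytic oracle: integrating the unit-integral radial profile around
  # the ring gives amplitude * circumference exactly (the 2*pi*int of
  # r * tent(r - R) dr reduces to 2*pi*R by symmetry of the tent)
  expect_equal(sum(ph$volume) / (2 * pi * r * amp), 1, tolerance = 0.01)
  expect_equal(ph$truth$radiusNm, r * 62.5)
})

test_that("scalar OTF has the analytic lateral cutoff and is normalized", {
  otf <- fixOtf128()
  H <- otf@otf
  d <- dim(H)
  expect_equal(Mod(H[d[1] / 2 + 1, d[2] / 2 + 1, d[3] %/% 2 + 1]), 1,
               tolerance = 1e-9)
  expect_lte(max(Mod(H)), 1 + 1e-9)
  fr <- SpatialSIM:::fftShift(SpatialSIM:::lateralFreqRadius(d[1], d[2])) /
    otf@lateralPixelNm
  beyond <- vapply(seq_len(d[3]),
                   function(z) max(Mod(H[, , z])[fr > otf@cutoffLateral * 1.001]),
                   0)
  expect_lt(max(beyond), 1e-12)
  expect_true(all(otf@psf >= -1e-12))
  expect_equal(sum(otf@psf), 1, tolerance = 1e-9)
})

test_that("focal-plane PSF width matches the Airy model within 10%", {
  otf <- fixOtf128()
  pz <- otf@psf[, 65, 5]
  pz <- pz / max(pz)
  i0 <- which.max(pz)
  xs <- (seq_along(pz) - i0) * 62.5
  half <- stats::approx(pz[i0:(i0 + 6)], xs[i0:(i0 + 6)], xout = 0.5)$y
  fwhm <- 2 * half
  expect_equal(fwhm, 0.51 * 525 / 1.4, tolerance = 0.1)
})

test_that("psf and otf are a transform pair", {
  otf <- fixOtfTiny()
  back <- Re(SpatialSIM:::ifftn(SpatialSIM:::ifftShift(otf@otf)))
  back <- SpatialSIM:::fftShift(back)
  expect_equal(back / sum(back), otf@psf, tolerance = 1e-9)
})

test_that("OTF model rejects unphysical inputs", {
  expect_error(makeOTF3D(1.6, 525, 62.5, 125, c(64, 64, 5)), "1.52")
  expect_error(makeOTF3D(1.4, -5, 62.5, 125, c(64, 64, 5)), "positive")
  expect_error(makeOTF3D(1.4, 525, 62.5, 125, c(16, 16, 5)), "too small")
})

test_that("unmodulated acquisition reduces to the widefield blur", {
  ph <- fixPhantom128()
  il0 <- defaultIllumination(a1 = 0, a2 = 0)
  stk <- simulateAcquisition(ph, il0, fixOtf128(), noise = NULL)
  d <- rawData(stk)
  ref <- d[, , , 1, 1]
  for (a in 1:3) for (i in 1:5)
    expect_equal(d[, , , i, a], ref, tolerance = 1e-12)
  # equals the direct psf convolution of the density
  H <- SpatialSIM:::ifftShift(fixOtf128()@otf)
  wfBlur <- Re(SpatialSIM:::ifftn(SpatialSIM:::fftn(ph$volume) * H))
  expect_equal(ref, wfBlur, tolerance = 1e-10)
})

test_that("summing the five phases cancels the sinusoidal excitation", {
  stk <- fixStackClean128()
  d <- rawData(stk)
  for (a in 1:3) {
    tot <- d[, , , 1, a] + d[, , , 2, a] + d[, , , 3, a] +
      d[, , , 4, a] + d[, , , 5, a]
    wf5 <- 5 * apply(d[, , , , a], 1:3, mean)
    expect_equal(tot, wf5, tolerance = 1e-12)
  }
})

test_that("demodulated first-order image carries a coherent peak at +p", {
  # phase demodulation across the five steps isolates the first-order
  # coefficient e^(i Omega(r)); sampled at many sparse emitters it
  # carries the pattern carrier. The spectrum argmax away from the OTF's
  # own low-frequency lobe sits at +p (oracle: brute-force argmax on the
  # zero-padded FFT); the 2p and -p components cancel by orthogonality.
  ph <- makePhantom("point", c(64, 64, 5), spacingNm = 150, pitchVox = 12,
                    pointSigmaNm = 0)
  il <- fixIllum()
  stk <- simulateAcquisition(ph, il, fixOtfTiny(), noise = NULL)
  d <- rawData(stk)
  yy <- matrix(0:63, 64, 64); xx <- t(yy)
  for (a in 1:3) {
    demod <- matrix(0i, 64, 64)
    for (i in 1:5)
      demod <- demod + d[, , 3, i, a] * exp(-1i * il@phaseSteps[i])
    spectrumAt <- function(k)
      Mod(sum(demod * exp(-2i * pi * (k[1] * yy + k[2] * xx))))
    p <- il@wavevectors[a, ]
    pmag <- sqrt(sum(p^2))
    # brute-force sweep over the |p| ring: the true direction must win,
    # and by a wide margin over the incoherent level at equal |k| (equal
    # OTF attenuation)
    th0 <- atan2(p[1], p[2])
    ths <- th0 + seq(-pi, pi - pi / 36, by = pi / 36)
    vals <- vapply(ths, function(th)
      spectrumAt(pmag * c(sin(th), cos(th))), 0)
    expect_equal(ths[which.max(vals)], th0, tolerance = 1e-9)
    expect_gt(max(vals), 5 * stats::median(vals))
  }
})

test_that("identical seeds give bit-identical noisy stacks", {
  ph <- fixPhantom128()
  il <- fixIllum()
  s1 <- simulateAcquisition(ph, il, fixOtf128(),
                            noise = list(photonBudget = 200, readSigma = 2),
                            rngSeed = 11)
  s2 <- simulateAcquisition(ph, il, fixOtf128(),
                            noise = list(photonBudget = 200, readSigma = 2),
                            rngSeed = 11)
  expect_identical(rawData(s1), rawData(s2))
  s3 <- simulateAcquisition(ph, il, fixOtf128(),
                            noise = list(photonBudget = 200, readSigma = 2),
                            rngSeed = 12)
  expect_false(identical(rawData(s1), rawData(s3)))
  expect_error(simulateAcquisition(ph, il, fixOtf128(),
                                   noise = list(photonBudget = 0, readSigma = 2)),
               "photonBudget")
})

test_that("background is a smooth additive term, separable by subtraction", {
  ph <- fixPhantom128()
  il <- fixIllum()
  s0 <- simulateAcquisition(ph, il, fixOtf128(), backgroundStrength = 0,
                            noise = NULL)
  s1 <- simulateAcquisition(ph, il, fixOtf128(), backgroundStrength = 2,
                            noise = NULL)
  diff1 <- rawData(s1)[, , 5, 1, 1] - rawData(s0)[, , 5, 1, 1]
  diff2 <- rawData(s1)[, , 5, 4, 2] - rawData(s0)[, , 5, 4, 2]
  # identical across phases/angles (phase-independent additive term)
  expect_equal(diff1, diff2, tolerance = 1e-10)
  # and smooth: energy above 0.1 cycles/pixel is negligible
  D <- Mod(SpatialSIM:::fftn(diff1))
  rad <- SpatialSIM:::lateralFreqRadius(128, 128)
  expect_lt(sum(D[rad > 0.1]^2), 1e-6 * sum(D^2))
})
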