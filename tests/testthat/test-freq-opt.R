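test_that("zero-depth notch is the identity and bad depths error", {
  spec <- array(stats::rnorm(32 * 32 * 3) + 1i * stats::rnorm(32 * 32 * 3),
                c(32, 32, 3))
  il <- fixIllum()
  expect_identical(notchFilter(spec, il, notchDepth = 0), spec)
  expect_error(notchFilter(spec, il, notchDepth = 1.2), "\\[0, 1\\]")
})

test_that("a full-depth notch removes a spike at the illumination peak", {
  il <- fixIllum()
  n <- 128
  spec <- array(0i, c(n, n, 3))
  fy <- SpatialSIM:::fftShift(SpatialSIM:::fftFreq(n)) * 2
  pk <- il@wavevectors[1, ]
  iy <- which.min(abs(fy - pk[1])); ix <- which.min(abs(fy - pk[2]))
  spec[iy, ix, 2] <- 100 + 0i
  out <- notchFilter(spec, il, notchWidth = 0.01, notchDepth = 1)
  expect_lt(Mod(out[iy, ix, 2]), 0.01 * 100)
})

test_that("the notch leaves energy far from every peak untouched", {
  il <- fixIllum()
  n <- 128
  set.seed(4)
  spec <- array(stats::rnorm(n * n * 3) + 1i * stats::rnorm(n * n * 3),
                c(n, n, 3))
  out <- notchFilter(spec, il, notchWidth = 0.01, notchDepth = 1)
  fy <- SpatialSIM:::fftShift(SpatialSIM:::fftFreq(n)) * 2
  dmin <- array(Inf, c(n, n))
  for (a in 1:3) for (m in c(-2, -1, 1, 2)) {
    pk <- m * il@wavevectors[a, ]
    dmin <- pmin(dmin, outer((fy - pk[1])^2, (fy - pk[2])^2, `+`))
  }
  far <- sqrt(dmin) > 5 * 0.01
  for (z in 1:3) {
    rel <- Mod(out[, , z][far] - spec[, , z][far]) / (Mod(spec[, , z][far]) + 1e-12)
    expect_lt(max(rel), 0.001)
  }
})

test_that("apodization is the stated triangular window", {
  n <- 64
  spec <- array(1 + 0i, c(n, n, 3))
  out <- apodize(spec, cutoffExtended = 0.5, cutoffAxial = Inf)
  fy <- SpatialSIM:::fftShift(SpatialSIM:::fftFreq(n)) * 2
  rad <- sqrt(outer(fy^2, fy^2, `+`))
  expected <- pmax(1 - rad / 0.5, 0)
  expect_equal(Re(out[, , 2]), expected, tolerance = 1e-12)
  expect_true(all(Mod(out)[rep(rad > 0.5, 3)] == 0))
})

test_that("apodized point response has sidelobes below 5%", {
  n <- 256
  spec <- array(1 + 0i, c(n, n, 1))      # delta in real space
  out <- apodize(spec, cutoffExtended = 0.4, cutoffAxial = Inf)
  img <- Re(SpatialSIM:::ifftn(SpatialSIM:::ifftShift(out[, , 1])))
  img <- SpatialSIM:::fftShift(img)
  pk <- max(img)
  center <- which(img == pk, arr.ind = TRUE)[1, ]
  prof <- img[center[1], ]
  # first zero crossing after the main lobe, then the largest sidelobe
  i <- center[2]
  while (i < n && prof[i + 1] > 0) i <- i + 1
  expect_lt(max(abs(prof[(i + 1):n])), 0.05 * pk)
})

test_that("two-step filter tends to a matched filter for large w", {
  il <- fixIllum()
  otfF <- fixOtfFineTiny()
  n <- dim(otfF@otf)
  set.seed(9)
  spec <- array(stats::rnorm(prod(n)) + 1i * stats::rnorm(prod(n)), n)
  big <- twoStepDenoise(spec, otfF, il, wienerW = 1e6,
                        twostepParams = c(0, 0))
  eff <- SpatialSIM:::effectiveTransfer(otfF, il)
  matched <- spec * (eff / max(eff))
  expect_equal(big, matched, tolerance = 1e-6)
  expect_error(twoStepDenoise(spec, otfF, il, wienerW = 0), "wienerW")
})

test_that("pure out-of-band noise is suppressed below 1%", {
  il <- fixIllum()
  otfF <- fixOtfFineTiny()
  n <- dim(otfF@otf)
  fy <- SpatialSIM:::fftShift(SpatialSIM:::fftFreq(n[1])) * 2
  rad <- sqrt(outer(fy^2, fy^2, `+`))
  cutExt <- otfF@cutoffLateral * otfF@lateralPixelNm * 2 +
    2 * max(sqrt(rowSums(il@wavevectors^2)))
  set.seed(10)
  spec <- array(0i, n)
  for (z in seq_len(n[3])) {
    pl <- matrix(stats::rnorm(n[1] * n[2]) + 1i * stats::rnorm(n[1] * n[2]),
                 n[1], n[2])
    pl[rad <= cutExt * 1.02] <- 0i
    spec[, , z] <- pl
  }
  out <- twoStepDenoise(spec, otfF, il, wienerW = 0.05)
  expect_lt(sum(Mod(out)^2), 0.01 * sum(Mod(spec)^2))
})

test_that("suppression is monotone in the Wiener constant", {
  il <- fixIllum()
  otfF <- fixOtfFineTiny()
  n <- dim(otfF@otf)
  set.seed(11)
  spec <- array(stats::rnorm(prod(n)) + 1i * stats::rnorm(prod(n)), n)
  norms <- vapply(c(0.01, 0.05, 0.2, 1, 5), function(w)
    sqrt(sum(Mod(twoStepDenoise(spec, otfF, il, wienerW = w))^2)), 0)
  expect_true(all(diff(norms) < 1e-9))
})

test_that("the identity filter bank reproduces the input to machine precision", {
  stk <- fixStackTiny()
  il <- fixIllum()
  sr0 <- recombineSpatial(stk, il)
  sr1 <- optimizeVolume(sr0, il, filters = identityFilterBank())
  expect_identical(srStage(sr1), "SR1")
  expect_lt(max(abs(srData(sr1) - srData(sr0))), 1e-10 * max(abs(srData(sr0))))
})

test_that("default optimization output is real-valued and finite", {
  stk <- fixStackTiny()
  il <- fixIllum()
  sr0 <- recombineSpatial(stk, il)
  sr1 <- optimizeVolume(sr0, il, fixOtfFineTiny(), defaultFilterBank())
  expect_true(all(is.finite(srData(sr1))))
  expect_identical(dim(srData(sr1)), dim(srData(sr0)))
})

test_that("interior planes of a short stack match the long-stack result", {
  # frequency optimization couples planes only through the padded axial
  # FFT; interior planes of a 3-layer run must closely match the same
  # planes of a deeper run
  ph <- makePhantom("point", c(64, 64, 22), spacingNm = 150, pitchVox = 16,
                    lateralPixelNm = 62.5, axialStepNm = 125)
  il <- fixIllum()
  otf <- makeOTF3D(1.4, 525, 62.5, 125, c(64, 64, 22))
  stk <- simulateAcquisition(ph, il, otf, noise = NULL)
  otfF <- makeOTF3D(1.4, 525, 31.25, 125,
                    c(128, 128, SpatialSIM:::.paddedNz(22)), storePsf = FALSE)
  srFull <- optimizeVolume(recombineSpatial(stk, il), il, otfF,
                           defaultFilterBank())
  sub <- RawStack(rawData(stk)[, , 10:12, , , drop = FALSE],
                  stk@lateralPixelNm, stk@axialStepNm,
                  stk@wavelengthEmNm, stk@na)
  otfF3 <- makeOTF3D(1.4, 525, 31.25, 125,
                     c(128, 128, SpatialSIM:::.paddedNz(3)), storePsf = FALSE)
  srShort <- optimizeVolume(recombineSpatial(sub, il), il, otfF3,
                            defaultFilterBank())
  full11 <- srData(srFull)[, , 11]
  short2 <- srData(srShort)[, , 2]
  expect_lt(relL2(short2, full11), 0.25)
})
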