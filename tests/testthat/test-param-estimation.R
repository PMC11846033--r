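test_that("band separation recovers the harmonics of the phase model", {
  # oracle: direct per-pixel least squares against the known phase design
  stk <- fixStackTiny()
  il <- fixIllum()
  bands <- separateBands(stk, 1)
  d <- dim(rawData(stk))
  E <- outer(il@phaseSteps, -2:2, function(ph, m) exp(1i * m * ph))
  flat <- matrix(rawData(stk)[, , , , 1], prod(d[1:3]), 5L)
  ls <- t(qr.solve(E, t(flat)))                  # independent solve route
  for (j in 1:5)
    expect_equal(as.vector(bands[[j]]), ls[, j], tolerance = 1e-9)
  # the m=+1 band carries a coherent spectral component at +p: its value
  # there dwarfs the incoherent level on the same frequency annulus
  yy <- matrix(0:63, 64, 64); xx <- t(yy)
  atP <- function(k) Mod(sum(bands$`m+1`[, , 3] *
                               exp(-2i * pi * (k[1] * yy + k[2] * xx))))
  p <- il@wavevectors[1, ]
  offs <- sapply(seq(0.3, 2 * pi - 0.3, length.out = 12), function(th)
    atP(sqrt(sum(p^2)) * c(sin(th), cos(th))))
  expect_gt(atP(p), 5 * stats::median(offs))
})

test_that("unmodulated stacks put all energy in the zero-order band", {
  ph <- fixPhantom128()
  il0 <- defaultIllumination(a1 = 0, a2 = 0)
  stk <- simulateAcquisition(ph, il0, fixOtf128(), noise = NULL)
  bands <- separateBands(stk, 1)
  wf <- apply(rawData(stk)[, , , , 1], 1:3, mean)
  expect_equal(Re(bands$m0), wf, tolerance = 1e-10)
  expect_lt(sum(Mod(bands$`m+1`)^2), 1e-16 * sum(Mod(bands$m0)^2))
  expect_lt(sum(Mod(bands$`m+2`)^2), 1e-16 * sum(Mod(bands$m0)^2))
})

test_that("duplicate phase steps make the phase matrix singular", {
  stk <- fixStackTiny()
  expect_error(separateBands(stk, 1, phaseSteps = c(0, 0, 1, 2, 3)),
               "singular")
})

test_that("wavevector recovery is sub-bin accurate without noise", {
  # the documented reference case: p = (0.12, 0.05) cycles/pixel
  ph <- makePhantom("point", c(128, 128, 5), spacingNm = 150, pitchVox = 32)
  wv <- matrix(c(0.12, 0.05,
                 -0.05, 0.12,
                 0.08, -0.10), 3, 2, byrow = TRUE)
  il <- IlluminationParams(wv, phase0 = c(0.5, 1.5, 2.5), a1 = 0.9, a2 = 0.45)
  otf <- makeOTF3D(1.4, 525, 62.5, 125, c(128, 128, 5))
  stk <- simulateAcquisition(ph, il, otf, noise = NULL)
  for (a in 1:3) {
    est <- estimateWavevector(stk, a)
    expect_lt(max(abs(est$p - wv[a, ])), 0.005)
  }
})

test_that("zero modulation raises a pattern-not-detected error", {
  ph <- fixPhantom128()
  il0 <- defaultIllumination(a1 = 0, a2 = 0)
  stk <- simulateAcquisition(ph, il0, fixOtf128(), noise = NULL)
  expect_error(estimateWavevector(stk, 1), "pattern not detected")
  stkN <- simulateAcquisition(ph, il0, fixOtf128(),
                              noise = list(photonBudget = 500, readSigma = 2),
                              rngSeed = 5)
  expect_error(estimateWavevector(stkN, 1), "pattern not detected")
})

test_that("wavevector recovery stays accurate at a low photon budget", {
  ph <- fixPhantom128()
  il <- fixIllum()
  errs <- vapply(1:10, function(s) {
    stk <- simulateAcquisition(ph, il, fixOtf128(),
                               noise = list(photonBudget = 100, readSigma = 2),
                               rngSeed = s)
    est <- estimateWavevector(stk, 1)
    max(abs(est$p - il@wavevectors[1, ]))
  }, 0)
  expect_lt(stats::median(errs), 0.01)
})

test_that("starting phase and modulation depths are recovered", {
  ph <- fixPhantom128()
  wv <- fixIllum()@wavevectors
  il <- IlluminationParams(wv, phase0 = c(0.7, 1.9, -2.0),
                           a1 = 0.9, a2 = 0.45)
  stk <- simulateAcquisition(ph, il, fixOtf128(), noise = NULL)
  for (a in 1:3) {
    pad <- estimatePhaseAndDepths(stk, a, il@wavevectors[a, ])
    expect_lt(abs(wrapPi(pad$phase0 - il@phase0[a])), 0.05)
    expect_lt(abs(pad$a1 - 0.9) / 0.9, 0.1)
    expect_lt(abs(pad$a2 - 0.45) / 0.45, 0.1)
  }
})

test_that("rotating the phase series shifts the estimated phase by one step", {
  stk <- fixStackClean128()
  il <- fixIllum()
  d <- rawData(stk)
  rot <- d[, , , c(2, 3, 4, 5, 1), , drop = FALSE]
  stkRot <- RawStack(rot, stk@lateralPixelNm, stk@axialStepNm,
                     stk@wavelengthEmNm, stk@na)
  p <- il@wavevectors[1, ]
  ph1 <- estimatePhaseAndDepths(stk, 1, p)$phase0
  ph2 <- estimatePhaseAndDepths(stkRot, 1, p)$phase0
  expect_lt(abs(wrapPi(ph2 - ph1 - il@phaseSteps[2])), 1e-6)
})

test_that("translating the recorded frame changes the phase but not the wavevector", {
  # circularly shifting the acquired images moves the recorded pattern
  # with them: the wavevector estimate is unchanged, and with
  # d2[y] = d1[y + shift] the starting phase grows by 2*pi * p_y * shift
  s1 <- fixStackClean128()
  il <- fixIllum()
  shift <- 10L
  d2 <- rawData(s1)[c((shift + 1):128, 1:shift), , , , , drop = FALSE]
  s2 <- RawStack(d2, s1@lateralPixelNm, s1@axialStepNm,
                 s1@wavelengthEmNm, s1@na)
  e1 <- estimateWavevector(s1, 2)
  e2 <- estimateWavevector(s2, 2)
  expect_lt(max(abs(e1$p - e2$p)), 1e-3)
  p1 <- estimatePhaseAndDepths(s1, 2, il@wavevectors[2, ])$phase0
  p2 <- estimatePhaseAndDepths(s2, 2, il@wavevectors[2, ])$phase0
  expected <- 2 * pi * il@wavevectors[2, 1] * shift
  # the circular wrap seam perturbs the weighted phase fit slightly
  expect_lt(abs(wrapPi(p2 - p1 - expected)), 0.15)
})

test_that("full estimation round trip recovers the generating parameters", {
  stk <- fixStackNoisy128()
  il <- fixIllum()
  est <- estimateIllumination(stk)
  expect_lt(max(abs(est@wavevectors - il@wavevectors)), 0.005)
  expect_lt(max(abs(wrapPi(est@phase0 - il@phase0))), 0.15)
  expect_lt(max(abs(est@a1 - il@a1) / il@a1), 0.15)
})

test_that("parameters serialize to text and back", {
  il <- estimateIllumination(fixStackClean128())
  f <- tempfile(fileext = ".txt")
  writeIlluminationParams(il, f)
  back <- readIlluminationParams(f)
  expect_equal(back@wavevectors, il@wavevectors, tolerance = 1e-14)
  expect_equal(back@phase0, il@phase0, tolerance = 1e-14)
  expect_equal(back@a1, il@a1, tolerance = 1e-14)
  expect_equal(back@a2, il@a2, tolerance = 1e-14)
  expect_equal(back@phaseSteps, il@phaseSteps, tolerance = 1e-14)
  unlink(f)
})
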