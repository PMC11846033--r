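test_that("zero-order removal leaves exactly zero phase-mean", {
  stk <- fixStackTiny()
  dz <- removeZeroOrder(stk, 2)
  m <- dz[, , , 1] + dz[, , , 2] + dz[, , , 3] + dz[, , , 4] + dz[, , , 5]
  expect_lt(max(abs(m)), 1e-10)
})

test_that("unmodulated input is annihilated by zero-order removal", {
  ph <- fixPhantom128()
  il0 <- defaultIllumination(a1 = 0, a2 = 0)
  stk <- simulateAcquisition(ph, il0, fixOtf128(), noise = NULL)
  dz <- removeZeroOrder(stk, 1)
  expect_lt(max(abs(dz)), 1e-12 * max(rawData(stk)))
})

test_that("a phase-independent background cancels exactly", {
  stk <- fixStackTiny()
  d <- rawData(stk)
  bg <- outer(outer(seq(1, 3, length.out = 64), seq(2, 5, length.out = 64)),
              rep(1, 5))
  d2 <- d
  for (a in 1:3) for (z in 1:5) d2[, , z, , a] <- d2[, , z, , a] + bg
  stk2 <- RawStack(d2, stk@lateralPixelNm, stk@axialStepNm,
                   stk@wavelengthEmNm, stk@na)
  dz1 <- removeZeroOrder(stk, 1)
  dz2 <- removeZeroOrder(stk2, 1)
  expect_lt(max(abs(dz1 - dz2)), 1e-10 * max(bg))
})

test_that("the demix operator is the trigonometric pseudoinverse", {
  W <- buildDemixMatrix()
  steps <- 2 * pi * (0:4) / 5
  # equal steps: orthogonality gives (2/5) * t(design)
  expect_equal(W[1, ], (2 / 5) * cos(steps), tolerance = 1e-12)
  expect_equal(W[2, ], (2 / 5) * sin(steps), tolerance = 1e-12)
  expect_equal(W[3, ], (2 / 5) * cos(2 * steps), tolerance = 1e-12)
  expect_equal(W[4, ], (2 / 5) * sin(2 * steps), tolerance = 1e-12)
  # every harmonic weight vector is orthogonal to the removed DC
  expect_lt(max(abs(rowSums(W))), 1e-12)
})

test_that("perturbed phase steps keep full rank and tiny refit residual", {
  steps <- 2 * pi * (0:4) / 5 + c(0, 0.01, 0, 0, 0)
  W <- buildDemixMatrix(steps)
  A <- cbind(cos(steps), sin(steps), cos(2 * steps), sin(2 * steps))
  expect_lt(max(abs(W %*% A - diag(4))), 1e-12)
  # rank-deficient designs are rejected
  expect_error(buildDemixMatrix(c(0, pi, 2 * pi, 3 * pi, 4 * pi)), "rank")
})

test_that("coefficient fields are orthogonal to the zero order per pixel", {
  il <- fixIllum()
  cf <- coefficientField(il, 1, c(64, 64))
  expect_lt(max(abs(cf[, , 1] + cf[, , 2] + cf[, , 3] + cf[, , 4] + cf[, , 5])),
            1e-12)
})

test_that("recombination of an unmodulated stack is identically zero", {
  ph <- fixPhantom128()
  il0 <- defaultIllumination(a1 = 0, a2 = 0)
  stk <- simulateAcquisition(ph, il0, fixOtf128(), noise = NULL)
  sr0 <- recombineSpatial(stk, fixIllum())
  expect_lt(max(abs(srData(sr0))), 1e-12)
})

test_that("recombination is linear in the raw data", {
  stk <- fixStackTiny()
  il <- fixIllum()
  sr1 <- recombineSpatial(stk, il)
  stk3 <- RawStack(3 * rawData(stk), stk@lateralPixelNm, stk@axialStepNm,
                   stk@wavelengthEmNm, stk@na)
  sr3 <- recombineSpatial(stk3, il)
  expect_equal(srData(sr3), 3 * srData(sr1), tolerance = 1e-12)
})

test_that("recombined spectrum shows first and second order lobes at m*p", {
  vol <- array(0, c(64, 64, 5)); vol[33, 33, 3] <- 1
  ph <- makePhantom("custom", c(64, 64, 5), volume = vol)
  il <- fixIllum()
  stk <- simulateAcquisition(ph, il, fixOtfTiny(), noise = NULL)
  sr0 <- recombineSpatial(stk, il)
  S <- Mod(SpatialSIM:::fftn(srData(sr0)[, , 3]))
  fy <- SpatialSIM:::fftFreq(128) * 2            # cycles per raw pixel
  # energy near every +/-p and +/-2p lobe center exceeds the energy far
  # outside the extended support
  far <- SpatialSIM:::lateralFreqRadius(128, 128) * 2 > 0.95
  floorE <- stats::median(S[far])
  for (a in 1:3) for (m in c(-2, -1, 1, 2)) {
    pk <- m * il@wavevectors[a, ]
    iy <- which.min(abs(fy - pk[1])); ix <- which.min(abs(fy - pk[2]))
    expect_gt(S[iy, ix], 10 * floorE)
  }
})

test_that("single-plane stacks recombine to a one-layer volume", {
  stk <- fixStackTiny()
  d1 <- rawData(stk)[, , 3, , , drop = FALSE]
  stk1 <- RawStack(d1, stk@lateralPixelNm, stk@axialStepNm,
                   stk@wavelengthEmNm, stk@na)
  sr <- recombineSpatial(stk1, fixIllum())
  expect_equal(dim(srData(sr)), c(128L, 128L, 1L))
})

test_that("recombination is purely per plane (limited-layer robustness)", {
  stk <- fixStackTiny()
  il <- fixIllum()
  full <- recombineSpatial(stk, il)
  sub <- RawStack(rawData(stk)[, , 2:3, , , drop = FALSE],
                  stk@lateralPixelNm, stk@axialStepNm,
                  stk@wavelengthEmNm, stk@na)
  two <- recombineSpatial(sub, il)
  expect_equal(srData(two), srData(full)[, , 2:3], tolerance = 1e-12)
})

test_that("missing parameters are rejected", {
  expect_error(recombineSpatial(fixStackTiny(), list(a1 = 1)),
               "IlluminationParams")
})
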