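# Shared fixtures, built once per test run and cached. All synthetic;
# nothing is read from disk.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# default optics used across tests
fixOptics <- list(na = 1.4, lambda = 525, px = 62.5, dz = 125)

fixIllum <- function() fixture("illum", function() defaultIllumination())

fixOtf128 <- function() fixture("otf128", function()
  makeOTF3D(fixOptics$na, fixOptics$lambda, fixOptics$px, fixOptics$dz,
            c(128L, 128L, 9L)))

fixPhantom128 <- function() fixture("phantom128", function()
  makePhantom("point", c(128L, 128L, 9L), spacingNm = 150, pitchVox = 32))

# noise-free acquisition with known ground-truth parameters
fixStackClean128 <- function() fixture("stackClean128", function()
  simulateAcquisition(fixPhantom128(), fixIllum(), fixOtf128(),
                      noise = NULL))

# noisy acquisition at the default photon budget
fixStackNoisy128 <- function() fixture("stackNoisy128", function()
  simulateAcquisition(fixPhantom128(), fixIllum(), fixOtf128(),
                      noise = list(photonBudget = 500, readSigma = 2),
                      rngSeed = 3L))

# tiny stack for fast structural tests
fixStackTiny <- function() fixture("stackTiny", function() {
  ph <- makePhantom("point", c(64L, 64L, 5L), spacingNm = 150, pitchVox = 16)
  otf <- makeOTF3D(fixOptics$na, fixOptics$lambda, fixOptics$px,
                   fixOptics$dz, c(64L, 64L, 5L))
  simulateAcquisition(ph, fixIllum(), otf, noise = NULL)
})

fixOtfTiny <- function() fixture("otfTiny", function()
  makeOTF3D(fixOptics$na, fixOptics$lambda, fixOptics$px, fixOptics$dz,
            c(64L, 64L, 5L)))

# fine-grid OTF matching the 64-grid stacks (2x lateral)
fixOtfFineTiny <- function() fixture("otfFineTiny", function()
  makeOTF3D(fixOptics$na, fixOptics$lambda, fixOptics$px / 2, fixOptics$dz,
            c(128L, 128L, 5L)))

relL2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

wrapPi <- function(x) ((x + pi) %% (2 * pi)) - pi
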