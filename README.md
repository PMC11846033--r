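# SpatialSIM

Spatial-domain reconstruction of three-dimensional structured
illumination microscopy (3D-SIM) with HiLo optical sectioning.

## What this solves, and for whom

A 3D-SIM acquisition records, per z plane, 15 raw images — 3 pattern
orientations × 5 phase steps — that encode the sample spectrum in five
harmonic bands per orientation (m = 0, ±1, ±2 at lateral offsets 0,
±p, ±2p). Classical reconstruction separates the bands in the
frequency domain, shifts them to their true positions, and merges them
with a generalized Wiener filter

    SR(k) = Σ_b conj(H_b(k)) S_b(k) / (Σ_b |H_b(k)|² + w),

which is slow and memory-hungry in 3D, needs ≥6 z planes, and is
vulnerable to the defocused background carried by the zero-order band.

SpatialSIM is for microscopists and image-analysis developers who need
the same doubled lateral resolution from the identical raw data, but
reconstructed in the spatial domain:

1. **Zero-order removal** — per orientation, subtract the per-pixel
   mean over the 5 phases: `D̃_θ,i = D_θ,i − (1/5) Σ_i D_θ,i`. The
   unmodulated widefield content *and* the defocused background vanish.
2. **Per-pixel recombination** — `SR0₋(r) = Σ_θ Σ_i c_θ,i(r) D̃_θ,i(r)`
   with analytic carrier coefficients built from
   cos/sin(Ω), cos/sin(2Ω), Ω = 2π p_θ·(r − r_c) + φ_θ, on a 2×
   upsampled grid. Multiplying by a carrier in real space is a
   frequency shift, so the ±1st and ±2nd bands land at their true
   frequencies without any explicit band separation. The package
   verifies this against its own classical frequency-domain engine:
   the two spectra agree to machine precision.
3. **Frequency optimization** — notch filters at residual illumination
   peaks, a two-step noise-suppression filter, triangular apodization.
4. **HiLo optical section** —
   `OS = (1/3) Σ_θ { Lo[D_θ,1] + Hi[(1/5) Σ_i D_θ,i] }` with an exact
   complementary Gaussian pair, restoring the in-focus low frequencies
   the zero-order removal discarded.
5. **Fusion** — `SR2 = SR1 + w·OS`, clamped at zero after the sum.

Because every spatial step is per-plane, stacks with only 2–3 z layers
reconstruct cleanly. The package also provides the classical
frequency-domain engine (as correctness oracle and comparator), a
synthetic 3D-SIM acquisition simulator with ground truth,
cross-correlation estimation of the illumination parameters, and the
evaluation metrics SBR, SNR, and image-decorrelation resolution.

## Worked example

```r
library(SpatialSIM)

phantom <- makePhantom("point", c(256, 256, 9), spacingNm = 150)
otf     <- makeOTF3D(na = 1.4, wavelengthEmNm = 525, lateralPixelNm = 62.5,
                     axialStepNm = 125, gridShape = c(256, 256, 9))
illum   <- defaultIllumination()
stack   <- simulateAcquisition(phantom, illum, otf,
                               noise = list(photonBudget = 500, readSigma = 2),
                               rngSeed = 1)

params  <- estimateIllumination(stack)
params
#> IlluminationParams (3 angles x 5 phases)
#>   angle 1: p = (0.00000, 0.26660) cyc/px (|p| = 0.26660), phi0 = 0.3135 rad, a1 = 0.886, a2 = 0.394, I0 = 1
#>   angle 2: p = (0.23082, 0.13327) cyc/px (|p| = 0.26653), phi0 = 1.0681 rad, a1 = 0.881, a2 = 0.299, I0 = 1
#>   angle 3: p = (0.23081, -0.13341) cyc/px (|p| = 0.26660), phi0 = 2.1861 rad, a1 = 0.892, a2 = 0.325, I0 = 1
#>   phase steps: 0.0000, 1.2566, 2.5133, 3.7699, 5.0265 rad

result  <- runPipeline(stack, params = params)
result$sr2
#> SRVolume [SR2]: 512 x 512 x 9, pixel 31.25 nm lateral, 125 nm axial
#>   intensity range [0, 625.7]

wf <- widefield(stack)
decorrelationResolution(wf[, , 5], 62.5)                  # 231.5 nm
decorrelationResolution(srData(result$sr2)[, , 5], 31.25) # 156.2 nm
```

The generating pattern here was |p| = 0.26667 cycles/pixel with
starting phases (0.3, 1.1, 2.2) rad and depths a₁ = 0.9, a₂ = 0.45:
wavevectors are recovered to ~1e-4 cycles/pixel and phases to ~0.02 rad
from a photon-budget-500 acquisition. The decorrelation figures show
the lateral resolution gain, 231.5 nm → 156.2 nm on this simulated bead
field (the metric reads a spectral knee of the fused image; the
underlying band support extends to ~104 nm — see the vignette's
discussion of the metric).

A thin command-line wrapper with `simulate` / `estimate` /
`reconstruct` / `evaluate` subcommands is installed at
`inst/scripts/spatialsim-cli.R`:

```sh
Rscript inst/scripts/spatialsim-cli.R simulate --out raw.tif --size 256 --layers 9 --seed 1
Rscript inst/scripts/spatialsim-cli.R estimate --raw raw.tif --params params.txt
Rscript inst/scripts/spatialsim-cli.R reconstruct --raw raw.tif --params params.txt --out run1
Rscript inst/scripts/spatialsim-cli.R evaluate --image run1/SR2.tif
```

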