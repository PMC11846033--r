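---
title: "Spatial-domain 3D-SIM reconstruction with optical sectioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-domain 3D-SIM reconstruction with optical sectioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Three-dimensional structured illumination microscopy (3D-SIM) acquires,
for every z plane, fifteen images: three orientations of a sinusoidal
excitation pattern, each stepped through five phases. The sample
spectrum is thereby encoded in five harmonic bands per orientation
(m = 0, ±1, ±2, at lateral offsets 0, ±p, ±2p), and a reconstruction
that separates the bands and returns them to their true frequencies
doubles the lateral resolution. The classical route does this
explicitly in the frequency domain — phase-separation matrix, band
shifting, generalized Wiener combination — which is memory- and
time-intensive in 3D, degrades when fewer than about six z planes are
available, and is sensitive to the defocused background that thick
samples put into the zero-order band.

This package implements the spatial-domain alternative. For each
orientation the per-pixel mean over the five phases — the unmodulated
zero order, which carries the widefield content *and* the defocused
background — is subtracted. The five zero-mean phase images are then
summed per pixel with analytic carrier coefficients

$$\mathrm{SR}_{0,-}(r,z)=\sum_{\theta=1}^{3}\sum_{i=1}^{5}
  c_{\theta,i}(r,z)\,D_{\theta,i}(r,z),$$

where the coefficients are built from the demixing weights of the
trigonometric design matrix
$[\cos\phi_i,\ \sin\phi_i,\ \cos 2\phi_i,\ \sin 2\phi_i]$ and the
carriers $\cos/\sin(\Omega)$, $\cos/\sin(2\Omega)$ with
$\Omega = 2\pi\,p_\theta\!\cdot\!(r - r_c) + \phi_\theta$ evaluated on
the output grid. Multiplication by a carrier in real space *is* a
frequency shift, so this plants every band at its true position without
ever separating or shifting spectra; the package proves the point by
comparing against an explicit frequency-domain reconstruction
(`reconstructReference(combine = "plain")`), which agrees with
`recombineSpatial()` to machine precision (the acceptance suite demands
relative L2 below 1e-6; the observed agreement is ~1e-15).

Because the recombination is purely per-plane, stacks of two or three z
planes reconstruct exactly as the corresponding planes of a deep stack
do — the limited-layer regime that frequency-domain pipelines with 3D
Wiener filters handle poorly.

The recombined volume is then optimized in the frequency domain
(`optimizeVolume()`): Gaussian notches at the residual illumination
peaks ±p, ±2p; a two-step noise-suppression filter (a Wiener-style gain
against the coverage-summed transfer, then out-of-band suppression with
a mild rolloff); and a triangular apodization. An identity
configuration (`identityFilterBank()`) reproduces the input exactly and
is tested.

Zero-order removal discards in-focus low-frequency content along with
the background. A HiLo optical section restores it
(`opticalSection()`): per orientation, the Gaussian low-pass of the
first-phase structured image plus the complementary high-pass of the
five-phase average, averaged over the three orientations to cancel
per-orientation intensity differences. The fusion
(`fuseVolumes()`) forms `SR2 = SR1 + w * OS`, clamped at zero after the
sum.

## Parameter estimation

Reconstruction needs, per orientation, the pattern wavevector $p$, the
starting phase $\phi$, and the modulation depths $a_1, a_2$
(`estimateIllumination()`, run once per dataset and cached as prior
knowledge). The estimator:

1. separates the m = 0 and m = +1 bands with the 5×5 phase matrix;
2. forms the per-pixel product $\overline{C_0}\,C_1$ after per-plane
   spectral whitening (phase correlation), zero-pads its spectrum 2×,
   and takes the sharpest peak relative to a locally smoothed
   background — sparse or partially periodic samples produce smooth
   correlation halos that would otherwise swamp the carrier peak;
3. refines to sub-bin precision with the phase-gradient of the
   band-limited correlation, then maximizes the continuous-frequency
   correlation magnitude (Nelder–Mead, deterministic);
4. fits a magnitude-weighted plane to the phase of the demodulated
   m = +1 band: the intercept at the grid center is $\phi$, and the
   fitted slope corrects the wavevector once more (typical noise-free
   accuracy ~1e-4 cycles/pixel, phase ~0.01 rad);
5. estimates $a_1, a_2$ by a least-squares complex cross-ratio of the
   demodulated bands against the zero order over the OTF-supported
   overlap region, dividing out the transfer ratio $H(k+mp)/H(k)$
   interpolated from the scalar OTF model built from the stack's own
   optics metadata.

Two conventions matter and are deliberate:

* **Carrier phases are referenced at the grid center,** not the array
  origin. With an origin reference, a wavevector error of 1e-4
  cycles/pixel masquerades as a ~0.1 rad phase error on a 512-pixel
  field — the phase criterion would measure the wavevector criterion
  twice. Center referencing (standard in SIM implementations) decouples
  the two.
* **Estimation pools a central window of at most nine z planes** and
  restricts the phase plane-fit to the brightest ~2×10⁵ pixels. The
  pattern is constant over depth, so this loses no information while
  bounding time and memory on large stacks.

## The synthetic acquisition generator

`simulateAcquisition()` produces acquisitions with known ground truth:
excitation $I_0[1 + a_1\cos(\Omega+\phi_i) + a_2\cos(2\Omega+2\phi_i)]$
times the fluorophore density, blurred by a scalar-diffraction 3D PSF
(pupil propagation with defocus phase; uniform circular pupil of radius
NA/λ; immersion index 1.518), plus an optional defocused background
(the density blurred by a heavily widened kernel), then Poisson shot
noise at a peak photon budget, Gaussian read noise, and quantization to
integer camera counts. Defaults: NA 1.4, λ_em 525 nm, 62.5 nm lateral
pixels, 125 nm z steps, pattern at 0.8× the widefield cutoff,
a₁ = 0.9, a₂ = 0.45, photon budget 500, read noise 2.

Phantoms (`makePhantom()`) place pairs of points, lines, or a ring at
exactly recorded sub-diffraction separations. Point markers are
Gaussian with σ = 41 nm (≈96 nm FWHM, the scale of common 100-nm
calibration beads), at uniformly random, minimum-distance-rejected
positions. Both choices are deliberate calibration, not incidental:

* *Random placement.* A periodic lattice of emitters has coherent
  lattice harmonics that corrupt correlation-based parameter
  estimation; real specimens are aperiodic.
* *Finite marker size.* Single-voxel deltas have a perfectly flat
  spectrum, so every decorrelation-based resolution measurement lands
  exactly on a support edge rather than at a noise crossover. The
  41 nm default was calibrated once against the widefield resolution
  of the default point study (512×512×41, focal plane, ≈231 nm,
  stable across acquisition seeds) and then frozen.

What the generator does *not* emulate: vectorial/polarization effects,
optical aberrations, sCMOS fixed-pattern noise, true three-beam axial
modulation of the excitation (the pattern is laterally sinusoidal with
two harmonics; axial transfer shaping is left to the OTF), and
sample-induced scattering. Passing tests therefore demonstrate
correctness of the algorithmic chain under an idealized but
statistically honest acquisition model — not robustness to instrument
non-idealities.

## Numerical choices

* All FFTs are unnormalized forward / 1/N inverse; frequency-domain
  arrays are DC-centered only where documented (the OTF model and the
  public filter operations); the pipeline's internal fused filter path
  works in natural layout to avoid shifting multi-gigabyte arrays.
* 2× lateral upsampling is exact trigonometric interpolation (spectrum
  zero-padding with the Nyquist bin split), so upsampled real images
  are exactly real and preserve the original samples.
* Large-volume transforms are chunked (2D per plane, then blocked
  axial lines); noisy stacks are stored as integer camera counts; the
  full 512×512×41 pipeline peaks at about 5 GB.
* The modulation-depth division uses a floor of 0.05 (Wiener-style gain
  limiting); the Wiener-gain transfer model may be sampled on a ≤512
  lateral grid and is bilinearly interpolated onto larger spectra (the
  gain is smooth in frequency).
* Short stacks are axially padded before the 3D filter FFT
  (edge-mirrored by 8 planes when nz ≥ 8, zero-padded otherwise).
* The classical reference engine transforms only m = 0, +1, +2 and adds
  the conjugate bands by Hermitian reflection; band transfers are
  evaluated at their exact sub-bin shifted frequencies. A sign
  subtlety worth recording: after the demodulating ramp, band m sits
  under the transfer H(k + mp) — pairing it with H(k − mp) silently
  yields a widefield-like reconstruction, which is why the suite checks
  the combiner against an independently written dense implementation.

## Open design points, as resolved here

* *Output grid.* The reconstruction is upsampled 2× laterally (the
  extended support exceeds the raw Nyquist); z is never resampled.
* *HiLo crossover.* The Lo cutoff defaults to |p|/4. The low-pass acts
  on the raw structured image, exactly as the combination rule states;
  no local-contrast demodulation is added. Consequently a smooth
  background passes the Lo branch — the background suppression of the
  method lives in the zero-order removal of the SR branch, and the
  suite asserts the section never amplifies background rather than
  that it suppresses it.
* *Notch placement.* Notches are applied to the recombined spectrum
  (bands are never separated in the fast path), as lateral cylinders
  at ±p, ±2p over all axial frequencies.
* *Fusion weight.* The combination rule is an unweighted sum, but SR1
  and OS come from differently normalized pipelines; the default
  weight rescales OS so its total intensity matches the removed
  zero-order energy, making the ratio independent of FFT conventions.
* *Depth-ratio spectral region.* Modulation depths are fitted over the
  OTF-supported overlap region with the transfer ratio divided out;
  a threshold of 5% of the per-plane transfer maximum defines
  "supported" (the 3D OTF's bin values scale with axial sampling, so
  the threshold is relative, not absolute).

## Known limitations

* The decorrelation resolution metric presumes a reasonably equalized
  reconstruction spectrum; on strongly colored spectra it reads a
  spectral knee, not the information limit. On the simulated point
  study it is effectively bimodal: the fused SR2, whose DC-matched
  optical section dominates the low frequencies, measures at the
  widefield knee (~195 nm), while the Wiener-flattened classical
  reconstruction measures at the extended-support edge (~105-110 nm).
  Intermediate values require a noise regime in which the SIM band's
  SNR crosses unity inside the band, which the default photon budget
  does not produce.
* The classical reference engine is deliberately minimal (single
  Wiener constant, no notch): it exists to verify band placement and
  weights. Under low-noise conditions it resolves to its support edge,
  which can differ from published figures produced by fully filtered
  traditional pipelines.
* Carriers are evaluated from a single global (p, φ) per orientation;
  spatially varying pattern distortion is not modeled or corrected.

## Problem sizes used by the test suite

The acceptance suite reproduces the full 512×512×41 point study once
(several minutes); all other properties are established on 64–256 pixel
grids with 5–22 planes, where every stage runs in seconds. The
Monte-Carlo parameter-recovery check uses ten seeded 256×256×9
acquisitions at photon budget 500.
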