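---
title: "Methods: the two-inversion EPI T1 model, distortion matching, and the digital phantom"
author: "epiT1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-inversion EPI T1 model, distortion matching, and the digital phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiT1)
```

# The signal model

One inversion-recovery (IR) period of duration `trIR` contains, in order:
an instantaneous adiabatic inversion mapping `Mz -> -eff * Mz`
(`eff` = inversion efficiency, default 1); a block of `shotsPerTiBlock`
excitations with flip angle `b1 * fa1` centered on `ti1`; a second block
with `b1 * fa2` centered on `ti2`; and free relaxation to the end of the
period. Between events the Bloch longitudinal equation has the exact
solution `Mz(t + D) = m0 + (Mz(t) - m0) exp(-D / t1)`, so the simulator
is event-driven: exponential segments chained through pulses, no ODE
integration. Each excitation produces transverse signal `Mz sin(a)` and
leaves `Mz cos(a)`; transverse magnetization is assumed fully spoiled
between shots, which is what produces the saw-tooth `Mz` pattern of a
segmented readout. A brute-force forward-Euler integrator (0.01 ms
steps) exists in the test suite purely as an independent oracle; the two
agree to a few times 1e-6 in relative terms on both shipped protocols.

Cycles are chained until two consecutive cycles agree to within `tol`
(default 1e-9 of m0, at most 50 cycles). Iterating is as exact as
solving the linear fixed point and simpler; the steady state is
independent of the starting magnetization, which the suite asserts. In
the constant-flip-angle limit the per-shot magnetization converges to
the Look-Locker fixed point `m0 (1 - E)/(1 - E cos a)`, `E =
exp(-tau/t1)`, with apparent rate `1/T1* = 1/t1 - log(cos a)/tau >
1/t1`: spin history accelerates apparent relaxation, which is why T1
quantification must run through this forward model rather than a
small-flip-angle Look-Locker fit.

Things deliberately *not* modeled, because they do not affect the
quantities this package computes from its own simulations: T2*/MT decay
during the readout (`te` is metadata only), off-resonance precession
within a shot, slice profiles, and parallel-imaging reconstruction.

## Timing conventions

- The inversion time of each block refers to the **center** of the shot
  block, and the k-space-center segment is taken to be the middle shot
  (`floor(n/2) + 1`) under linear segment ordering. A first-shot
  convention would simply shift the effective TI by half a block.
- `shotsPerTiBlock` is an explicit parameter; validation enforces that
  the TI1 block ends before the TI2 block begins and that both blocks
  fit inside the IR period. The defaults — 27 shots for the
  retrospective protocol, 10 for the acquisition-matched one — were
  chosen once so that the computed whole-brain durations (210.6 s and
  202 s over four polarity volumes) land inside the 3:00–3:40 min
  window the protocols are specified to occupy, and are not revisited.
- Effective echo spacing is `echoSpacing / (nSegments * rInplane)`, the
  standard interleaved multi-shot convention: segmentation and in-plane
  acceleration both multiply the k-space line spacing covered per unit
  time, and EPI distortion is proportional to this quantity. The actual
  echo spacing default (1.05 ms) is a representative value for a
  0.8 mm, 232-matrix EPI readout at 7 T.

# CNR and flip-angle optimization

The displayed contrast between gray and white matter is the normalized
difference `C = (sGM - sWM) / (|sGM| + |sWM|)` in [-1, 1]. Image noise
of SD `sigma` propagates to first order through the analytic partials,
`sigmaC = sigma * sqrt((dC/dsGM)^2 + (dC/dsWM)^2)`, and `CNR = C /
sigmaC`. A Monte-Carlo oracle (1e6 draws) guards the algebra in the
tests and in `scripts/acceptance.R`.

One subtlety is intrinsic to this contrast: if the two signed signals
straddle zero, `C` saturates at exactly +/-1, where both partials vanish
and the first-order CNR is infinite. A reconstructed image used for
segmentation carries magnitudes, not polarity, so `cnrForProtocol()` and
`optimizeFlipAngles()` evaluate the contrast on `|s|`; the saturation
behavior of the signed form is documented and tested but excluded from
optimization. `cnrFromSignals()` itself accepts signed inputs.

The optimizer evaluates `|CNR|` on every node of the flip-angle grid
(exhaustive search, no gradient ascent — the surface is cheap and this
avoids basin ambiguity), with deterministic tie-breaking toward the
smallest `fa1`, then `fa2`. Because noise only scales the surface, the
argmax is independent of `sigma`. Whether the published protocol
optimizes the TI1 image, the TI2 image or a combined quantity is not
fixed; all three are available through `whichTi` (default: the TI1
image, which drives segmentation). The combined option propagates noise
through the `s1/s2` quotient and keeps the ratio's sign, since the sign
carries T1 information.

# Lookup-table T1 quantification

`buildLookupTable()` tabulates the signed steady-state ratio `s1/s2`
over a T1 grid (default 500–4500 ms in 10 ms steps) and records the
largest contiguous strictly monotonic sub-range; `lutInvert()`
interpolates the inverse map linearly and returns NA outside the
tabulated ratio range rather than clamping, so failures stay visible.
The signed ratio is the quantified quantity — the pipeline averages
complex data, so the TI1 image retains polarity; a magnitude-mode
pipeline would fold the ratio axis and halve the invertible range.

Transmit-field inhomogeneity scales the realized flip angles and hence
the spin history, so tables are B1-specific. `mapT1()` builds one table
per B1 bin (default 20 bins spanning the supplied map's range) and
inverts each voxel with its nearest bin — a first-order correction
mirroring the use of a coarse template B1 map. On the phantom, assuming
uniform B1 biases GM T1 by ~4% (median); supplying the map that
generated the data reduces the median bias below 1%, bounded by the bin
quantization. Voxels with `|s2|` under `s2Floor` (default 1e-6 m0
units) are NA.

# Polarity combination

The N/2 ghost has opposite phase for the two read-gradient polarities;
the "fuzzy-ripple" artifact likewise flips sign. Averaging the real and
imaginary parts of the two read-polarity volumes therefore cancels both
exactly while retaining signal and halving complex noise variance;
magnitudes are formed afterwards as `sqrt(Re^2 + Im^2)`. Averaging is
unweighted. Inputs are assumed motion-corrected (registration is
out-of-scope glue); a center-of-mass guard warns above 0.5 voxel —
additive polarity-flipping artifacts legitimately move the
intensity-weighted COM by a few tenths of a voxel on the low-signal TI1
images, so a tighter guard would false-alarm on artifact-bearing but
perfectly aligned inputs.

Read-polarity pairs are averaged first; the opposite *phase*-polarity
volumes are deliberately not averaged (their distortions differ) and
instead feed the distortion module. This ordering is a documented
pipeline choice.

# Distortion estimation, scaling, synthesis

Opposite phase-encode polarities displace signal by equal and opposite
amounts `d = B0[Hz] * espEff[s] * nPE` along the PE axis. The stored
field is the *correction* field of the +PE image: resampling the +PE
image at `x + d` (and the -PE image at `x - d`) recovers the midpoint
(true) geometry. Re-distorting a corrected image applies the negated
scaled field; scaling by `target/estimated` synthesizes any distortion
level, with 0 giving the distortion-free reference.

The estimator is a multiresolution (4x, 2x, 1x block-mean pyramid)
Gauss-Newton scheme on the voxelwise 1-D displacement: the residual
between the pair corrected by the current field drives a
demons-normalized update `-r g / (g^2 + r^2)` (bounded by half a voxel
per iteration), smoothed by a Gaussian kernel of width `knotSpacing`
voxels; a line search accepts a step only if both the SSD and the
SSD-plus-bending-energy objective decrease, so the data term is
monotone. This replaces an explicit tensor-B-spline parameterization
with the equivalent smoothness control expressed as update filtering —
far better suited to vectorized array arithmetic — and is a functional
stand-in for external reverse-PE tools, not a re-implementation of any
of them. The default kernel width of 5 voxels was fixed after phantom
validation: narrower kernels leave the field unconstrained (near zero)
inside flat tissue interiors where the image carries no PE gradient,
and 5 voxels roughly halves the brain-mask RMSE relative to 4. The
bending-energy weight (0.1) is a declared default. Resampling is linear
and edge-padded, with Jacobian intensity modulation `1 + dd/dx`
(clipped at 0) on by default; mass is conserved to <0.5% under the
phantom's fields.

On 64-cube phantoms with 10–46 Hz off-resonance blobs the field is
recovered to ~0.15 voxels RMSE (median over ten phantoms), synthesis at
the source echo spacing reproduces the acquired +PE volume to ~1.2% of
the intensity range, and synthesis at twice the spacing matches a fresh
simulation at that spacing to ~2.2%.

# Depth profiles

`extractProfile()` pools any scalar map over equal-width cortical-depth
bins of a precomputed depth map (layering itself — surfaces, equivolume
corrections — is out of scope; the phantom supplies depth directly).
`detectDip()` returns the most prominent interior local minimum above a
prominence threshold, excluding the two boundary bins as partial-volume
edges. A Gaussian 100 ms T1 depression injected at mid-depth (the
stand-in for the heavily myelinated band used to calibrate geometric to
myeloarchitectonic layers) is localized within one bin width of a
21-bin profile.

# The digital phantom

`makePhantom()` builds nested ellipsoids — WM core, a >=3-voxel GM
ribbon with a normalized [0, 1] depth map, a CSF shell — with a smooth
polynomial B0 field plus one localized Gaussian blob (default 30 Hz,
emulating air-cavity inhomogeneity; position jittered by the seed), and
a radial B1 profile spanning [0.7, 1.3]. Tissue values (T1 1200/1900/
4000 ms and M0 0.70/0.85/1.00 for WM/GM/CSF) are representative 7 T
values; the spec-level GM/WM pair is the package default for CNR work.
`simulateAcquisition()` applies, in order: the steady-state signal at
each voxel's tissue and local B1 (interpolated over a fine B1 grid);
PE displacement with Jacobian modulation; a pure-imaginary N/2 ghost
whose sign tracks read polarity (5% default — the minimal model that
complex averaging cancels exactly); an additive low-frequency sinusoidal
ripple, also read-polarity-flipping (3% of the WM signal); and seeded
complex Gaussian noise. Ghost and ripple amplitudes are arbitrary
fixtures — no quantitative artifact levels exist to reproduce.

What the phantom does *not* emulate: realistic anatomy and
susceptibility physics (fields are smooth and low-order), T2* blur,
motion, coil sensitivities and parallel-imaging noise amplification.
Passing tests therefore demonstrate correctness of the algorithms under
their stated models — signal equations, cancellation algebra, field
scaling arithmetic, parameter recovery — not robustness to every
real-scanner effect.

# Noise conventions and problem sizes

"SNR 50" in the recovery experiments means each signal volume receives
additive Gaussian noise with SD equal to its own brain-mean magnitude
divided by 50. Tests run phantoms at 32 cubed; the acceptance checks
and `scripts/acceptance.R` use 64-cube phantoms (ten of them for field
recovery), 1e6 Monte-Carlo draws, a 30x30 flip-angle grid, and the full
64-cube workflow — sizes chosen so the whole suite completes in a few
minutes on one CPU while every estimate's sampling error is far from
its acceptance margin.

# Known limitations

- The steady-state model assumes perfect spoiling and an instantaneous
  inversion; incomplete inversion is representable (`inversionEfficiency`)
  but no value is fitted.
- B1 correction is nearest-bin; a voxel exactly between bins carries up
  to half a bin of flip-angle error (<1% T1 at 20 bins over [0.7, 1.3]).
- The field estimator recovers what the data constrain: displacement in
  large flat regions is interpolated by the smoothing kernel, not
  measured. Sub-voxel accuracy degrades gracefully, not catastrophically,
  as blob amplitude grows.
- Scan-duration accounting reproduces printed totals only to the extent
  the loop structure is specified; the kz/segment interleaving order is
  schematic, so durations are plausibility quantities, not exact claims.
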