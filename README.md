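# epiT1

Quantitative T1 mapping and distortion matching for two-inversion
segmented 3D-EPI structural acquisitions.

## The problem

High-resolution (layer) fMRI at 7 T pools functional signals across
cortical depths, which requires registering EPI functional data to a
structural reference. Conventional anatomical references (e.g. MP2RAGE)
are distortion-free, while EPI is geometrically distorted along its
phase-encode axis by B0 inhomogeneity — so tissue borders derived from
the anatomy land in the wrong voxels of the functional data. A structural
scan that is *itself* an EPI acquisition can either match the functional
distortion exactly or have its distortion estimated and rescaled to any
desired level, making registration trivial.

`epiT1` implements the computational core of such an approach: a
T1-weighted two-inversion Look-Locker segmented 3D-EPI acquisition,
acquired in all four combinations of read and phase-encode gradient
polarity, with

- a forward Bloch model of the steady-state inversion-recovery cycle
  with segment-specific excitation flip angles,
- gray/white-matter contrast-to-noise (CNR) optimization over the
  flip-angle pair by exhaustive grid search,
- lookup-table T1 quantification from the TI1/TI2 signal ratio, with
  B1-binned table families correcting transmit-field inhomogeneity,
- complex averaging across read polarities, which cancels EPI artifacts
  whose sign flips with the read gradient (N/2 ghost, "fuzzy ripples"),
- reverse-phase-encode displacement-field estimation (TOPUP-style) with
  echo-spacing rescaling, so the corrected data can be re-synthesized at
  any distortion level — including zero,
- cortical-depth profile extraction with landmark dip detection, and
- a digital brain phantom and acquisition simulator that exercises the
  full pipeline with known ground truth.

## The model

One inversion-recovery cycle of duration `TR_IR` starts with an adiabatic
inversion (`Mz -> -eff * Mz`), followed by two blocks of
`shotsPerTiBlock` excitations centered on the inversion times `TI1` and
`TI2`, with flip angles `a1 = B1 * FA1` and `a2 = B1 * FA2` and shot
spacing `TR_shot`. Between events the magnetization relaxes in closed
form, `Mz(t + D) = M0 + (Mz(t) - M0) exp(-D / T1)`; each excitation reads
`Mxy = Mz sin(a)` and leaves `Mz cos(a)` (perfect spoiling). Cycles are
chained to steady state; the signals `s1`, `s2` of the k-space-center
shots of the two blocks give the signed ratio `s1/s2`, a monotonic
function of T1 that a per-B1-bin lookup table inverts to milliseconds.

EPI distortion is modeled as a voxel displacement along the phase-encode
axis, `d = B0[Hz] * esp_eff[s] * n_pe`, with sign following the
phase-encode polarity and `esp_eff = echoSpacing / (nSegments * R)` the
effective echo spacing. A field estimated from a reverse-PE pair at one
`esp_eff` scales linearly to any other — multiply by
`target / estimated` (0 gives distortion-free synthesis).

## Worked example

```r
library(epiT1)

p <- retrospectiveProtocol()
p
#> ProtocolParams 'retrospective'
#>   TI1/TI2/TE/TRshot/TRIR = 930/2368/8/23/3097 ms, FA = 10/10 deg
#>   segments 14, R 1, kz-CAIPI 3, partial Fourier 0.75
#>   matrix 232x232x186, voxel 0.8x0.8x0.8 mm, echo spacing 1.05 ms (effective 0.075 ms)
#>   27 shots per TI block, inversion efficiency 1

scanDuration(p)          # whole-brain, all four polarity volumes
#> [1] 210.596              (seconds, i.e. ~3:30 min)

steadyStateSignals(p, tissueParams("GM", 1900, 0.85))
#> SignalPair: s1 = 0.00742, s2 = 0.06765 (m0 units), ratio = 0.10974

lut <- buildLookupTable(p, seq(600, 3000, by = 10))
lut
#> LookupTable (retrospective, B1 = 1): 241 T1 nodes in [600, 3000] ms
#>   ratio in [-0.0488, 0.6553], monotonic domain [600, 3000] ms

sp <- steadyStateSignals(p, tissueParams("unknown", 1500))
lutInvert(lut, s1(sp) / s2(sp))
#> [1] 1500                  (ms; round trip through the table)
```

The ratio is strictly monotonic in T1 over the whole tabulated range, so
inversion is well posed; `s1` is small because TI1 sits near the tissue
nulls, which is what makes the TI1 image strongly T1-weighted.

The full phantom pipeline (simulate a four-polarity session, average
read polarities, estimate and rescale the displacement field, map T1,
extract a depth profile):

```r
res <- runRetrospectiveWorkflow(runConfig(seed = 1, outputDir = "out"))
str(res$report[c("field_rmse_vox", "t1_median_abs_err_pct")])
#> $ field_rmse_vox       : num 0.145
#> $ t1_median_abs_err_pct:List of 2
#>  ..$ gm: num 0.666
#>  ..$ wm: num 0.455
```

Median T1 error under 1% in both compartments and a displacement field
recovered to ~0.15 voxels RMSE against the simulator's ground truth.

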