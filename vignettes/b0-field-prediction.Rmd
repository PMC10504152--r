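---
title: "Predicting motion-induced B0 field changes in head MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting motion-induced B0 field changes in head MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Static-field (B0) inhomogeneity in head MRI is dominated by the susceptibility
contrast between air, bone and soft tissue. Because the induced field depends
on the orientation of those interfaces relative to the scanner's z axis, every
head movement changes the field map, and a field map measured once at a
reference position loses validity as the subject moves. Re-measuring at every
position costs minutes each time. `b0predict` implements a forward-simulation
alternative: build a subject-specific susceptibility model once, decompose the
reference measurement into physically meaningful components, and then
*predict* the field map at any new rigid head position — including the option
to correct the model with a cheap body mask when large motion deforms the
soft tissue of the neck.

## The field model

The simulated off-resonance map is a sum of five components, each in Hz:

* `B_SH` — the scanner's static shim field, evaluated from 9 coefficients
  over the real solid-harmonic basis
  `{1, x, y, z, 2z² − x² − y², zx, zy, x² − y², xy}` in scanner mm
  coordinates (order 0 in Hz, order 1 in Hz/mm, order 2 in Hz/mm²). No vendor
  normalisation is assumed; the basis order is part of the package contract
  so external coefficients can be converted.
* `B_chi` — the tissue-induced field, computed from a susceptibility map
  chi(r) (ppm) by the Lorentz-corrected Fourier dipole approximation:
  `B(r) = f0·1e-6 · IFFT{ (1/3 − kz²/k²) · FFT(chi) }`. The kernel value at
  k = 0 is set to 0, making the field mean-free over the computational
  volume; any constant belongs to `B0_shift` downstream. The map is
  zero-padded by a factor of 3 per axis (centred) before the transform so
  that the periodic images of the source do not fold field back into the
  FOV, and cropped afterwards.
* `B_k` — a linear "phase-error" field along the first phase-encode (y)
  axis. It is estimated from the data as a k-space centre shift
  `dk_n = −a·t_n` per echo: a shift of `dk` cycles across `N_y` samples at
  echo time `t` is the field gradient `dk/(N_y·dy·t)` Hz/mm. The estimator
  is the magnitude-weighted lag-1 autocorrelation phase along y of the
  demodulated complex echoes (wrap-around pair excluded — it would carry the
  whole phase span across the FOV and bias sub-integer shifts), which via
  Parseval equals the intensity-weighted centroid of the central k-space
  line and is exact for a pure ramp, with no sub-bin interpolation bias. The
  fit intercept is fixed at zero (`dk_0 = t_0 = 0`).
* `B_chi'` — the field of susceptibility sources outside the imaging volume
  (chiefly the lungs), approximated by a single axial point dipole
  `P/|r−rd|³ (3cos²θ − 1)` with `P` in Hz·mm³. `P` and the offset are linear
  in the model, so they are profiled out by least squares and only the
  3-D position is searched: a coarse 5×5×5 grid around a start 100 mm
  inferior to the FOV centre, then Nelder-Mead simplex refinement with one
  restart.
* `B0_shift` — a global frequency offset aligning simulated and measured
  maps.

The *simple-model residual* (SMR) is what the literature 3-class model cannot
explain; the *multi-model residual* (MMR) is the analogous residual of the
fitted multi-segment model. By construction `measured = components + residual`
exactly, so the combined prediction below is lossless at the reference
position.

## Segmentation and the multi-segment susceptibility fit

Tissue classes come from a proton-density UTE-like image. In
`x = −log(I/I_max)` units, soft tissue forms a low peak and air/noise a high
peak; both are located on a smoothed 256-bin histogram (two highest local
maxima at least 10 bins apart, the second at least 5% of the first — below
that the histogram is declared unimodal) and each is fitted by least squares
with a Gaussian over a window of half the inter-peak distance, capped at
2.5x the peak's own half-width at half maximum and initialised from it — the
bone signal forms a shoulder between the peaks, and an uncapped window lets
it pull the soft-tissue Gaussian off its peak on small, noisy histograms. The 3-class rule labels soft tissue below
`center_soft + 1.4·FWHM_soft`, air above `center_noise − 1.4·FWHM_noise`, and
bone between; literature susceptibilities are air 0 ppm (reference), soft
tissue −9.6 ppm, bone −11.4 ppm. Intensities are floored at the 0.01
percentile of nonzero voxels before the log.

The multiple-segment model bins voxels outside the brain mask by `x` over
`[center_soft − 1.4·FWHM_soft, center_noise]` with width 0.1 (below-interval
voxels are soft tissue, above-interval air, brain-mask voxels are fixed at
the soft-tissue value). Each (bin, VOI) pair — VOIs are disjoint regions that
allow the same intensity bin different susceptibilities in different
anatomical neighbourhoods — receives its own chi, fitted to minimise the RMSE
between `B_diff_m = measured − B_SH − B_chi' − B_k` and the model field over
the brain, within bounds [−14, 1] ppm, starting from a linear interval
[−12, 0] ppm matched to the bins (more air-like bins start closer to 0).
Because the forward model is linear in the per-pair values, the fit is
bounded *linear* least squares over precomputed unit-response fields; we
solve the unconstrained problem by pivoted QR (exact for noiseless
identifiable data) and polish with projected quasi-Newton steps only when a
bound becomes active. This honours the iterative-optimiser contract while
being deterministic and fast. Pairs smaller than 5 voxels are merged into the
nearest bin of the same VOI; unmergeable remnants are frozen at their
initialisation value. Voxels outside every VOI fall back to the 3-class
literature assignment — in a phantom FOV the surrounding air dwarfs the head,
whereas in vivo VOIs cover everything of interest.

Design note on the unit-response basis: building one FFT per pair is
wasteful. The forward map is a circular convolution on the padded lattice,
so the basis columns are assembled from a single impulse response by gathered
summation; for sources and field points inside the FOV the offset never
wraps, making this bit-for-bit identical to the per-pair FFT.

## Motion strategies

Given 6-DOF motion parameters (intrinsic rotations `R = Rx·Ry·Rz` about the
scanner axes through the volume centre, then translation — the convention is
fixed so external registration outputs can be converted):

* **Transformed FM** — subtract `B_SH` (it does not move with the head),
  rigidly resample the measured reference map (trilinear), add `B_SH` back.
* **Simulated FM** — rigidly transport the susceptibility model
  (nearest-neighbour, so no intermediate susceptibilities are invented at
  interfaces; out-of-support voxels become air), rerun the forward
  calculation, and keep `B_SH`, `B_k`, `B_chi'` and `B0_shift` unchanged in
  the scanner frame.
* **Combined FM** — the simulated FM plus the rigidly transported MMR. At
  the identity transform this returns the measured reference map exactly.

Large nodding rotations deform the soft tissue of the neck, which rigid
transport cannot represent. When a body mask measured at the new position is
available (threshold at 10% of the robust magnitude maximum, largest
6-connected component, morphological closing of radius 2 voxels), the
transported model is corrected: voxels outside the new mask become air,
air voxels inside it (outside the brain) become soft tissue. Predictions are
scored by RMSE against the measured map over the brain mask and by the
volume standard deviation (Vol.σB0).

## Multi-coil shimming

Shim currents for a 16-channel coil array minimise the sum of squared
residual field over the (optionally 2 mm block-mean downsampled) brain mask,
subject to 4 A per coil and 50 A total (sum of magnitudes). The global
frequency offset is not a shim channel and the homogeneity metric ignores
it, so the constant component is projected out of both target and basis
columns. The QP is solved by exact cyclic coordinate descent under the box
constraints with the total-current constraint handled through bisection on
its Lagrange multiplier, short-circuited by the unconstrained QR solution
whenever that is feasible and finished with an exact active-set polish; a
projected-gradient KKT residual is reported. The cross-evaluation protocol —
currents solved on a *predicted* map, scored on the *measured* map —
replicates shimming at a new head position without a new measurement.

## The digital head phantom

No public dataset accompanies the method, so the package ships a seeded
generator that emulates every input: an ellipsoidal head (scalp, 4 mm skull
shell, brain compartment) on a neck cylinder with a bone "spine", two air
cavities standing in for the frontal sinus and the deeper nasal/sphenoid
air spaces, UTE intensities drawn per class in −log units (soft 0.5 ± 0.18,
bone 1.8 ± 0.15, air 4.0 ± 0.45 — giving the bimodal histogram the
segmentation needs), dual-echo GRE signal at TE = 2.68/7.49 ms whose phase
encodes the full component sum, an out-of-FOV dipole (P = 6·10⁷ Hz·mm³ at
(5, −10, −220) mm), a phase-error ramp (a = 50 k-index/s), second-order SH
shim coefficients, a 3 Hz global offset, and circular Gaussian complex noise
(SD 0.02 on unit soft-tissue magnitude, i.e. roughly 0.9 Hz of field-map
noise: sqrt(2)·0.02 rad of phase-difference noise over 2π·4.81 ms). The Larmor frequency default is 123.2 MHz (3 T); the paper-style
acquisition never prints one, so it is configurable.

Two phantom behaviours deserve explanation:

* **Auto-shim.** The head-plus-neck tissue column would put the unshimmed
  brain field several hundred Hz off resonance, which no scanned subject
  ever sees: scanners shim before measuring. `generate_phantom()` therefore
  fits the 9-term SH basis against the tissue and dipole fields over the
  brain once, at the reference position, and holds those effective
  coefficients fixed for every subsequent position — exactly the
  experimental protocol in which the shim is set once and the subject then
  moves.
* **Phase aliasing.** With echo spacing 4.81 ms the dual-echo field map
  aliases at ±103.9 Hz. The literature air/tissue contrast produces several
  hundred Hz immediately at cavity poles, for any phantom — so the phantom
  exports a wrap mask, and the zero-noise consistency guarantee (measured
  field map = component sum) holds at magnitude-valid, non-aliased voxels.
  The brain mask is built with ≥10 mm clearance from cavity surfaces and is
  alias-free by construction, which is what all brain-mask metrics rely on.

Rigid motion is applied by nearest-neighbour transport of labels,
susceptibility and UTE intensities (newly exposed voxels get fresh air-class
draws from a seed-derived substream, keeping determinism); the measurement is
then re-simulated at the new position. With `deform_neck = TRUE` a posterior
soft-tissue bulge with fixed scanner-frame geometry (half-ellipsoid,
semi-axes 18×14×16 mm, restricted to the inferior third of the volume) is
added to the moved body, emulating the skin folding that makes rigid
transport wrong in the neck. Its magnitude is a free parameter of the
generator, not an estimate of the in-vivo effect.

What the phantom does *not* emulate: anatomical detail (no atlas meshes, no
partial-volume microstructure), receive-coil sensitivity and RF bias,
physiological noise, eddy currents beyond the linear ramp, and chemical
shift. Passing tests therefore demonstrate the correctness and internal
consistency of the algorithms under known ground truth — not in-vivo
accuracy, which requires volunteer data.

## Problem sizes, tolerances and other numerical choices

* Default grid 64³ at 2 mm (128 mm FOV). Tests use 32³ at 4 mm and fit
  checks 48³ at 8/3 mm — the same physical head on coarser lattices — so the
  whole suite runs on a laptop in minutes. A higher-resolution profile
  (e.g. 128³ at 1.5 mm, or ≤1 mm with padding ≥3 as the Fourier method
  prefers) is available through `phantom_spec()`; results in this package's
  documentation are computed at the default sizes.
* Padding factor 3 throughout. The uniform-sphere oracle (48³ grid, radius
  6 voxels) shows the external on-axis error falling 88% → 5.6% → 4.1% for
  pad 1 → 2 → 3; at the 64³/radius-8 acceptance configuration pad 3 reaches
  3.0%. Beyond pad 2 the improvement is small — the padding mainly protects
  against the periodic fold-over that ruins pad 1.
* Dipole-fit convergence: simplex `reltol` 1e-13, two passes; positions are
  clipped no closer than half a voxel to any lattice point when evaluating
  the dipole kernel.
* Field-map validity: voxels below 5% of the robust (99th percentile)
  magnitude are flagged invalid and excluded from every fit and score. No
  spatial unwrapping is attempted; only the temporal principal value is
  used.
* Shim solver: coordinate-descent tolerance 1e-12 A, multiplier bisection to
  machine interval, KKT residual reported. Zero current is always feasible,
  so shimming can never worsen the homogeneity metric.
* Degenerate inputs fail loudly: all-zero UTE images, unimodal histograms,
  inverted bone intervals (overlapping peaks), empty masks, grids or units
  that do not match, geometry that does not fit the grid, and transforms
  that push most of the body outside the FOV are all errors; an empty brain
  mask in the multi-segment model is a warning (the fit proceeds without
  fixed brain voxels).

## Reproducing the package's validation numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every headline
quantity from scratch: the sphere-oracle errors, the brute-force convolution
equivalence, the decomposition identity and residual, slope/dipole/chi/shim
recovery errors, the 10-seed motion-strategy comparison and the shim
cross-evaluation gap. The README shows a worked example with the numbers a
default run prints.
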