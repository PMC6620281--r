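---
title: "Quantifying liver surface nodularity: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying liver surface nodularity: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsnquant)
```

## The measurement

As hepatic fibrosis advances, the liver surface loses its smooth capsular
outline and becomes nodular. The liver surface nodularity (LSN) score turns
this morphological change into a scalar imaging biomarker: trace the liver
boundary on a 2-D abdominal slice, fit a smooth low-order polynomial curve to
arcs of that boundary, and summarize how far the traced surface deviates from
the fitted curve. `lsnquant` implements the whole measurement chain plus the
statistical layer used to relate LSN to histological fibrosis grade, and a
synthetic phantom generator that provides ground truth the clinical data
cannot.

The pipeline is

1. **Bias-field correction and segmentation.** The slice is modelled as
   $I = bJ + n$: a piecewise-constant true image $J$ (liver intensity $c_1$,
   background $c_2$), a smooth multiplicative bias field $b$ (MR coil
   inhomogeneity), and zero-mean Gaussian noise $n$. Segmentation minimizes a
   local-intensity-clustering level-set energy
   $$E(\phi, b, c) = \sum_y \sum_{i=1,2} \int K_\sigma(y-x)\,
     \lvert I(x) - b(y)c_i \rvert^2 M_i(\phi(x))\,dx
     \;+\; \nu\,\mathrm{Length}(\phi) \;+\; \mu\,\mathrm{DistReg}(\phi),$$
   where $K_\sigma$ is a truncated Gaussian window, $M_1 = H_\varepsilon(\phi)$,
   $M_2 = 1 - H_\varepsilon(\phi)$ with a smoothed Heaviside, and DistReg is
   the standard double-well penalty keeping $\lvert\nabla\phi\rvert \approx 1$.
   `segment_with_bias()` alternates an explicit gradient step in $\phi$ with
   the closed-form minimizers in $c$ and $b$; the $c$ and $b$ updates can only
   lower the energy, and the sweep as a whole is required (and tested) to be
   non-increasing to within $10^{-6}$ relative.
2. **Surface line.** `extract_surface_line()` traces the largest connected
   component's boundary by marching squares with linear interpolation at
   iso-level 0.5 and resamples it at 1-pixel arc-length steps, so residuals
   are computed on a pixel-by-pixel basis.
3. **ROIs and fitting.** Arcs of the surface line (reader-supplied via CSV,
   or auto-placed: `n_rois` equal windows at equal spacing) are rotated into
   their intrinsic frame — the principal axis of the arc's point cloud — and
   fitted with an order-2/3/4 polynomial by ordinary least squares
   (`fit_segment_polynomial()`).
4. **Score.** Per ROI, the signed residuals $d_i$ between the surface and the
   fit give $\mathrm{lsn}_{\mathrm{roi}} = \sqrt{\operatorname{mean}(d_i^2)}$
   (RMS; the mean absolute residual is available as an alternative). The
   subject score is the arithmetic mean over at least three ROIs
   (`subject_lsn()`), with the per-subject CV reported alongside.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `kernel_scale` ($\sigma$) | 4 | px | window of the local clustering criterion; sets the scale on which $b$ may vary |
| `length_weight` ($\nu$) | $0.002 \cdot 255^2$ | intensity$^2$ | contour smoothness; the $255^2$ factor matches a 0–255 intensity scale |
| `regularization_weight` ($\mu$) | 1 | – | distance regularization; stability needs $\mu\,\Delta t < 0.25$ |
| `heaviside_width` ($\varepsilon$) | 1 | px | smoothing of the phase memberships |
| `time_step` ($\Delta t$) | 0.1 | – | explicit Euler step of the $\phi$ flow |
| `energy_tol` | $10^{-5}$ | relative | convergence of the alternating sweep |
| `bias_floor` | 0.1 | – | guards the division $J = I / b$ |
| `poly_order` | 4 | – | fitted curve order (2–3 selectable) |
| `resample_step` | 1 | px | pixel-by-pixel residual basis |
| `n_rois` / `min_rois` | 4 / 3 | – | at-least-three-ROIs rule for the subject score |
| units | pixels | – | mm mode multiplies by the pixel spacing exactly |

Units of the score: residuals are in pixels by default (`units = "mm"`
rescales exactly by the pixel spacing). No claim is made that phantom scores
land on any particular clinical scale: a clinical LSN of, say, 1.3–2.0
depends on scanner, spacing, interpolation and reader protocol in ways a
phantom cannot reproduce.

The energy has an exact gauge and scale structure worth knowing when changing
parameters: $(b, c) \to (kb, c/k)$ leaves everything invariant (only the
product $bc$ is identified — phantoms pin it down by normalizing the true
bias to mean 1), and $(I, \nu, \mu, \Delta t) \to (kI, k^2\nu, k^2\mu,
\Delta t/k^2)$ reproduces the identical evolution with $c$ and $J$ scaled by
$k$. The tests assert both in exact form.

## The phantom: what it emulates, what it does not

`phantom_spec()` describes a star-convex "liver" — radius
$r(\theta) = r_0(\theta) + A \sum_k \exp\!\big(-\tfrac{1}{2}
(\theta - \theta_k)^2 / w^2\big)$, a low-order Fourier base shape $r_0$ plus
compact Gaussian bumps — on a darker background, multiplied by a smooth bias
field (planar ramp or Gaussian bump, normalized to mean 1) and corrupted by
additive Gaussian noise. Everything is a pure function of the spec: same
spec, bit-identical phantom.

Defaults are chosen once for testability at a clinically plausible geometry:
128×128 px at 0.74 mm/px (a typical high-resolution T1 in-plane spacing),
liver 180 vs background 70 a.u., 16 nodules of angular width 0.12 rad
(≈10 mm of arc at the default radius — bump flanks stay well below 45° to
the surface, so the boundary remains single-valued in any ROI frame, a
precondition of the curve-fit model itself), noise SD 5.5 a.u. (5% of
contrast). The nodularity amplitude $A$ (px) is the ground-truth knob: the
acceptance suite requires the median subject LSN to increase strictly in
$A \in \{0,\dots,4\}$ across 20 seeds.

What a green phantom test does **not** establish: anatomical realism (no
ribs, vessels, partial-volume fat), MR acquisition physics, reader behaviour
in ROI placement, or the clinical score scale. It establishes that the
implementation measures what it claims — controlled nodularity in, larger
score out — and that bias, noise and discretization at plausible levels do
not break that monotonicity.

## Numerical choices

- **Convolutions** are separable Gaussian products with *reflective* borders
  (avoids energy artifacts at image edges); kernels are truncated at
  $\lceil 2.5\sigma \rceil$ and normalized. Every convolution-based term is
  tested against literal direct-summation oracles on small grids.
- **Surface extraction** smooths the binary mask with $\sigma = 1$ px before
  interpolated marching squares at iso 0.5. Midpoint crossings on the raw
  binary mask overestimate a digitized disk's perimeter by ~8% (staircase
  bias), which would inflate every LSN score; the smoothed field localizes
  the boundary to sub-pixel accuracy (disk perimeter within 0.4% of
  $2\pi r$). The measured discretization floor of the whole pipeline — a
  noiseless $A = 0$ phantom scored with the ground-truth mask — is
  ≈0.11 px RMS, frozen in the tests as a ≤0.3 px regression bound.
- **Residual direction**: residuals are measured along the intrinsic frame's
  $u$ axis, not as true perpendicular distances to the curve. The difference
  is second order for the shallow arcs the method fits, and the choice keeps
  the fit an ordinary linear least-squares problem. Fold-over (the arc not
  single-valued in its frame) is an error advising a shorter ROI; sub-step
  wiggles are tolerated since they do not break the model at the resampled
  resolution.
- **Saddle cells** in marching squares are disambiguated by the cell-center
  average; ROI auto-placement windows are half-open in arc length so windows
  are pairwise disjoint even when they tile the contour exactly.
- **Initialization**: $b \equiv 1$, $c$ from the initial mask's inside and
  outside means, $\phi$ a ±2 binary step. The initial mask comes from an
  Otsu threshold plus largest-component selection, a user-supplied box/mask,
  or a full segmentation override file (the file-based stand-in for a
  reader confirming the surface line).

## The statistics layer

`cohort_report()` mirrors the clinical analysis: per-group mean ± SD with the
CV (SD/mean × 100), a Kruskal–Wallis H test across groups, labelled pairwise
Mann–Whitney tests, the same by fibrosis stratum with F2 and F3 merged, and
ROC analyses (F0 vs F1–F3, F0&F1 vs F2&F3, F1 vs F2&F3). Choices made where
the protocol is underdetermined:

- **Exact vs approximate tests**: Mann–Whitney p-values are exact (null
  permutation distribution) for $n_a + n_b \le 12$ without ties, Wilcoxon
  signed-rank for $n \le 15$; above that, normal approximations with tie and
  continuity corrections. Thresholds chosen for desk-scale runtime and
  verified against full-enumeration oracles.
- **ICC form**: ICC(2,1) — two-way random effects, absolute agreement,
  single measure — because interobserver *agreement* on the score value is
  what an LSN reliability table interprets, not mere consistency. F-based
  McGraw–Wong intervals; reliability bands poor < 0.4 ≤ moderate < 0.6 ≤
  good < 0.8 ≤ excellent.
- **AUC inference**: DeLong variance for the CI and the test against
  AUC = 0.5; the Youden-optimal cutoff is reported as "positive when score
  greater than t", ties broken toward the smaller threshold. Confidence
  limits may differ in the second decimal from legacy SPSS output.
- **Multiplicity**: pairwise p-values are unadjusted by default (matching
  common clinical reporting); `holm = TRUE` switches on a Holm correction.
- Two-sided tests throughout.

## Known limitations

- Single 2-D slice per subject; no volumetric averaging, no 3-D level sets.
- Two-phase segmentation only (liver vs rest); adjacent isointense organs
  are handled by initialization and the largest-component rule, not by a
  multi-organ model.
- The DICOM reader is minimal: single-frame, explicit-VR little-endian,
  uncompressed. NIfTI-1, 16-bit PNG, plain PGM and CSV cover the rest.
- Which part of the liver surface to measure, and which slice, are
  configuration, not automated anatomy: the auto mode tiles the whole
  contour, which is the right default for phantoms and a neutral one for
  clinical slices.
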