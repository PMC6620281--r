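# lsnquant

Quantification of **liver surface nodularity (LSN)** from 2-D abdominal MR
slices, for imaging researchers studying hepatic fibrosis staging in fatty
liver disease. As fibrosis advances the liver capsule becomes nodular; the
LSN score measures this as the RMS deviation of the traced liver surface
line from a smooth polynomial curve fitted along it — a noninvasive
biomarker that separates fibrosis strata without biopsy.

The package implements the full measurement chain:

1. **Bias correction + segmentation** — the slice is modelled as
   `I = b·J + n` (smooth multiplicative bias `b`, piecewise-constant truth
   `J`, Gaussian noise); liver and bias field are estimated jointly by
   minimizing a local-intensity-clustering level-set energy
   `E = Σ_y Σ_i ∫ K_σ(y−x) |I(x) − b(y)c_i|² M_i(φ(x)) dx + ν·Length(φ) + μ·DistReg(φ)`
   with alternating closed-form updates for `c` and `b` and an explicit
   gradient flow for `φ`.
2. **Surface line** — sub-pixel marching-squares boundary of the liver mask,
   resampled at 1-pixel arc-length steps.
3. **ROI curve fitting** — arcs of the surface line fitted with an order
   2/3/4 polynomial in the arc's intrinsic (principal-axis) frame.
4. **Score** — per ROI `lsn_roi = sqrt(mean(d²))` of the signed residuals
   `d`; per subject the arithmetic mean over ≥ 3 ROIs.
5. **Diagnostic statistics** — Kruskal–Wallis, Mann–Whitney, Wilcoxon
   signed-rank, CV, ICC(2,1) with McGraw–Wong intervals, and ROC/AUC with
   DeLong inference and Youden cutoffs, reported in the layout used in
   clinical LSN studies.

A seedable **phantom generator** provides synthetic livers with a
controllable boundary-nodularity amplitude (plus known bias field, noise and
ground-truth mask), so every stage is validated against ground truth.

## Worked example

```r
library(lsnquant)

# a nodular phantom (amplitude 3 px) with a 30% planar bias ramp and noise
spec <- phantom_spec(nodularity_amplitude = 3, noise_sd = 5.5,
                     bias_contrast = 0.3, bias_kind = "planar_ramp", seed = 42)
ph    <- generate_phantom(spec)
slice <- lsn_slice(ph$image, pixel_spacing = spec$pixel_spacing)

res <- measure_subject(slice, lsn_config(params = lic_params(max_iters = 120)))
sprintf("subject LSN score: %.3f %s (CV %.1f%%)", res$lsn_score, res$units, res$cv_percent)
#> subject LSN score: 0.816 pixels (CV 45.0%)
round(res$lsn_roi, 3)   # the four per-ROI scores averaged into the subject score
#> [1] 0.678 1.108 1.120 0.360
```

The score is the mean RMS roughness (in pixels) of the liver surface over
four automatically placed ROIs; it rises monotonically with the phantom's
nodularity amplitude (≈0.11 px discretization floor at amplitude 0). The
segmentation recovered the ground truth exactly here (Dice 1.0) and the
estimated bias field correlates 0.996 with the true ramp inside the liver.

ROC analysis of scores against a binary fibrosis label:

```r
rr <- roc_analysis(c(1.31, 1.29, 1.42, 1.50, 1.61, 1.44, 1.72, 1.66, 1.55, 1.38),
                   c(0,    0,    0,    0,    1,    0,    1,    1,    1,    1))
sprintf("AUC %.3f (95%% CI %.3f-%.3f), cutoff > %.2f, sens %.1f%%, spec %.1f%%",
        rr$auc, rr$ci95[1], rr$ci95[2], rr$cutoff, rr$sensitivity, rr$specificity)
#> "AUC 0.880 (95% CI 0.626-1.000), cutoff > 1.50, sens 80.0%, spec 100.0%"
```

A command-line surface wraps the same pipeline
(`phantom`, `measure`, `stats`, `roc` subcommands), e.g.

```sh
Rscript -e 'quit(status = lsnquant::cli_main())' phantom --out out --amplitude 2 --seed 3
Rscript -e 'quit(status = lsnquant::cli_main())' measure --input out/phantom.nii --subject s1 --out out
```

Inputs: single-frame DICOM (explicit-VR little-endian), NIfTI-1
(`.nii`/`.nii.gz`), 16-bit PNG, plain PGM, CSV matrices. Outputs are
text-diffable (JSON results, CSV contours/curves, Markdown reports) and
byte-identical across reruns of the same configuration.

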