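---
title: "Methods: g-ratio weighted imaging and the transmit-field correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: g-ratio weighted imaging and the transmit-field correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gratiomap)
```

## The model

G-ratio weighted imaging estimates, per voxel, an aggregate of the
inner-to-outer radius ratio of myelinated axons. Two independent
contrasts are combined: magnetization transfer saturation (MTsat), a
semi-quantitative proxy for macromolecular (myelin) content in percent
units, and the NODDI diffusion compartments `ν_icvf` (intracellular)
and `ν_iso` (free water). The chain is

* `MVF = α · MTsat` — a proportional calibration without intercept;
* `AWF = (1 − ν_iso) · ν_icvf` — the axonal water fraction;
* `AVF = (1 − MVF) · AWF` — the axonal share of the non-myelin volume;
* `g = sqrt(AVF / (MVF + AVF))` — ranging from 0 (no axon) to 1 (no
  myelin).

The package assumes all maps are already aligned on one grid;
registration, segmentation, MTsat estimation from raw multi-echo data
and NODDI fitting are upstream concerns and out of scope. Volumes
travel as `volume_map` objects (3-D array + 4×4 affine); undefined
voxels are `NaN`, never 0, because MTsat near 0 is a legitimate value
in CSF.

### Transmit-field correction

MTsat retains a residual dependence on the transmit field `B1+`
(expressed as fraction of the nominal flip angle). The heuristic
correction is multiplicative,

`MTsat_corr = MTsat_uncorr · (1 − C) / (1 − C · B1+)`,

with `C = 0.4` for the MT pulse the default targets; `C` is always a
configuration value because other pulses need recalibration. The
correction is exactly invertible (`apply_b1_bias()` /
`correct_mtsat()` compose to the identity), which the tests exploit.
Implausible B1+ values are propagated, never silently clipped; a
non-positive denominator aborts with the offending voxel count, and
percent-of-nominal inputs (median > 10) are rescaled with a warning.

Three variants are compared throughout: correction with a measured
reference field (`REFERENCE_B1`), no correction (`NONE`), and
correction with a data-driven field estimate (`DATA_DRIVEN`). Each
variant is calibrated separately, so calibration absorbs any global
scale difference — the comparison isolates *spatial* field structure.

### Histology-anchored calibration

`α` is anchored in a region with a known histological myelin volume
fraction. From a fiber table (inner radius `r`, sheath thickness `m`,
count), `mvf_from_histology()` builds the cross-sectional volume
budget: myelinated-axon area `TAV_m = Σ π r²`, myelin area
`TMV = Σ π (r+m)² − TAV_m`, unmyelinated-axon area as a fraction of
`TAV_m` (default 0.43 — the common report of unmyelinated axons as 30 %
of total axonal volume corresponds to 0.3/0.7 ≈ 43 % of the myelinated
volume), and an extracellular fraction of the total (default 0.25);
`MVF_hist = TMV / TV`. `calibrate_alpha()` divides `MVF_hist` by the
group-average MTsat in the calibration region. The group average is the
unweighted mean of per-subject/session ROI means (pooling both
sessions); whether the source analyses pooled voxels or subject means
is not derivable, and subject-level means are the package's convention
for every ROI statistic, so they are used here too.

## Quality masking

Low diffusion SNR drives `ν_icvf` into a ceiling artifact
(`ν_icvf ≥ 0.999`). The pipeline therefore:

1. builds a group WM mask by thresholding the average WM tissue
   probability at 0.95;
2. computes `SNR = (mean_b0 / σ) √n_b0` per subject (`n_b0 = 12` b0
   images by default; σ is a precomputed scalar noise estimate — raw
   noise estimation is out of scope);
3. sweeps an SNR threshold grid (integers 1–80 by default) and picks
   the value minimizing the group-mean ratio of artifactual to total
   voxels in the mask `WM ∧ (SNR ≥ t)`, tie-breaking to the smallest
   threshold to retain as many voxels as possible;
4. selects ROIs: *whole-WM* ROIs lie completely inside the WM mask;
   *high-SNR* ROIs additionally overlap the high-SNR mask in at least
   95 % of their voxels (voxel-count fraction, not Dice).

The search drops a subject from a candidate threshold when that
candidate empties the subject's mask, and excludes (with a warning)
candidates that empty every mask; the contract only fixes the
all-empty case, and keeping partial information mirrors how a
practitioner reads the swept curve.

## Agreement statistics

Per-ROI means (over defined voxels, optionally restricted to the WM
mask) are aggregated into group means. For paired per-ROI values,
`bland_altman()` computes differences `δ_i = ref_i − test_i`, bias
`δ̄ = mean(δ)`, and error `ε = 1.96 · SD(δ)` with the sample (N−1)
denominator — the textbook limits-of-agreement half-width. Both are
normalized by the *dynamic range* `Δ_DR = max − min` of the per-ROI
group means of the reference metric, yielding percentages comparable
across metrics. The sign convention is reference minus test. Two
numerical conventions deserve note: the N−1 denominator (consistent
with the 1.96·SD reading of the error) and the 1/N factor in the bias;
both are verified against brute-force recomputation in the tests.
Test-retest agreement applies the same machinery to session-wise group
means of the reference variant.

## CoV analysis

Group variability per variant is assessed on tissue-weighted smoothed
maps: `G∗(map·tpm) / G∗(tpm)` with a Gaussian kernel of 6 mm FWHM
(converted to per-axis sigma via the affine's voxel sizes), reflective
boundaries, undefined voxels contributing zero weight, and output
undefined where the smoothed tissue weight falls below 0.05. The
smoother is implemented as separable 1-D convolutions (precomputed
band matrices), which keeps a 32³ volume well under a millisecond per
axis. CoV is `100 · SD / mean` across all subject/session maps
(N−1 denominator), undefined at voxels with fewer than two
contributions or non-positive mean. The wording "ratio between the
group mean and group standard deviation" found in some descriptions is
taken as reversed: a mean/SD ratio is not a CoV, and published
magnitudes are consistent with SD/mean. Voxel-wise Bland–Altman on CoV
maps normalizes by the mask-mean of the reference CoV (the summary
used for the normalizer is not fixed by convention; the mask-mean is
the package's choice and is reported alongside).

## The synthetic phantom

Real multi-subject MRI for this design is not redistributable, so the
package ships a generator whose defaults *are* the study conditions:
25 subjects × 2 sessions on a 32³ grid (2 mm isotropic), 24 box ROIs
plus a calibration region, and:

* **Ground truth.** Per-ROI true MVF runs 0.445 → 0.408 and AVF
  0.308 → 0.384 (anti-correlated, matching the published ranges where
  the highest-myelin ROI has the lowest g); the calibration region
  plants MVF = 0.3623, the histological anchor value, and sits inside
  the low-SNR slab — as a brainstem calibration region does — so it
  joins the whole-WM but not the high-SNR ROI set. `MTsat_true =
  MVF_true / α_true` with `α_true = 0.25 p.u.⁻¹`; `ν_iso` is drawn
  per ROI from [0.02, 0.12]; `ν_icvf = AWF_true / (1 − ν_iso)`.
* **Transmit field.** A fixed center-high quadratic dome (the typical
  head-coil transmit profile at 3 T) plus a per-subject random
  second-order polynomial at half weight, centered to spatial mean 1
  and scaled to max deviation 0.2. The shared dome gives the
  uncorrected variant a systematic group-level bias — the phenomenon
  the comparison design exists to measure — while the random part
  varies the field across subjects. The data-driven surrogate is the
  true field plus an independent smooth error field of amplitude 0.05;
  no generative estimation model is re-implemented, because the
  comparison only needs a second, imperfect field source.
* **Noise.** Additive Gaussian on the derived maps (SD 0.08 p.u. on
  MTsat ≈ 0.02 in MVF units, 0.02 on ν_icvf, 0.01 on ν_iso), fresh per
  session; measured fractions are clamped to [0, 1]. Map-level noise is
  the right abstraction here since map estimation is out of scope;
  Rician raw-signal simulation is deliberately not attempted.
* **SNR and ceiling.** SNR is 60 in the main volume and 20 in the
  bottom-quarter slab; the mean-b0 volume is constructed as
  `SNR·σ/√n_b0` so `snr_map()` reproduces the profile exactly. Each
  voxel's `ν_icvf` is replaced by a value in [0.999, 1] with
  probability `0.5·exp(−SNR/13)` — monotone decreasing in SNR, ≈ 11 %
  at SNR 20 and ≈ 0.5 % at SNR 60.

The dataset is a pure function of the configuration (a fixed-seed RNG
scope that also restores the caller's RNG state). What the phantom
does *not* emulate: registration error, susceptibility distortion,
biological between-subject variation of the ground truth, Rician noise
floors, and partial-volume tissue boundaries. Passing tests therefore
validate the *analysis machinery* — calibration normalization,
bias propagation, masking logic, agreement statistics — not
acquisition robustness on real data.

## Design choices and degenerate inputs

* Grid compatibility tolerates 1e-4 (world units) on affine entries;
  no resampling exists in-package.
* Out-of-range MVF voxels are counted and reported, not clipped, at
  the operation level; the pipeline driver enables clipping
  (`clip = TRUE`) because noisy non-tissue voxels (MTsat ≈ 0 ± noise)
  otherwise make `g` undefined. With both fractions non-negative,
  `AVF/(MVF+AVF) ∈ [0, 1]` keeps `g` real without further guards;
  `MVF = AVF = 0` yields `NaN`.
* `g` ROI statistics average voxel-wise `g`, never `g` of averaged
  MVF/AVF (the two differ by Jensen's inequality; voxel-wise-first is
  the established construction).
* The YAML configuration round-trips all numeric fields; the ceiling
  probability function, being code, is restored as the default on
  read.
* Problem sizes in the tests (16³ grids, 2–4 subjects) and the
  acceptance run (the 32³, 25-subject default) were chosen to keep a
  full suite run in the tens of seconds while leaving every group-level
  statistic well-conditioned (≥ 21 ROIs, ≥ 2 sessions).

## Known limitations

* The histological anchor transfers a fixed-age, single-donor estimate
  to every subject; a calibration error propagates as a global bias in
  MVF and hence g.
* The data-driven-correction surrogate's error amplitude is a free
  knob, not an estimate of any particular algorithm's error structure;
  conclusions about the *ratio* of improvement are qualitative
  (ordering), not quantitative.
* The SNR threshold search assumes the ceiling artifact is the
  dominant SNR-linked failure mode; other low-SNR biases in NODDI are
  not modeled.
* Whole-WM comparisons recompute their own dynamic range from the
  whole-WM ROI set; published whole-WM normalizers were not printed
  and cannot be verified.
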