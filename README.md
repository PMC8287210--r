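# gratiomap

Voxel-wise MR g-ratio weighted imaging with transmit-field (B1+) bias
correction, for quantitative-MRI researchers who combine a
myelin-sensitive map (magnetization transfer saturation, MTsat) with
axon-sensitive NODDI parameters.

## The science

The g-ratio of a myelinated axon is the ratio of its inner to outer
radius. At the voxel level, an aggregate MR g-ratio is computed from the
myelin volume fraction (MVF) and axon volume fraction (AVF):

    MVF = α · MTsat
    AWF = (1 − ν_iso) · ν_icvf
    AVF = (1 − MVF) · AWF
    g   = sqrt( AVF / (MVF + AVF) )

where `ν_icvf` and `ν_iso` are the NODDI intracellular and isotropic
volume fractions, and α is a calibration constant anchoring MTsat to a
histological MVF estimate in a reference region (computed in-package
from a fiber table of inner radii and myelin sheath thicknesses).

MTsat retains a residual dependence on the radio-frequency transmit
field B1+. The package applies the heuristic multiplicative correction

    MTsat_corr = MTsat_uncorr · (1 − C) / (1 − C · B1+)

with `C = 0.4` by default (calibrated per MT pulse), and quantifies
what omitting or approximating this correction does to g, AVF and MVF:

* **Three correction variants** — reference field map (`REFERENCE_B1`),
  none (`NONE`), and a data-driven field estimate (`DATA_DRIVEN`) —
  each with its own calibrated α.
* **Quality masking** — a group white-matter mask from tissue
  probability maps, an SNR map from the mean-b0 volume, and an SNR
  threshold optimized against the low-SNR ceiling artifact in ν_icvf
  (ν_icvf ≥ 0.999); ROI selection by complete-WM membership and ≥95 %
  high-SNR overlap.
* **Agreement statistics** — Bland–Altman bias (mean paired difference)
  and error (1.96 × SD of differences) between variants and between
  sessions, expressed as percentages of the metric's dynamic range
  across ROIs.
* **Group variability** — tissue-weighted Gaussian smoothing (6 mm
  FWHM) followed by voxel-wise coefficient-of-variation maps across
  subjects/sessions, compared between variants.
* **Synthetic phantom** — a multi-subject, two-session dataset with
  known ground-truth MVF/AVF/g, a smooth dome-plus-random-polynomial
  B1+ field, session noise, and an SNR-dependent ν_icvf ceiling, so the
  entire pipeline is testable without any acquisition.

All volumes are NIfTI-1/2 (via RNifti); atlases are integer NIfTI plus
a TSV name table; all tabular outputs are TSV.

## Worked example

```r
library(gratiomap)

cfg <- analysis_config(phantom = phantom_config(n_subjects = 6, seed = 42))
report <- run_full_analysis(cfg)
report
#> <analysis_report>
#>   alphas: REFERENCE_B1=0.2500, NONE=0.2573, DATA_DRIVEN=0.2503
#>   SNR threshold: 21; 25 whole-WM / 24 high-SNR ROI(s)
#>   dynamic range: g=0.05635 AVF=0.07513 MVF=0.0372
#>   method agreement (relative %):
#>     g    vs NONE         [high_snr]: bias   +4.03%  error  19.69%
#>     g    vs DATA_DRIVEN  [high_snr]: bias   +1.76%  error   3.12%
#>     avf  vs NONE         [high_snr]: bias   +2.42%  error  11.67%
#>     avf  vs DATA_DRIVEN  [high_snr]: bias   +1.07%  error   1.85%
#>     mvf  vs NONE         [high_snr]: bias   -8.08%  error  39.41%
#>     mvf  vs DATA_DRIVEN  [high_snr]: bias   -3.53%  error   6.25%
#>     mvf  vs NONE         [whole_wm]: bias   -3.50%  error  17.49%
#>     mvf  vs DATA_DRIVEN  [whole_wm]: bias   -1.53%  error   2.84%
```

Reading the output: the phantom plants α = 0.25 and the
reference-corrected variant recovers it; skipping the B1+ correction
(`NONE`) biases the ROI-level g-ratio by ~4 % of its dynamic range with
a ~20 % error, while the imperfect data-driven correction shrinks both
several-fold — the qualitative conclusion the comparison design is
built to expose. Individual stages are available directly:
`correct_mtsat()`, `mvf_from_histology()`, `calibrate_alpha()`,
`compute_gratio_set()`, `snr_map()`, `optimize_snr_threshold()`,
`select_rois()`, `roi_stats_table()`, `bland_altman()`,
`tissue_weighted_smooth()`, `cov_map()`.

## Package layout

* `R/volume-map.R` — `volume_map`/`label_atlas` containers, NIfTI I/O,
  masked arithmetic
* `R/transmit-correction.R` — heuristic B1+ correction and variants
* `R/histology-calibration.R` — fiber-table MVF and α calibration
* `R/gratio-maps.R` — MVF/AWF/AVF/g computation
* `R/quality-masks.R` — SNR maps, WM masks, threshold search, ROI rules
* `R/agreement-stats.R` — ROI statistics, dynamic range, Bland–Altman
* `R/cov-analysis.R` — tissue-weighted smoothing, CoV maps and
  comparison
* `R/phantom.R` — synthetic dataset generator and NIfTI writer
* `R/pipeline.R` — configuration and the end-to-end driver
* `vignettes/gratio-mapping.Rmd` — methods and design notes
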