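# csfflow

Quantification of pulsatile cerebrospinal-fluid (CSF) flow from
cardiac-gated cine phase-contrast MRI (pcMRI), with the longitudinal
paired statistics used to follow shunted hydrocephalus patients.

## The problem

With every heartbeat, CSF oscillates between the cranial and spinal
compartments: through the aqueduct of Sylvius (intraventricular flow) and
through the cervical subarachnoid space at C2–C3 (whole craniospinal
flow). Cine pcMRI encodes fluid velocity into image phase; a
retrospectively gated acquisition reconstructed to 32 frames over one
averaged cardiac cycle yields a per-pixel velocity waveform. From it one
measures the **stroke volume** (SV) at each site — the volume displaced
back and forth per cardiac cycle — and the **CSF ratio**

```
CSF_RATIO = SV_AQU * 100 / SV_CERV   (percent),
```

the intraventricular share of total craniospinal pulsatility (≈10% in
healthy adults, 40–50% in normal-pressure hydrocephalus). Tracking these
quantities before and after shunt surgery asks for paired tests on a
small cohort, where an enumeration-exact Wilcoxon signed-rank test is
preferable to approximations.

## What the package does

- **Segmentation by cardiac synchrony.** For each pixel in a rectangular
  ROI, the FFT of its velocity time series gives the amplitude of the
  first (fundamental) harmonic — the subject's heart frequency, since the
  gated cycle spans exactly one period. With the `2/N` normalization a
  pixel moving as `A·sin(2πk/N)` scores exactly `A` cm/s, so the
  parametric image is thresholded in velocity units
  (`compute_parametric_image()`, `segment_by_threshold()`,
  `suggest_threshold()` for an Otsu-style automatic cut).
- **Aliasing handling.** Velocities beyond the velocity-encoding limit
  (VENC) wrap: `v ↦ ((v+VENC) mod 2·VENC) − VENC`. Samples whose sign
  opposes the mask's instantaneous dominant sign at near-VENC magnitude
  are flagged and shifted by `2·VENC` back toward the jet
  (`detect_aliasing()`, `correct_aliasing()`); if more than a few mask
  pixels are affected, correction is refused and re-acquisition at twice
  the VENC is advised.
- **Eddy-current calibration.** The per-frame mean velocity of a static
  background region near the ROI is subtracted everywhere
  (`background_correct()`).
- **Flow and stroke volume.** `Q(k) = Σ_mask v·a` (0.01 mL/s per
  cm/s·mm²) reconstructs the 32-point flow curve; trapezoidal quadrature
  on the periodic grid gives the directional displaced volumes `V⁺`,
  `V⁻`, the stroke volume `SV = (V⁺+V⁻)/2` and the net flow `V⁺−V⁻`
  (`compute_flow_curve()`, `compute_stroke_volume()`).
- **Cohort statistics.** Per-patient CSF ratios, percent changes, and all
  pairwise timepoint comparisons with an enumeration-exact Wilcoxon
  signed-rank test (mid-ranks for ties, zeros dropped and counted) and a
  paired t-test gated by a Shapiro–Wilk normality check
  (`wilcoxon_signed_rank_exact()`, `paired_t()`, `summarize_cohort()`).
- **Synthetic truth.** A phantom generator (`generate_cine_series()`)
  emits NIfTI + JSON-sidecar series with analytically known masks, flow
  curves and stroke volumes, including noise, planar eddy offsets and
  phase wrapping; `generate_cohort()` simulates three-timepoint paired
  cohorts with log-normal marginals, within-patient correlation and a
  configurable non-responder fraction.

## Worked example

```r
library(csfflow)

spec <- aqueduct_phantom(noise_sd = 0.5, seed = 42)   # 10 cm/s jet, VENC 10
g    <- generate_cine_series(spec)
bg   <- background_ring(c(33, 33), 5, 8, dim = c(64, 64))
res  <- quantify_cine_series(g$series, threshold = "otsu", background = bg)

res$report$threshold        # 2.71  cm/s, automatic two-class cut
res$report$n_mask_pixels    # 9     pixels in the recovered jet
res$sv
#> stroke volume (aqueduct): 59.1 uL/cc (V+ 59.2, V- 59.0, net +0.2 uL)
g$truth$regions[[1]]$sv_ul  # 57.8  analytic ground truth
```

The recovered stroke volume (59.1 µL per cardiac cycle) sits within the
noise-driven few-percent band around the phantom's analytic truth
(57.8 µL). A synthetic preoperative/6-month/12-month cohort runs through
the same summary the clinical study would use:

```r
tab <- generate_cohort(cohort_spec(seed = 1))
summarize_cohort(tab)
#> Cohort summary (mean +/- SD):
#>   sv_aqu     T1: 260.5 +/- 120.3  T2: 240.8 +/- 152.5  T3: 220.0 +/- 108.7
#>   sv_cerv    T1: 633.8 +/- 178.0  T2: 582.7 +/- 180.5  T3: 583.6 +/- 273.0
#>   csf_ratio  T1: 48.2 +/- 36.0   T2: 46.3 +/- 35.7   T3: 46.5 +/- 34.7
#> Pairwise tests (two-sided p):
#>   sv_aqu     T1-T2  wilcoxon_signed_rank_exact   p = 0.5416
#>   sv_aqu     T1-T2  paired_t                     p = 0.4858
#>   ...
```

(a single simulated 14-patient cohort is noisy; the generator's means are
calibrated to 240/214/193 µL aqueductal and 627/557/496 µL cervical).

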