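---
title: "Quantifying pulsatile CSF flow from cine phase-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsatile CSF flow from cine phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfflow)
```

## The measurement model

Cine phase-contrast MRI encodes the through-plane velocity of each voxel
into image phase. A cardiac-gated acquisition, retrospectively
reconstructed to $N = 32$ frames spanning one averaged cardiac cycle of
duration $T$, yields a stack $p(x, y, k)$ of stored phase values. This
package uses a single explicit linear convention, declared in a JSON
sidecar: the integer range $(p_{\min}, p_{\max})$ maps onto
$(-V_{enc}, +V_{enc})$,

$$ v = V_{enc}\left( \frac{2\,(p - p_{\min})}{p_{\max}-p_{\min}} - 1 \right), $$

with positive velocity craniocaudal. Vendor DICOM phase conventions vary
and are out of scope; making the convention part of the data keeps every
downstream computation bit-exactly testable. Stored phase is kept
real-valued on the declared grid (quantization is available but off), and
the value $+V_{enc}$ is representable at $p_{\max}$: only magnitudes
strictly beyond $V_{enc}$ alias. This matters because the velocity
encoding is deliberately chosen close to the expected peak velocity
(10 cm/s at the aqueduct, 5 cm/s at the neck), so the peak of a
well-encoded jet sits exactly at the edge of the range.

## Segmentation by cardiac synchrony

CSF is distinguished from static tissue not by its intensity but by its
*periodicity*: it pulses at the heart rate. Because one gated record
spans exactly one cardiac cycle, the heart frequency is discrete Fourier
bin 1 of the per-pixel time series. The parametric image is

$$ P(x, y) = \frac{2}{N}\left| \sum_{k=0}^{N-1} v(x,y,k)\,
   e^{-2\pi i k / N} \right|, $$

computed by FFT over all pixels of a rectangular ROI. The $2/N$
normalization makes $P$ an amplitude in cm/s — a pixel moving as
$A \sin(2\pi k/N + \varphi)$ scores exactly $A$ — so the segmentation
threshold is a velocity, directly comparable to the operator's visual
cut between weakly and strongly pulsatile voxels. The parametric value
is insensitive to any temporally constant offset (DC lives in bin 0),
which is why eddy-current offsets do not disturb the segmentation, and
zero for any pure higher harmonic.

`segment_by_threshold()` keeps every ROI pixel with $P \ge$ threshold;
nothing else — no morphology, no size filtering — because the reference
procedure is thresholding only (an optional largest-component filter
exists, off by default). `suggest_threshold()` offers an automatic
starting point: the exact Otsu criterion (between-class variance
maximization) evaluated over the sorted amplitudes themselves rather
than over a binned histogram, since the ROI contains at most a few
thousand continuous values; the returned cut is the midpoint of the gap
at the optimal split, hence strictly between the two classes. It errors
when all values are identical, where no two-class separation exists.

## Velocity aliasing

A true velocity outside $[-V_{enc}, V_{enc})$ wraps modularly:
$v \mapsto ((v + V_{enc}) \bmod 2V_{enc}) - V_{enc}$ (`wrap_phase()`).
For a coherent jet with single wraps, an aliased sample betrays itself
by carrying near-VENC magnitude with the *wrong sign* relative to the
rest of the region at that frame. `detect_aliasing()` therefore flags
mask samples whose sign opposes the mask's instantaneous dominant sign
(the sign of the mean mask velocity at that frame) while
$|v| \ge \alpha V_{enc}$, default $\alpha = 0.8$. This is intentionally
the simplest rule consistent with single-wrap jets — not spatial phase
unwrapping — and it is validated sample-for-sample against the
generator's wrap log. Its known blind spot: a sample wrapped so far that
its aliased magnitude falls below $\alpha V_{enc}$ (true magnitude above
$(2-\alpha)V_{enc}$) escapes detection, which is one reason double wraps
are rejected at generation time.

`correct_aliasing()` shifts each flagged sample by $2V_{enc}$ toward the
dominant sign. Correction is refused when more than "a few" mask pixels
are affected — the remedy then is re-acquisition at twice the VENC. "A
few" is quantified as more than 10% of mask pixels *and* more than an
absolute floor of 3 pixels (both configurable). The absolute floor is a
deliberate design choice: an aqueductal jet can be under ten pixels, and
a percentage-only policy would refuse to fix a single wrapped pixel —
which is exactly the "only few pixels" case postprocessing is meant to
handle.

## Eddy-current calibration and flow reconstruction

Scanner eddy currents add a spatially smooth, temporally constant
spurious velocity baseline. `background_correct()` subtracts, at each
frame, the mean velocity of a static background region close to the
ROI. For a locally planar offset field, a background that is symmetric
about the CSF region (e.g. `background_ring()`) averages to the offset
at the region's center, so the subtraction cancels what the mask sees.

The volumetric flow curve is $Q(k) = \sum_{\text{mask}} v(x,y,k)\,a$
with pixel area $a$; 1 cm/s over 1 mm² is 0.01 mL/s. Stroke volume
integrates the directional lobes by trapezoidal quadrature on the
periodic grid (closing frame $N-1$ back to frame 0, which on a uniform
periodic grid is the sample mean times $T$):

$$ V^{+} = \int_0^T \max(Q, 0)\,dt, \quad
   V^{-} = \int_0^T \max(-Q, 0)\,dt, \quad
   SV = \tfrac{1}{2}(V^{+} + V^{-}). $$

$SV$ is the mean back-and-forth displaced volume; the net flow
$V^{+} - V^{-}$ (physiologic CSF production at the aqueduct) is reported
alongside, never suppressed, and both directional volumes are emitted so
a systolic-only convention remains recoverable. For a half-sine lobe
sampled at 32 points the quadrature error is about 0.3% (the integrand
has kinks at the zero crossings, which fall on sample points for a pure
fundamental); this is the accuracy floor the acceptance checks measure
against the closed form $\int_0^T |\sin(2\pi t/T)|\,dt\cdot\frac12 = T/\pi$.

Choosing $SV = (V^{+}+V^{-})/2$ has a consequence worth stating: a small
constant flow offset $C$ on a zero-mean waveform of amplitude $B$
perturbs $SV$ only at second order ($\approx c^2/2$ with $c = C/B$),
because it inflates one lobe and deflates the other almost equally. The
*directional* volumes are each biased at first order
($\approx \pi c/2$). Eddy-current correction therefore matters most for
$V^{\pm}$ and for the net flow; the symmetric $SV$ is intrinsically
robust to small baselines. The package's own eddy-correction checks
report both error channels.

## The synthetic phantom

`generate_cine_series()` builds velocity truth as
$v(x,y,t) = \sum_r v_{peak,r}\, s_r(x,y)\, w_r(t) + e(x,y) + \epsilon$:

- **Regions**: a disc (aqueductal jet) or annulus (cervical crown) with
  a parabolic (Poiseuille-like) or flat spatial profile $s \in [0,1]$,
  sampled at pixel centers with no partial-volume integration — this
  keeps the analytic stroke volume exact and testable. The waveform $w$
  is a truncated Fourier series in cardiac phase (fundamental plus
  optional harmonics and a constant net-flow term).
- **Defaults**: aqueduct — disc of radius 2 px at 0.55 mm spacing,
  parabolic, peak 10 cm/s, VENC 10 cm/s, pure fundamental over a 1 s
  cycle (true SV ≈ 58 µL/cycle); cervical — annulus 6–9 px, flat
  4.3 cm/s, VENC 5 cm/s (true SV ≈ 584 µL/cycle, about ten times the
  aqueductal value, matching the physiological ratio).
- **Artefacts**: i.i.d. Gaussian velocity noise per pixel per frame (on
  velocity, not on the complex MR signal — sufficient to stress the
  fundamental-harmonic segmentation, which is the mechanism under
  test); a planar eddy offset $e_0 + e_r\,\mathrm{row} +
  e_c\,\mathrm{col}$; optional phase wrapping with a wrap log. Region
  peaks at or beyond $2V_{enc}$ are rejected under wrapping (an
  irrecoverable double wrap) unless explicitly overridden.
- **Ground truth**: per region, the analytic flow curve at the sample
  times, the pixel mask, and the stroke volume from a dense (2^15-point)
  quadrature of the continuous waveform — for a pure fundamental this
  matches the closed form $(\sum s\,a)\,v_{peak}\,T/\pi$ to well below
  0.1%.

What the phantom does *not* emulate: k-space/complex-signal physics,
partial-volume and chemical-shift effects, gating jitter, motion,
through-plane misalignment, and blood-flow compartments. Passing the
recovery tests therefore demonstrates the correctness of the numerical
chain (segmentation, aliasing, calibration, quadrature), not robustness
to every in-vivo artefact.

## The synthetic cohort

`generate_cohort()` draws per-patient stroke volumes at three timepoints
(preoperative, 6 and 12 months) from log-normal marginals
moment-matched to the requested mean/SD —
$\sigma^2 = \log(1 + SD^2/M^2)$, $\mu = \log M - \sigma^2/2$ — so the
specified moments hold exactly and draws are strictly positive (a normal
model with SD ≈ 0.5·mean would routinely produce negative volumes).
Defaults are calibrated to a 14-patient shunted cohort: aqueductal
240/214/193 µL (SD 114/157/145), cervical 627/557/496 µL
(SD 229/234/234). Within-patient correlation across timepoints comes
from a shared patient factor,
$Z_t = \sqrt{\rho}\,U + \sqrt{1-\rho}\,\epsilon_t$. The study reports no
per-patient values, so $\rho$ is unconstrained by data; the default 0.6
is a mid-range test–retest dependence chosen once as plausible for
repeated pcMRI measurements. A configurable fraction of "non-responder"
patients (default 2/14, the observed minority with postoperative
increases) has its patient-level log-change from baseline sign-flipped,
$\log X'_t = 2\log X_{T1} - \log X_t$; flipping on the log scale keeps
reflected trajectories positive, which the raw-scale reflection
$2X_{T1} - X_t$ would not.

## Paired statistics

`wilcoxon_signed_rank_exact()` drops zero differences (reporting the
count), assigns mid-ranks to tied magnitudes, and for up to 20 pairs
computes the null distribution of the positive-rank sum exactly via its
generating function over doubled ranks (all $2^n$ sign assignments,
without enumeration); the study's $n = 14$ sits comfortably in exact
range. The two-sided p is twice the smaller tail, capped at one. Beyond
20 pairs a normal approximation with the tie-robust variance
$\sum r_i^2/4$ is used and flagged as approximate. `paired_t()` is the
classical paired t-test accompanied by a Shapiro–Wilk normality check on
the differences, reported (and warned about below 0.05) rather than
silently gating — the analyst sees both test families side by side, and
no multiplicity correction is applied by default (a Holm option exists).

Degenerate inputs are first-class: all-zero differences, zero variance,
fewer than two complete pairs, and single-patient tables all produce
defined errors, which `summarize_cohort()` converts into explicit
"unavailable" entries rather than numbers.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run the full pipeline on
64×64×32 phantoms over 20 seeds, check the FFT path against a
direct-summation oracle at 16×16×32 to 1e−10 relative tolerance, verify
the exact Wilcoxon against explicit $2^n$ enumeration to 1e−12, and
estimate its type-I rate from 2000 simulated null cohorts and its power
against a 20% paired decrease (correlation set by the closed-form
log-normal covariance identity so the effect-to-difference-SD ratio is
one) from 200 replicates. These sizes were chosen as the smallest that
make the Monte-Carlo bounds sharp (3-standard-error bands; binomial 95%
bounds at $n = 2000$).

## Known limitations

- Single slice, single VENC per series; no multi-site joint model.
- The aliasing rule assumes a coherent single-wrap jet; scattered or
  double wraps are out of its design envelope (and double wraps are
  refused at generation).
- The sign-opposition detector cannot see wraps whose aliased magnitude
  falls below $\alpha V_{enc}$.
- The cohort simulator reproduces marginal moments, positivity,
  correlation and the non-responder pattern — not any mechanistic model
  of shunt response.
- Stored-phase conventions other than the package's own linear sidecar
  convention (e.g. vendor DICOM encodings) must be converted upstream.
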