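---
title: "Chamber-specific heartbeat phenotyping: models and methods"
author: "chamberbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chamber-specific heartbeat phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberbeat)
```

## The problem

Embryonic zebrafish are a standard model for cardiac drug screening: the
heart is transparent, two-chambered (atrium and ventricle), and beats at
roughly 2--3 Hz at 2 days post-fertilization. Fluorescent reporter lines
(e.g. myocardium-specific GFP) make both chambers visible in time-lapse
microscopy. Many cardiotoxic effects are chamber-specific — an
atrioventricular (AV) conduction block slows the ventricle but not the
atrium — so a useful phenotyping tool must segment the chambers separately
and quantify each one's rate, size and contraction.

`chamberbeat` turns a heartbeat recording (a TIFF/PNG image series with
frame rate and pixel size) into a per-fish phenotype record, and provides
the screen-level statistics used to call hits and score toxicity across
hundreds of compounds. A synthetic beating-heart generator with analytic
ground truth makes every stage testable without microscope data.

## Segmentation model

**Heart ROI.** The temporal-maximum image is thresholded at an intensity
quantile (`primary_threshold_quantile`, default 0.90) and the bounding box
of the largest connected supra-threshold component, padded by `roi_pad`
pixels, becomes the region of interest. The quantile form assumes the
heart occupies well under 10% of the field of view, which holds for
plate-based whole-embryo imaging. The dim AV canal still exceeds this
threshold, so both chambers land in one component and one ROI. The ROI may
be rotated (degrees, about its center) before seeds are interpreted,
mirroring the rotate-then-draw order of interactive tools; multiples of
90° are exact, other angles use bilinear interpolation.

**Chambers.** The user supplies one seed polygon per chamber in ROI
coordinates (from the JSON sidecar; chamber identity is never inferred
from geometry). Within each frame's ROI a secondary threshold separates
chambers from the canal, the supra-threshold pixels are labeled into
connected components, and each chamber is the component maximally
overlapping its seed. If both seeds select one component — e.g. when the
canal is unusually bright — it is split by distance to the seed centroids,
with a warning. Masks are disjoint in every frame by construction.

Two numerical choices here deserve justification:

* *Range fraction, not quantile.* The secondary threshold is placed at a
  fraction (`secondary_threshold_frac`, default 0.60) of the within-ROI
  intensity range (robustified to the 0.1th/99.9th percentiles). An
  intensity *quantile* was tried first and rejected: the fraction of the
  ROI occupied by background swings by ~20 percentage points over the beat
  cycle as the chambers contract, so any fixed quantile crosses the
  canal/chamber intensity gap during the cycle and intermittently merges
  the chambers. A range fraction sits between canal and chamber intensity
  regardless of area fractions; it only requires the fraction to exceed
  the canal-to-chamber intensity ratio (~0.45 in our synthetic scenes).
* *Pre-threshold smoothing.* The ROI is smoothed with a small box filter
  (`smooth_radius`, default 1, i.e. 3×3) before thresholding. Without it,
  pixel noise at signal-to-noise ratio 5 punches enough holes into the
  chamber components to drop mask IoU against ground truth below 0.6; with
  it, IoU stays above 0.92 across the tested noise/contraction grid at the
  default threshold. The threshold is recomputed *per frame* so chamber
  borders track intensity fluctuation during contraction.

Chamber area per frame is the mask pixel count times the squared pixel
size (µm²).

## Heartbeat traces and frequency estimation

Each chamber's raw signal combines two per-frame measurements: the sum of
pixel intensities inside the mask, and the mask area. Each is detrended by
removing a least-squares line — photobleaching and focus drift otherwise
bias both frequency estimators — then min--max normalized to [0, 1]; the
combined signal is their mean. Min--max normalization (chosen over
divide-by-maximum) makes every frequency output invariant to rescaling all
intensities by a constant. A signal that is constant after detrending is
flagged, and downstream fits report failure instead of raising.

**Sine fit.** The model is $y(t) = A\sin(2\pi f t + \varphi) + c$. Thirty
candidate frequencies are spaced uniformly over
$[0.25, \min(6, f_s/2)]\,\mathrm{s^{-1}}$ — an increasing-frequency search
covering embryonic heart rates up to 360 beats/min without exceeding
Nyquist. For fixed $f$ the remaining parameters are linear and solved
exactly; each candidate is refined by a 1-D least-squares search within
one seed spacing. The winner maximizes the Pearson correlation between raw
and fitted signal (the `fit_score`). The whole procedure repeats on the
first quarter of the trace, and whichever fit scores higher on its own
support is kept (`used_truncated`), guarding against beats that
destabilize mid-recording; ties within numerical noise go to the
full-length fit. Fits scoring below `min_fit_score` (default 0.1) are
failure results, not exceptions.

**FFT.** The discrete Fourier transform of the mean-subtracted combined
signal; the frequency of the largest non-DC bin is reported. "First
harmonic" is read as the dominant non-DC component — literally taking bin
1 would always return 1/duration regardless of the signal. Resolution is
one bin, $f_s/n = 1/\mathrm{duration}$.

At frame rates of 9 f/s and above the sine estimate is preferred; at lower
rates (6 f/s screens) the sine search can alias and the FFT route is used.
The package reports both.

**Autocorrelation score.** A data-quality metric: the maximum, over lags
from 2 samples to half the trace, of the lag-$k$ autocorrelation with each
lag normalized by its two overlapping windows' energies (Pearson-style, so
a perfect periodic signal scores ~1 however many cycles the overlap
spans). A constant signal scores 0 by convention. The printed definition
of this score in the original tooling is not public; this convention is a
documented stand-in. Monte-Carlo calibration: white noise of length 60
scores below 0.5 in 98 of 100 fixed seeds (max ~0.6), clearly separated
from periodic signals (~1.0); the residual tail is inherent to a
max-over-lags statistic.

## Phenotypes

* **Heart size**: median of the first six frames' total (atrium +
  ventricle) area — a morphology estimate deliberately insensitive to how
  much of the beat cycle the recording covers.
* **Extremes**: maximal dilation and contraction are the 95th/5th
  percentiles of the area trace, not the literal min/max, so one glitched
  segmentation frame cannot dominate contractility.
* **Contractility**: absolute = dilation − contraction (µm²); relative =
  absolute / dilation × 100%.
* **Ejection fraction**: areas are converted to approximate volumes by the
  isotropic scaling $V \propto A^{3/2}$ (exponent configurable), giving
  $EF = 100\,(1 - (A_{ctr}/A_{dil})^{3/2})$. Since $1 - x^{3/2} \ge 1 - x$
  on (0, 1), EF always dominates relative contractility.
* **Arrhythmia score**: beats are peaks of the combined signal above
  mid-range with a minimum separation of half a beat period; the score is
  the coefficient of variation of inter-beat intervals (population SD over
  mean) scaled by 1/0.5 and capped at 1. Scores ≥ 0.7 are flagged. The
  population SD is used because the anchor example — intervals alternating
  0.3 s / 0.7 s giving CV 0.4 and score 0.8 — only holds with the
  n-denominator. Fewer than 3 beats give an indeterminate result.
* **Conduction score**: the atrium:ventricle frequency ratio is snapped to
  the nearest simple ratio (1:1, 2:1, 3:1, 3:2, 4:1 or inverses, relative
  tolerance 0.15); when snapping succeeds the score is the mismatch of the
  *snapped* ratio, $1 - \min(a,b)/\max(a,b)$, otherwise the raw mismatch,
  with ratio "irregular". Scores ≥ 0.5 flag a conduction defect; a flagged
  2:1 is annotated as Mobitz-II-like. Scoring the snapped ratio is
  deliberate: a true 2:1 block sits exactly at the 0.5 boundary, and
  scoring raw estimates would let estimation noise flip the flag on
  half the runs. The arrhythmia and conduction formulas are
  implementation-defined (only their 0.7/0.5 flag thresholds are anchored
  externally) and are documented as such.

## Brightfield module

Without fluorescence there are no chambers to segment; brightfield
contrast is motion. The temporal standard deviation of every pixel is
computed over all frames and the 10 highest-SD pixels (ties broken in
row-major order) are averaged into one trace — the SD-top-10 rule *is* the
automatic heart selection, with no separate region step. The trace then
goes through the same detrend/normalize/sine/FFT machinery; the reported
rate uses the FFT below 9 f/s and the sine fit otherwise.

## Screen statistics

Heart rates are divided by the mean of the DMSO control rows of the same
experiment (fold change), then z-scored with the sample (n−1) SD over all
compound fold changes of the screen — one screen-wide population rather
than per-plate, chosen for power and exposed as a design point. Hits are
|z| ≥ 1.64 (90% confidence, fewer false negatives) or 1.96 (95%); both
thresholds are the two-sided standard-normal critical values rounded to
two decimals, computed, not hard-coded.

The toxicity score for a treatment group of $n$ embryos is
$$\mathrm{ToxScore} = \frac{n_{edema}}{n} + \frac{n_{delay}}{n} +
\mathbf{1}\{|z_{HR}| \ge 1.64\} + \frac{2\,n_{arrest}}{n},$$
capped at 5; an embryo recorded as deceased and not intact is assigned the
maximal score 5 outright. The heart-rate term is an indicator at the 90%
band, consistent with the hit-calling threshold; the z-score is taken at
the compound level.

Validation correlations (e.g. automated vs manual rate counts) fit a
least-squares line, exclude points whose residual exceeds three residual
SDs, and report Pearson's r on the remainder together with the exclusion
count.

## The synthetic generator

`generate_heart_video()` renders two bright ellipses (atrium left,
ventricle right) on a dark canvas, joined by a canal band at a fraction
(default 0.45) of chamber intensity, with seeded Gaussian pixel noise.
Chamber areas follow $A(t) = A_0\,(1 - m\,(1+\sin(2\pi f t+\varphi))/2)$;
both ellipse axes scale by the square root of the area ratio so the
analytic area follows the waveform exactly, and ground truth (masks,
areas, frequencies, beat times) is read off the rendered geometry. Rhythm
modes: `regular`, `block_2to1` (ventricle at half the atrial rate),
`flutter` (atrium at ≥ 2× the ventricle with halved amplitude) and
`irregular` (log-normal jitter on beat intervals with a configurable CV).
Frequencies at or above Nyquist warn but render, so aliasing behavior can
be studied.

Defaults are the simulated study conditions and are not revisited
per-test: 2.5 s⁻¹ (150 beats/min) in both chambers, chamber areas 8,000
and 10,000 µm² with 40% area modulation, canal at 0.45 of chamber
intensity, chamber intensity 150 with noise SD 5 on an 8-bit-like scale,
6-second recordings at 30 f/s, 2.5 µm pixels, on a 220×160 canvas. These
match a 2-dpf embryo imaged for a screen: heart rate ~150 beats/min,
whole-heart area ~1.2×10⁴ µm², and a heart occupying well under 10% of
the field so that quantile ROI detection behaves as it does on plate
imagers. Property suites vary frequency (0.5–4 s⁻¹), noise (SNR ≥ 3) and
frame rate (6 and 10 f/s) around these conditions; bulk suites run 6 s at
10 f/s (60 frames per video, 100 videos per property) to keep a full test
run within minutes on one CPU.

What the generator does *not* emulate — and therefore what passing tests
cannot show — includes: optical point-spread and depth blur, occlusion by
pigment or yolk, heart looping geometry (chambers are axis-aligned
ellipses), intensity bleed between overlapping chambers, motion of the
whole embryo, and photobleaching beyond a linear trend. Real recordings
will need seed polygons drawn by a user and may need the threshold
fraction adjusted to their canal brightness.

`generate_bf_video()` renders the brightfield analogue: a bright,
statically textured background with a small dark pulsing region.
`generate_screen_dataset()` draws per-embryo heart rates around
per-experiment control means (160 ± 8 beats/min per embryo, experiment
shifts SD 4) with a chosen fraction of compounds spiked by a chosen number
of fold-change SDs, returning the true hit labels alongside.

## Degenerate inputs and edge policies

* Fewer than 6 frames: refused at load (morphology needs six).
* Constant traces: flagged; sine fit returns a failure result; FFT returns
  `NA`; autocorrelation returns 0; the results sheet writes empty cells.
* Flat intensity range in the animation: mapped to a single mid-LUT color,
  outlines still drawn.
* Trimming is anchored at the start of the recording (the original
  acquisition order is the more trustworthy end).
* Seed polygons outside the ROI, chambers without a supra-threshold
  component in more than half the frames, and stacks with mixed frame
  sizes raise typed errors naming the offender.

## Known limitations

* Masks under a non-multiple-of-90° rotation are reported in rotated-ROI
  space embedded at the ROI's frame location; areas and traces are
  unaffected, but overlays on the original frames are approximate.
* Video containers (AVI/MP4) are not read; recordings must be supplied as
  TIFF/PNG series (one file per frame, numerically ordered) or multi-page
  TIFFs.
* The arrhythmia/conduction score formulas are stand-ins with externally
  anchored flag thresholds; absolute score values should not be compared
  across tools, only across fish analyzed with this package.
* Ejection fraction rests on the $A^{3/2}$ volume approximation, which
  assumes isotropic chamber shape change.
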