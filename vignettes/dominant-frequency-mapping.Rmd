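---
title: "Dominant-frequency mapping of atrial and body-surface signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-frequency mapping of atrial and body-surface signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdfmap)
```

## The problem

During atrial fibrillation (AF) the atria sustain rapid, spatially
heterogeneous activation at fibrillatory rates of roughly 4–10 Hz. A
channel's *dominant frequency* (DF) — the frequency of maximum spectral
power in that band — is a widely used surrogate for the local activation
rate, and regions hosting the *highest* DF (HDF) are candidate AF
drivers and ablation targets. Two recording modalities see this activity
very differently. Endocardial (virtual) electrograms sample the atrial
surface node by node; body-surface mapping (BSM) electrodes see every
atrial source at once through the torso volume conductor, which acts as
a spatial low-pass: the contribution of a small, fast source is averaged
away against the large, slower background, so torso-side HDF estimates
are biased downward relative to the endocardium, and increasingly so the
faster the driver. `afdfmap` implements the complete analysis that
quantifies this effect — per-window spectra, DF/HDF maps, organization
index (OI) thresholding, paired BSM−endocardial HDF differences — plus a
synthetic source-and-volume-conductor simulator that makes every stage
verifiable against known ground truth.

## Signal model and processing chain

An analysis run takes two time-aligned multichannel recordings (roles
`atrial-node` and `torso-electrode`, plus a shared `reference-ecg`
lead) and proceeds:

1. **Resampling** to a common rate (512 Hz default) by polyphase
   rational resampling with an anti-aliasing FIR, so acquisition rates
   such as 2048, 1200 or 2034.5 Hz land on one timeline.
2. **Band-pass filtering** 2–50 Hz with a zero-phase moving-average
   cascade (below).
3. **Channel QC**: any channel whose full-record power within
   mains ± 0.5 Hz exceeds 0.5% of total spectral power is flagged
   invalid and excluded from analysis.
4. **Alignment** of the two streams by the lag maximizing the
   normalized cross-correlation of the shared ECG lead; the run aborts
   if the peak correlation is below 0.5.
5. **QRS-T cancellation**: R peaks are detected on the reference lead;
   for each channel the average beat over all annotated spans
   (100 ms before to 450 ms after the R peak) is subtracted at every
   beat, with 20 ms cosine-tapered template edges so no step
   discontinuities inject broadband power.
6. **Spectral metrics** per channel per 4 s window (50% overlap):
   Welch spectrum, DF, peak power, OI, F-ratio significance, harmonic
   classification.
7. **HDF mapping and comparison**: per-window HDF and hosting areas at
   every OI threshold, harmonic window exclusion, paired BSM−VEGM
   differences with 0.5 Hz binning, exponential curve fit, and
   HDF-area distribution comparison.

## Spectral estimation

Each 4 s window receives its own spectrum on a zero-padded grid with
exactly 0.05 Hz spacing (transform length `fs / 0.05`, i.e. 10240
points at 512 Hz). Two estimators are available and share the grid:

* `welch` (default): the window is split into three Hamming-tapered
  2 s sub-segments at 50% overlap and their periodograms averaged —
  lower variance, slightly wider peaks;
* `fft`: a single Hamming-tapered periodogram of the whole window —
  higher resolution, higher variance.

The DF is the arg-max of power in the closed 4–10 Hz band, ties broken
toward the lower frequency so results are deterministic.

### Organization index

For a one-sided spectrum $Y[f]$ the OI is

$$\mathrm{OI} \;=\;
\frac{\sum_{|f-f_\mathrm{DF}|\le k} Y[f]\;+\;
      \sum_{n\ge 2}\,\sum_{|f-nf_\mathrm{DF}|\le k} Y[f]}
     {\sum_{f_l \le f \le f_h} Y[f]},$$

with half-width $k = 0.375$ Hz, band $f_l = 0$, $f_h = 20$ Hz, and
harmonic windows included only while $nf_\mathrm{DF} + k \le f_h$. Bins
covered by more than one window are counted once, so
$0 \le \mathrm{OI} \le 1$ holds structurally. The OI measures how much
of the spectral area is concentrated at the DF and its harmonics: a
highly periodic signal approaches 1, broadband activity approaches the
ratio of window width to band width (0.1125 for a flat spectrum with a
6 Hz DF). Harmonic windows sit at exact integer multiples of the DF;
re-centering each on the local power maximum within $\pm k$ is available
via `refine_harmonics = TRUE`.

### F-ratio peak test and harmonic classification

A DF peak can be a harmonic of slower activity rather than genuine
fibrillatory rate. Each peak is therefore tested by the ratio of its
power to the mean power of 10 neighboring frequencies on each side
(21 frequencies in all), referred to the upper 5% point of the F
distribution with 2 and 2(F−1) = 40 degrees of freedom — critical value
3.23, computed from `qf()` rather than hard-coded. Zero-padded 0.05 Hz
bins are strongly correlated, which would break the independence
assumption behind that reference distribution, so neighbors are sampled
at the native pre-padding resolution (1/window length = 0.25 Hz)
by default; `neighbor_spacing = bin_width` restores contiguous padded
bins for sensitivity analyses.

When the test fails, the peak is checked against stronger candidate
fundamentals below it: the strongest frequency in [1 Hz, peak) flags a
possible ventricular (cardiac-cycle) harmonic, the strongest in
[4 Hz, peak) a harmonic of a slower fibrillatory driver. A candidate
$g$ qualifies when the peak lies within $k$ of an integer multiple
$n g$, $n \ge 2$, and $g$ carries at least the peak's power. The
classification rule is a documented package choice: the criterion the
original clinical analysis used is not fully specified anywhere we
could verify, so the minimal rule consistent with the two search ranges
is implemented and exposed.

## HDF mapping and the paired comparison

Within one window and one dataset, channels with OI strictly above the
threshold are eligible; the HDF is their maximum DF and the hosting
area is every eligible channel with DF within 0.25 Hz below it. With no
eligible channel the window's HDF is undefined. Windows in which either
dataset's HDF-hosting peak was classified as a possible harmonic are
excluded from the paired analysis.

The OI threshold sweep (grid 0–1, step 0.1) reports per threshold the
percentage of windows with a defined HDF — with two denominators, all
analyzable windows and windows surviving harmonic exclusion, since both
framings are useful — and, at a chosen comparison threshold (default
0.5, halfway between the OI extremes), the per-window set arithmetic
against the unthresholded hosting sets: percentage of nodes hosting,
percentage persisting ($100\,|B\cap A|/|B|$) and percentage new
($100\,|A\setminus B|/|A|$), summarized as median and interquartile
range across windows.

Paired differences (BSM HDF − VEGM HDF) are grouped into 0.5 Hz bins of
the endocardial HDF with half-open edges $[x.0, x.5)$ on integer and
half-integer hertz (centers at x.25/x.75), and the per-bin medians are
fitted with

$$d(f) = -a\,e^{b\,(f - f_0)} + c,$$

$f_0$ fixed at the lowest bin center, by Levenberg–Marquardt nonlinear
least squares (`minpack.lm::nlsLM`), with starting values from a
log-linearization of $c - d$ and a deterministic ladder of rescaled
restarts. The functional form is a package choice — an exponentially
growing downward deviation captures a flat-then-decaying negative
difference — and is reported alongside asymptotic 95% confidence
intervals and $R^2$ against the bin medians. Constant medians take an
explicit degenerate branch (constant model, $b = 0$). Rank tests for
the HDF-area distribution comparison are delegated to
`stats::wilcox.test`.

## The band-pass filter

The published processing chain calls for a 2–50 Hz moving-average
band-pass without stating its order or direction. The implementation is
a zero-phase cascade of centered moving averages: a short window of
`round(fs/high)` samples (low-pass) followed by subtraction of the
running baseline estimated with a long window of `round(fs/low)`
samples. Both stages are symmetric FIRs, so the cascade has exactly
zero group delay — window indices stay aligned across the two streams —
and its measured response at 512 Hz (11 and 257 sample windows) passes
6 Hz within 0.3 dB, removes DC completely, and attenuates 150 Hz by
more than 22 dB; the measured −3 dB points sit at about 1.6 and
20.2 Hz, with the 4–10 Hz analysis band comfortably inside. The
response is obtained by FFT of the filter's impulse response — the same
measurement the test suite performs — rather than assumed. Note the
upper −3 dB point is well below the nominal 50 Hz corner: a
moving-average low-pass rolls off early, which is a property of the
filter family itself, and is harmless here because everything the
analysis consumes lives below 20 Hz.

## The synthetic generator

`synthetic_scenario()` encodes the study conditions the analysis
assumes, with full ground truth:

| Parameter | Default | Meaning |
|---|---|---|
| `n_atrial_nodes` | 256 | nodes on a 70° unit-sphere cap |
| `n_torso_electrodes` | 64 | electrodes on a radius-2.5 shell |
| `background_freq` | 6.0 Hz | large-area background rate |
| `driver_freq` | 9.0 Hz | compact fast driver rate |
| `driver_area_frac` | 0.05 | fraction of nodes in the driver patch |
| `harmonic_amps` | 1, 0.4, 0.15 | source harmonic series |
| `leadfield_exponent` | 2 | inverse-distance weight power |
| `leadfield_smoothing` | 0.3 | spatial blur radius (unit-sphere units) |
| `ventricular_rate` | 1.0 Hz | mean beat rate of the far field |
| `rr_jitter_s` | 0.05 s | RR-interval jitter (see below) |
| `noise_sigma` | 0.05 | white-noise SD vs unit sources |
| `mains_amp` | 0.02 | 50 Hz contamination amplitude |
| `freq_jitter` | 0.02 Hz | slow cycle-length modulation depth |
| `duration_s`, `fs` | 60 s, 512 Hz | recording geometry |

Each node emits a harmonic-series oscillator at its assigned rate with
a smooth spatial phase gradient, small seeded phase scatter and slow
frequency modulation — the spectral structure (dominant fundamental
plus decaying harmonics) that the OI presumes, with exact ground truth,
rather than a biophysical action-potential model. The volume conductor
is a memoryless linear mixing matrix: inverse-distance weights,
row-normalized, then blurred over each node's spatial neighborhood.
That is deliberately the *mechanism* under study in its purest form —
frequency damping of small fast areas arises from spatial averaging
alone, with no temporal filtering — so the direction and growth of the
BSM−VEGM difference follow from the geometry, not from a tuned filter.

The ventricular far field is a stylized shared QRS-T train with
per-channel amplitudes and a clean appended reference lead. Its RR
intervals are jittered (`rr_jitter_s`) because fibrillation conducts
irregularly to the ventricles; an exactly periodic train phase-locked
to the atrial background (1.0 Hz against 6.0 Hz is exactly 6 cycles per
beat) would let average-beat cancellation absorb coherent atrial signal
— a pathology of the synthetic setup, not of the method.

What the generator does **not** emulate: fibrillatory conduction
(rotors, wavebreak, meander), anatomically realistic torso/atrial
geometry, frequency-dependent tissue conduction, inverse-solution
artifacts of real virtual electrograms, electrode contact noise, or
baseline wander. Passing tests therefore demonstrate that the analysis
chain is correct and that spatial averaging alone produces the
torso-side HDF bias — not that clinical recordings will show any
particular effect size.

## Numerical choices and degenerate inputs

* DF ties break toward the lower frequency; window enumeration drops a
  trailing partial window; a recording shorter than one window yields
  an empty (warned) result rather than an error.
* OI masks use a 1 ns-scale floating tolerance (1e−9 Hz) when
  comparing grid frequencies to window edges, so bin membership never
  depends on floating-point representation.
* A zero-power OI band raises an explicit undefined-OI error; an empty
  eligible set yields an undefined HDF with reason
  `no-node-above-threshold`; fewer than 3 beats skips cancellation
  with a warning and passes the signal through.
* F-ratio neighbors extending past the grid edge are truncated with a
  warning and the count adjusted.
* All simulator randomness derives from the scenario seed through
  stage-specific offsets; the global RNG state is saved and restored,
  and identical configurations reproduce byte-identical artifacts
  (hashed into every run report with `rlang::hash`).

## Problem sizes

The shipped test suite and the acceptance script run scaled-down
scenarios chosen as the smallest sizes at which every qualitative
property is stable: 48–64 atrial nodes, 24–32 electrodes, 12–30 s
recordings (9–14 analysis windows), against the 256-node, 64-electrode,
60 s defaults. The driver-frequency sweep {6.5, 7.5, 8.5, 9.5} Hz with
a 5% driver patch reproduces, at these sizes, a non-positive median
BSM−VEGM HDF difference whose magnitude grows with the driver rate —
the central volume-conductor signature — and noiseless runs recover the
driver frequency to within one 0.05 Hz bin in every window.

## Known limitations

* The harmonic-classification rule and the exponential model form are
  documented package choices (see above); parameter estimates from the
  exponential fit are therefore comparable only within this package.
* The F-test reference distribution assumes independent neighbor bins;
  the native-resolution spacing is an approximation to that, not a
  guarantee.
* The EDF/BDF reader covers the common fixed-rate case (identical
  sampling rate on all signals, no annotation channels).
* Body-surface OI values from the simulator are systematically lower
  than endocardial ones, so OI thresholds calibrated on one modality
  should not be transferred to the other — on real data or synthetic.
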