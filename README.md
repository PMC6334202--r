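# afdfmap — dominant-frequency mapping of atrial and body-surface signals

`afdfmap` is an R package for spectral analysis of multichannel cardiac
recordings in atrial fibrillation (AF). It is written for
electrophysiology signal-processing researchers who want to compare
fibrillatory rate estimates taken simultaneously on the atrial
endocardium (virtual electrograms, VEGMs) and on the torso surface
(body-surface mapping, BSM), and to study how the torso volume
conductor and the analysis parameters shape the non-invasive estimate.

## The science in brief

For each channel and each 4 s analysis window (50% overlap) the package
computes a Welch power spectrum on an exact 0.05 Hz zero-padded grid
and derives:

* **Dominant frequency (DF)** — the frequency of maximum power in the
  4–10 Hz fibrillatory band (ties break low).
* **Organization index (OI)** — with DF window half-width k = 0.375 Hz
  and band 0–20 Hz,

  $$\mathrm{OI}=\frac{\sum_{|f-f_{DF}|\le k}Y[f]+\sum_{n\ge2}\sum_{|f-nf_{DF}|\le k}Y[f]}{\sum_{0\le f\le 20}Y[f]},$$

  the fraction of spectral area under the DF and its harmonics —
  a measure of how dominant (organized) the periodicity is.
* **F-ratio peak test** — peak power over the mean of 10 neighboring
  frequencies each side, significant above the F(2, 40) upper-5% point
  (3.23); non-significant peaks are screened as possible harmonics of
  a slower cardiac or fibrillatory rate and the window excluded.
* **Highest DF (HDF)** — per window and dataset, the maximum DF over
  channels whose OI exceeds a threshold; channels within 0.25 Hz below
  it form the HDF-hosting area.

Paired (BSM HDF − VEGM HDF) differences are binned by the endocardial
HDF in 0.5 Hz bins and the bin medians fitted with an exponential decay
d(f) = −a·exp(b·(f−f₀)) + c by Levenberg–Marquardt. The package also
ships a synthetic generator — harmonic-series atrial sources with a
compact fast driver patch, an inverse-distance volume-conductor
projection, a jittered ventricular far field, mains and white noise —
with full ground truth, so the whole chain is testable without patient
data.

## Worked example

Simulate a 30 s scenario with a 9 Hz driver occupying 5% of a 6 Hz
background atrium, and run the full pipeline:

```r
library(afdfmap)
scn <- synthetic_scenario(n_atrial_nodes = 64, n_torso_electrodes = 32,
                          duration_s = 30, driver_freq = 9, seed = 42)
res <- run_pipeline(pipeline_config(scenario = scn))
print(res)
#> <pipeline_result>
#>   windows paired: 14 (included at OI 0: 14)
#>   median BSM - VEGM HDF difference (OI 0): -3.00 Hz
#>   config ba3364d9a5e9cb890fbe0c973b4c2d20, seed 42
res$diff0$bins
#>   bin_center median q25 q75  n
#> 1       9.25     -3  -3  -3 14
```

Every endocardial window finds the 9 Hz driver (HDF bin centered
9.25 Hz), while the body surface reports the 6 Hz background: the small
fast patch is averaged away by the volume conductor, giving the
−3.00 Hz median difference. The OI threshold sweep shows the
endocardial HDF is defined in 100% of windows up to an OI threshold of
0.8 and in none above 0.9:

```r
res$sweep_vegm$curve[, 1:2]
#>    threshold pct_windows_defined
#> 1        0.0                 100
#> ...
#> 9        0.8                 100
#> 10       0.9                   0
```

`run_pipeline(pipeline_config(..., out_dir = "out"))` additionally
writes tidy CSV tables (per-channel DF metrics, HDF pairings, threshold
sweeps, difference bins) and a JSON run report stamped with a
configuration hash and the seed. The same analysis runs on recorded
data via `load_recording()` (delimited matrix + YAML sidecar, or
EDF/BDF), and `scripts/run_pipeline.R` wraps everything for shell use.

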