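# bowcoord

Coordination analysis of fast repetitive violin-bowing patterns.

Rapid string-crossing passages require a violinist to coordinate two
oscillatory components of the bowing movement: bow velocity *v(t)*, which
reverses at every bow change, and bow inclination *θ(t)*, which selects the
string. Because bow hair and strings are compliant, a string crossing spans a
finite inclination band of half-width *w* in which the total bow force is
cross-faded between the strings. Two dimensionless parameters locate a
coordination strategy in this model:

* **relative phase** Δφ — the phase lead of bow inclination over bow
  velocity, positive when the string crossing precedes the bow change;
* **normalized range** r = 2w / P — the band width divided by the
  peak-to-peak inclination extent P.

A bow change falls inside the crossing band exactly when |Δφ| ≤ arcsin(r),
which bounds the "within-band" region of the two-dimensional coordination
space (Δφ, r). A third parameter, the inclination offset θ_offset, shifts the
movement relative to the band center.

The package is aimed at movement scientists studying intralimb coordination
in skilled motor behavior. It provides:

* a forward **simulator** of the coordination model (circular CW/ACW patterns
  and the 2:1 figure-of-eight, phase jitter, center wander, measurement
  noise, triangular inclination shapes, the 20-condition experimental grid);
* **preprocessing** — zero-phase Butterworth filtering and differentiation;
* two estimator families for Δφ and r: **Hilbert-based** (analytic-signal
  continuous relative phase) and **time-domain** (sub-sample bow-change and
  band-crossing timing), implemented independently so that they can
  cross-validate each other;
* per-bow-change **feature extraction** with missing-value reason codes;
* **coordination-space geometry** (boundary curve, inside/outside
  classification, 68 %-coverage ellipses, percentile summaries);
* the **two-step aggregation** (per transition, then unweighted across
  transitions) to per-condition summaries, plus tidy export for external
  inferential statistics.

See `vignettes/coordination-analysis.Rmd` for the methods account.

## Worked example

Simulate a clockwise pattern at 92 bpm with ground truth Δφ = 15°, r = 0.32,
2° per-half-cycle phase jitter and 30 dB measurement noise, then extract and
summarize features:

```r
library(bowcoord)

cfg <- bowing_config(pattern = "CW", tempo_bpm = 92, n_bars = 6,
                     delta_phi_deg = 15, r_norm = 0.32,
                     cycle_jitter_sd_deg = 2,
                     noise_sd = c(velocity = snr_noise_sd(0.8, 30),
                                  inclination = snr_noise_sd(5, 30)),
                     seed = 42)
ts <- generate_pattern(cfg)
ts
#> <bowing_series> CW at 92 bpm, 2817 samples @ 240 Hz (11.73 s)

feats <- extract_features(ts)   # 72 bow changes, first/last beat discarded
nrow(feats)
#> [1] 64

summarize_condition(feats, metadata = list(participant = "SYN1"))
#>                 feature     mean      sd n_transitions n_events participant
#> 1 delta_phi_hilbert_deg 1.53e+01 4.11079             2       64        SYN1
#> 2    delta_phi_time_deg 1.50e+01 2.31137             2       64        SYN1
#> 3                 r_amp 3.20e-01 0.00181             2       64        SYN1
#> 4                r_time 3.19e-01 0.00938             2       64        SYN1
#> 5      theta_offset_deg 5.71e-04 0.14041             2       64        SYN1
```

Both estimator families recover the configured truth (15° and 0.32) within
noise; the `sd` column is the across-transition average of the
per-transition standard deviations, the stability metric. Distribution and
geometry summaries:

```r
s <- distribution_summary(feats$delta_phi_hilbert_deg)
#> median 15.1 deg, 10-90% range [10.4, 20.5]

boundary_phase(0.32)      # 18.7 deg
classify_inside(15, 0.32) # TRUE: bow changes fall inside the crossing band
```

A command-line interface is installed at
`system.file("cli", "bowcoord", package = "bowcoord")`:

```sh
bowcoord simulate --pattern CW --tempo 92 --phase 15 --range 0.32 --seed 1 -o series.csv
bowcoord extract -i series.csv -o features.csv
bowcoord summarize -i features.csv --group pattern -o summary.csv
```

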