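---
title: "Methods: coordination analysis of fast repetitive bowing patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordination analysis of fast repetitive bowing patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowcoord)
```

## The model

Fast repetitive bowing patterns on the violin combine two oscillatory
components of the bowing movement: bow velocity $v(t)$, which reverses sign at
every bow change, and bow inclination $\theta(t)$, the angular coordinate that
selects the string. Because bow hair and strings are compliant, a string
crossing is not instantaneous: there is a finite inclination band of half-width
$w$ around the crossing center in which the bow touches both strings and the
constant total bow force $F$ is transferred from one string to the other in a
cross-fade-like manner.

`bowcoord` implements a simplified generative model of this behavior in which
both $v$ and $\theta$ are sinusoids. Two dimensionless parameters locate a
coordination strategy:

* the **relative phase** $\Delta\varphi$, the phase lead of bow inclination
  over bow velocity, positive when the band-center crossing precedes the bow
  change (expressed in degrees of the velocity cycle);
* the **normalized range** $r = 2w / P$, the full band width divided by the
  peak-to-peak inclination extent $P$.

A third parameter, the **inclination offset** $\theta_{\text{offset}}$,
displaces the oscillation center from the band center and breaks the symmetry
between the two transition directions.

Under the sinusoidal model a bow change falls inside the crossing band exactly
when $|\Delta\varphi| \le \arcsin r$; this curve bounds the "within-band"
region of the two-dimensional coordination space $(\Delta\varphi, r)$
implemented in `boundary_phase()` and `classify_inside()`. The boundary
formula is *not* assumed in the tests: it is checked cell by cell against a
forward-simulation oracle that measures the force split at the bow change.

Three patterns are supported. The circular patterns CW and ACW have equal
velocity and inclination frequencies with a spatial quadrature of $+90°$
(CW) or $-90°$ (ACW). The figure-of-eight (Fo8) has a 2:1 frequency
relation — the inclination period is twice the velocity period — so that only
every second bow change coincides with a string crossing.

## Frequencies and the condition grid

Patterns are notated in sixteenth notes, so at tempo $b$ bpm the note rate is
$4b/60$ notes/s and the circular movement frequency is half of that. The four
metronome tempi 58, 72, 92 and 112 bpm give note rates of 3.87, 4.80, 6.13 and
7.47 notes/s, conventionally printed as 3.9/4.8/6.1/7.5, with circular
movement frequencies printed as half the rounded note rate (1.95/2.4/3.05/3.75
Hz). The generator always uses the exact values; the rounded ones appear only
in reporting. `frbp_conditions()` enumerates the 20 controlled conditions
(2 dynamic-level blocks of 4 conditions, 4 tempo blocks of 3), and
`generate_protocol_sequence()` renders one condition as six seamlessly
repeated 12-note bars — 72 notes. The dynamic-level conditions are notated
"92–112 bpm, free tempo"; the generator needs a single number and uses the
midpoint 102 bpm, keeping the label in the metadata.

## The synthetic generator: what it emulates, and what not

`generate_pattern()` is a forward simulator of the model above, with the
departures from ideality that the estimators must tolerate:

* **per-half-cycle phase jitter** (`cycle_jitter_sd_deg`): Gaussian jitter of
  the inclination phase, interpolated piecewise-linearly between half-cycle
  anchors so channels stay continuous. This makes per-transition feature
  standard deviations nonzero, which stability metrics need.
* **inclination-center wander** (`offset_jitter_sd_deg`): slow Gaussian drift
  of the oscillation center, the error source that differentially inflates the
  variance of the time-domain phase estimate (see below).
* **additive white measurement noise** per channel. `snr_noise_sd()` converts
  a target SNR in dB into a noise standard deviation; the recovery tests use
  30 dB, a realistic level for optical motion capture after rigid-body
  averaging.
* **rounded-triangular inclination** (`incl_shape = "triangular_rounded"`): a
  triangle wave convolved with a Gaussian kernel whose width defaults to 5 %
  of the inclination period, emulating the linearly changing inclination with
  rounded inversions seen in slow figures-of-eight.

Defaults describe a comfortable fast-forte circular pattern: 92 bpm,
$\Delta\varphi = 15°$, $r = 0.32$ (the center of typically observed
strategies), $P = 10°$, bow-velocity amplitude 0.8 m/s, bow force 0.9 N.
The band half-width is derived as $w = r\,P/2$, so the configured $r$ *is*
the amplitude-based normalized range in the noise-free case. The dynamic-level
presets couple band width to bow force ($w \propto F$): the piano preset
halves force and hence band width, and scales velocity amplitude by 0.6. The
physical string-compliance model that maps force and bow-bridge distance to
band width on a real instrument is deliberately not implemented; the band
width is a direct model input.

The generator does **not** emulate: drift of tempo, force fluctuation within a
stroke, bow-bridge-distance dynamics, marker occlusion artifacts, or any
biomechanics. A green recovery test therefore establishes that the estimator
chain is unbiased and precise *under the stated model*, not that it is robust
to everything real motion-capture data can do.

Sign conventions (the model is agnostic; one choice is fixed and documented):
down-bow velocity is positive, inclination increases toward the higher-pitched
string, and the band center sits at inclination 0 by default.

## Preprocessing

All channels are filtered with zero-phase (forward–backward) Butterworth
low-passes: bow velocity at 30 Hz (2nd order), the band-width channel at 48 Hz
(2nd order), and angular velocity — the central-difference derivative of
inclination — again at 30 Hz. The forward–backward application doubles the
effective order and cancels phase lag exactly, which matters because every
feature is a *timing* measurement. The filter kernel is implemented
in-package (Butterworth poles via the bilinear transform with pre-warping) and
is validated in the tests against the analytic magnitude response; edges use
an odd (point-reflected) extension of three filter lengths, and the filter
state is referenced to the starting level so constant offsets pass through
exactly.

## Two estimator families

**Hilbert-based.** `continuous_phase()` takes the unwrapped phase of the FFT
analytic signal; velocity-domain signals (bow velocity, angular velocity) are
used because they are naturally zero-centered. `relative_phase()` subtracts
the two phases; for Fo8 the velocity phase is first halved to compensate the
2:1 frequency relation and the result is doubled back so all patterns share
the velocity-cycle scale. The nominal quadrature offset — the nearest integer
multiple of 90°, which is $+90°$, $-90°$ and $0°$ for CW, ACW and Fo8 — is
subtracted from a robust central estimate (median of the middle 80 % of
samples) so the series is referenced to zero. This re-referencing is
idempotent. Half a movement cycle at each end of the record is unreliable due
to analytic-signal edge effects; the first/last-beat trimming of the feature
table covers this.

**Time-domain.** Bow changes are zero crossings of filtered velocity with
sub-sample linear interpolation (`detect_bow_changes()`). The time-domain
relative phase is $\Delta\varphi_t = 360° \,(t_{bc} - t_c)/T$, where $t_c$ is
the band-center crossing belonging to the transition and $T$ the local full
velocity cycle (time between the same-direction bow changes bracketing the
event). The time-domain normalized range inverts the sinusoidal crossing-time
relation, $r_t = \sin(\pi\,\Delta t/T_\theta)$, where $\Delta t$ is the time
spent inside the band and $T_\theta$ the *inclination* cycle. Both formulas
are validated against closed-form oracles (a sinusoid of period $T$ spends
$T \arcsin(r)/\pi$ inside a band of normalized range $r$).

Two normalization choices deserve a note, because the patterns disagree about
what "one cycle" means:

* $\Delta\varphi_t$ always uses the **velocity** cycle, for comparability with
  the doubled Hilbert convention in Fo8;
* $r_t$ always uses the **inclination** cycle ($2T$ for Fo8), because it is a
  geometric property of the inclination movement; with the velocity cycle the
  Fo8 value would not estimate $r$.

A band-center crossing is paired with a bow change only if it falls within a
quarter cycle; beyond that it belongs to a neighboring transition. This is
what makes the two non-crossing bow changes per Fo8 cycle come out as missing
(`no_crossing`) rather than picking up a meaningless half-cycle-away crossing.
Missing features always carry a reason code and are never silently dropped.

## The figure-of-eight pathology

When the inclination is triangular rather than sinusoidal, its derivative is
nearly a square wave and the analytic-signal phase fluctuates strongly within
each cycle. Sampled at the bow changes — half of which sit at the square
wave's transitions — the Hilbert estimate acquires a large systematic
inflation while the time-domain estimate, which only uses crossing times, is
unaffected. With the default 5 % rounding the inflation is mild (~15 % at
$\Delta\varphi = 20°$); as the triangle sharpens the ratio of the two
estimates approaches two. This is reproduced as an acceptance criterion, at
$\Delta\varphi = 20°$, a representative slow-tempo figure-of-eight value (the
inflation is roughly additive, so the ratio depends on the operating point).
In such conditions the time-domain estimate is the one to trust.

A converse effect explains the variance side: when the inclination center
wanders by a fixed angular amount and the inclination amplitude shrinks with
tempo (amplitudes are constrained at speed), the induced timing error of $t_c$
is constant while the cycle it is normalized by shrinks — so the variance of
$\Delta\varphi_t$ inflates relative to the Hilbert estimate at high tempo.
The property test constructs exactly this scenario.

## Aggregation

`summarize_condition()` follows a strict two-step scheme: means and standard
deviations are computed per *transition* (2 per cycle for circular patterns, 4
for Fo8, keyed by position within the pattern cycle), then averaged across
transitions **unweighted**. This is not the pooled statistic: transitions with
unequal event counts contribute equally, which keeps asymmetric transitions
(e.g. under an inclination offset) from being swamped. Transitions with no
valid events are excluded and counted. `export_tidy()` melts summaries into
one row per participant × condition × feature × statistic for external
mixed-design ANOVA tools; inferential statistics are deliberately out of
scope.

`coverage_ellipse()` honors its coverage claim: the mean/covariance ellipse is
scaled by $\sqrt{\chi^2_{2}(p)}$ so that the requested fraction $p$ (default
0.68) of a bivariate normal falls inside — a plain 1-SD Mahalanobis ellipse
would cover only ~39 %. Percentiles in `distribution_summary()` interpolate
linearly between order statistics (R's type-7 definition).

## Numerical choices and degenerate inputs

* Zero crossings: linear interpolation between bracketing samples; an
  exactly-zero sample is an event at that sample's time; tangencies (zero
  runs with equal flanking signs) are not events.
* Cycle duration at segment edges falls back to the nearest available full
  cycle; fewer than three bow changes is an error.
* `time_domain_range()` rejects $\Delta t > T/2$ (inconsistent with the
  sinusoidal model); inside the pipeline such events become missing rather
  than aborting the table.
* The all-zero signal has no phase (error); degenerate covariance (collinear
  or identical points) is an error naming the deficiency.
* Filters reject NaN inputs naming the first offending index, and cutoffs at
  or above Nyquist.

## Known limitations

* The generator's jitter model is phenomenological; it produces realistic
  feature dispersions but not the autocorrelation structure of real motor
  variability.
* The Hilbert estimator assumes quasi-sinusoidal, narrow-band signals; the
  package reproduces its failure mode for triangular inclination but does not
  attempt to correct it.
* Fo8 transition indexing assumes the note pattern starts at the beginning of
  a pattern cycle, as the protocol generator guarantees; externally supplied
  recordings with pickup notes would need re-indexing.
* Condition summaries mirror a per-participant × condition feature table; no
  between-participant inference is provided or implied.
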