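---
title: "Aligning two-device ECG clocks by amplitude cross-correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning two-device ECG clocks by amplitude cross-correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsync)
```

## The problem

Wearable devices that record the same signal type — here a wrist-watch-style
ECG resembling clinical Lead I and a chest-patch-style ECG resembling Lead
V2 — rarely share a clock. When a short "spot check" sample from one device
must be located inside a longer recording from the other, the estimator of
choice is the simplest one available: slide the short *reference* sample
across the longer *search* sample one sample at a time, compute a
correlation at every integer lag, and report the lag of the correlation
peak. Because it works directly on amplitudes, the estimator needs no beat
detection, landmarks or learned encodings, and transfers unchanged to any
common signal type.

The package implements that estimator together with everything needed to
study it end to end: the preprocessing chain, a beat-level signal-quality
index, a calibrated noise-stress harness, a dynamic-time-warping baseline,
and a synthetic two-lead ECG generator that provides ground-truth lags.

## The estimator

With a reference $x$ of $n$ samples and a search signal $y$ of $N \ge n$
samples at a common rate $f_s$, the package computes, for every integer lag
$k \in \{0, \dots, N-n\}$,

$$ r_k = \mathrm{corr}\!\left(x,\; y_{k+1..k+n}\right), $$

and reports $\hat\tau = \arg\max_k r_k / f_s$. Two per-lag statistics are
available: the Pearson coefficient (`mode = "pearson"`, the default) and the
plain inner product (`mode = "raw"`, the unnormalized cross-correlation
convention of common signal-processing toolboxes). The Pearson form is the
default because it is invariant to the per-window mean and scale, which makes
the curve comparable across lags; the raw form is kept for parity with
toolbox output. Only full-overlap ("valid") lags are scored: zero-padded
edge products produce spurious maxima and the sampling design guarantees the
true lag lies inside the valid range. Ties break toward the smallest lag so
results are deterministic.

The implementation uses one FFT cross-correlation plus cumulative window
sums, and is pinned by tests to a brute-force per-lag loop at $10^{-10}$.

### Sample geometry and the sync-delay metric

A sample pair consists of an $m$-second reference and a search sample
covering the same span plus a `margin` (default 30 s) of context on each
side, so the search is $2\cdot\mathrm{margin}$ seconds longer and the true
lag equals `margin` by construction. The *sync delay* — the absolute
difference between estimated and true lag — is the performance metric
throughout. Its maximum detectable value equals the margin.

## Preprocessing

Three steps, in fixed order:

1. **Resampling to a working rate** (default 250 Hz). A polyphase rational
   resampler (e.g. up 250 / down 257) with a Kaiser-windowed sinc
   anti-aliasing filter, taps centered so the step is zero-phase. We wrote
   this primitive because the lag estimate is only as good as the resampler's
   phase behaviour: an interpolator with even a few samples of group delay
   would bias every estimate.
2. **Zero-phase band-pass**, second-order Butterworth, 2–10 Hz, applied
   forward and backward (net phase zero; effective magnitude response is the
   squared single-pass response). The band keeps QRS energy while rejecting
   baseline wander below and muscle/powerline noise above. Startup
   transients are suppressed with odd-reflection padding of three effective
   impulse-response lengths (measured from the slowest filter pole), and the
   padding is discarded.
3. **Min-max normalization** over the whole sample, mapping the range to
   $[0,1]$. With the Pearson per-lag statistic this is a no-op
   mathematically; it matters in `raw` mode and keeps channels with
   different gains on an equal footing.

Note that preprocessing is deterministic and phase-neutral but *not*
idempotent: running the chain twice applies the band-pass twice. The second
pass cannot shift the lag (zero phase) and leaves the waveform correlated
above 0.97, which is what the tests assert.

## The dynamic signal-quality index (dSQI)

A sample-level quality score used to gate the estimator:

* **Beat detection** — an energy detector in the Pan–Tompkins family:
  5–15 Hz zero-phase band-pass, derivative, squaring, 150 ms moving-window
  integration, adaptive threshold, 200 ms refractory period, peak refinement
  on the band-passed amplitude.
* **Beat time–frequency maps** — each beat window (R − 0.25 s to R + 0.45 s,
  covering P–QRS–T at normal rates) is mapped with a discrete smoothed
  pseudo Wigner–Ville distribution (SPWVD) of its analytic extension, with
  separable Hamming windows: time smoothing of half-width 10 ms, lag window
  of half-width 30 ms. The magnitude is kept and the frequency axis is
  truncated to 0–40 Hz, where ECG energy lives. The SPWVD is bilinear, so
  amplitude scaling by $a$ scales maps by $a^2$ and cancels in the
  normalized score.
* **Rolling template score** — for every beat $k \ge 4$ the template is the
  mean map of the three preceding beats, and the beat's score is the
  zero-lag two-dimensional Pearson correlation between template and map.
  The first three beats have no template and stay unscored. We interpret
  "cross-correlation" of two maps as this bounded, scale-free coefficient
  because it is comparable across beats and records.
* **Sample SQI** — the fraction of scored beats at or above the good-beat
  cut-off (default 0.9). The cut-off is calibrated in-repo so clean
  synthetic records score exactly 1.0 while −6 dB electrode-motion records
  score below 0.5. It should be recalibrated when devices, signal types or
  environments change.

The SQI is computed on the working-rate signal *without* the 2–10 Hz
alignment band-pass: the quality score judges morphology over 0–40 Hz, and
the narrow alignment band would erase exactly the structure being scored.

## Synthetic study data

The generator emulates the study conditions: paired 257 Hz records with
shared beat timing and lead-specific morphology, 30-minute-scale durations,
occasional arrhythmic beats, and additive noise at controlled SNR.

* **Rhythm** — base rate 75 bpm with AR(1) beat-to-beat variation
  (coefficient 0.8, SD 30 ms), premature beats with probability 0.02 per
  beat (0.6 of the nominal interval, then a compensatory pause), and an
  optional AF-like mode with i.i.d. RR uniform on [0.4, 1.2] s. The values
  are ordinary resting-ECG figures; the AR coefficient gives the slow
  undulation real RR series show.
* **Morphology** — each beat is a sum of Gaussian bumps (P, Q, R, S, T) with
  per-lead amplitude profiles; the Lead V2 preset has the taller R, deeper
  S and taller T of a precordial lead. Both leads share beat times; a
  respiration-like gain modulation (~0.25 Hz, 10% depth) is shared between
  leads while 3% per-beat gain jitter is lead-independent.
* **Noise** — three canonical classes, each zero-mean, unit RMS,
  deterministic given a seed. Baseline wander: three sinusoids in
  0.05–0.5 Hz plus a low-passed random walk. Muscle artifact: 20–50 Hz
  noise with 0.5–2 s amplitude-modulation bursts. Electrode motion: Poisson
  step transients (0.2/s, decay constants 50–300 ms) plus bursty 1–60 Hz
  noise carrying a $1/f$ spectral envelope — electrode displacement is
  physically a low-frequency phenomenon, and this envelope reproduces the
  in-band (2–10 Hz) disruptiveness that makes electrode motion the hardest
  class for the estimator.
* **SNR accounting** — `add_noise()` scales the noise so that
  $10\log_{10}(P_\text{signal}/P_\text{noise})$ hits the request exactly,
  with powers defined as mean squared deviation from the mean over the full
  segment. The convention is round-trip testable to 0.01 dB. (Tools that
  measure signal power from QRS amplitudes will label the same mixture with
  a different number; only the labelling differs.)

What the generator does **not** emulate: conduction-level morphology change
(bundle branch block, ST shifts), respiration-driven baseline movement
coupled to beat morphology, electrode pop artifacts that mimic QRS exactly,
and recorded noise from real hardware. Passing tests therefore demonstrate
the estimator's behaviour under controlled, well-understood corruption — not
its performance on any particular clinical database.

## Benchmark presets

Experiments run against named noise conditions, frozen once:

* `clean` — no added noise;
* `moderate` — electrode motion at 0 dB, the pivot region where short
  samples start to fail while 30-s samples stay stable;
* `stress` — electrode motion at −6 dB;
* `mixed` — half the pairs at 24 dB, half at −6 dB, a bimodal quality
  population for SQI-thresholding studies.

Noise is added to both leads, independently seeded, at the same nominal SNR
(configurable via `noise_on`).

## The experiment harness

Five runners mirror the evaluation design, each returning a tidy table and
a statistics report at $\alpha = 0.05$:

1. **Duration** — reference durations 10–50 s; one-way ANOVA + Tukey HSD.
2. **SQI thresholds** — 0 to 1 in steps of 0.1; per-threshold retained
   fraction and delay, Pearson correlation of threshold vs mean delay.
   Note one structural subtlety: with a bimodal quality population the
   retained-set mean need not fall at *every* step — dropping a low-SQI
   sample that happened to align fine shrinks the denominator and can nudge
   the mean up. The association (negative correlation, endpoint
   improvement) is the robust property.
3. **Noise** — kinds × SNR factorial; two-way ANOVA with interaction,
   simple main effects when the interaction is significant, Tukey HSD per
   factor.
4. **Sampling rate** — the *same* pairs preprocessed to 150/200/250 Hz.
   Because the alignment information lives in the 2–10 Hz band, far below
   every Nyquist rate involved, per-pair results barely move across rates.
5. **Method comparison** — cross-correlation vs subsequence DTW on
   RR-interval series, two-sample t-test.

Every runner is a pure function of (configuration, seed).

### The DTW baseline

RR intervals are extracted with the package detector; open-begin/open-end
(subsequence) dynamic time warping with Euclidean local cost aligns the
reference RR sequence inside the search RR sequence, and the estimated lag
is the median beat-time offset along the warping path — the median resists
path wander at the free endpoints. Costs are computed on raw intervals in
seconds: both leads record the same heart, so the sequences are directly
comparable, and z-scoring each sequence independently would let the search
sample's surrounding rhythm rescale the embedded pattern (we measured ~4 s
of induced bias on a constructed embedding; `normalize = "z"` remains
available). The baseline's resolution is bounded below by beat spacing, and
on near-regular rhythm the subsequence match is ill-determined — which is
precisely why an amplitude-level method is preferable when the signal type
is shared.

## Numerical choices and degenerate inputs

* Zero-variance search windows in Pearson mode score $-\infty$ and can
  never be selected as the peak.
* Constant signals cannot be min-max normalized (classed error); flat
  records yield an empty beat annotation with a warning and the SQI is
  reported undefined rather than fabricated.
* Tie-breaks: correlation maxima break toward the smallest lag; beat
  refinement re-enforces the 200 ms refractory gap after peak snapping.
* All timestamps are seconds as doubles, sample indices are 0-based in lag
  arithmetic, windows are half-open.
* Problem sizes: the shipped checks use 100–200 sample pairs per condition
  (and 20 seeds per SNR level for quality curves). These sizes give the
  direction tests comfortable power while keeping a full run in minutes on
  a single core.

## Known limitations

* The estimator needs a common signal type on both devices; it estimates a
  constant offset, not clock drift.
* No sub-sample lag interpolation: resolution is one working-rate sample.
* The good-beat cut-off and the SQI operating threshold are
  device-and-setting specific; treat the defaults as starting points.
* Synthetic validation bounds what can be claimed about clinical data; see
  the generator's non-goals above.
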