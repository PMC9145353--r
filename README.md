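# ecgsync

Time synchronization of physiological signals recorded by different devices
that share a common signal type. The motivating setting is digital health:
a wrist-watch ECG (morphologically close to clinical Lead I) and a
chest-patch ECG (close to Lead V2) record the same heart on unsynchronized
clocks, and a short spot-check sample from the watch must be located inside
the patch's continuous recording.

## Method

Given a reference sample $x$ ($n$ samples) and a longer search sample $y$
($N$ samples) at a common working rate $f_s$, the package scores every
integer lag $k \in \{0,\dots,N-n\}$ with a per-lag correlation

$$ r_k = \mathrm{corr}\big(x,\, y_{k+1..k+n}\big), $$

and estimates the lag as $\hat\tau = \arg\max_k r_k / f_s$ (Pearson per-lag
statistic by default; the raw inner-product convention is available). Both
signals first pass a fixed conditioning chain — polyphase resampling to
250 Hz, zero-phase second-order Butterworth band-pass at 2–10 Hz, min-max
normalization — so that filtering cannot bias the estimated lag. Around the
estimator the package provides:

* a beat-level **dynamic signal-quality index** (dSQI): smoothed pseudo
  Wigner–Ville time–frequency maps of detected beats, scored against a
  rolling three-beat template; the sample-level index is the fraction of
  good beats and can gate the estimator;
* a **synthetic two-lead ECG generator** (shared beat timing, lead-specific
  Gaussian-bump morphology, arrhythmic beats, 257 Hz native rate) with
  known ground-truth lags;
* calibrated **noise-stress machinery** (baseline wander, electrode motion,
  muscle artifact at exact SNR);
* a **DTW-on-RR-intervals baseline** estimator;
* an **experiment harness** (sample duration, SQI thresholds, noise
  factorial, sampling rate, method comparison) with ANOVA/Tukey/Pearson/
  t-test reporting;
* WFDB (format 16) and CSV readers/writers, and a command-line entry point.

## Worked example

Generate a paired record, cut a 30-s reference with a 90-s search sample
(true lag 30 s by construction), corrupt the search signal with electrode
motion at 6 dB, align, and assess quality:

```r
library(ecgsync)

rec  <- generate_record_pair(duration = 180, rhythm_spec(), seed = 42)
pair <- select_samples(rec$lead_I, rec$lead_V2, m = 30, n_samples = 1,
                       seed = 7)[[1]]
pair
#> <sample_pair> reference 30 s (I) in search 90 s (V2), true lag 30.0 s

noisy <- add_noise(pair$search,
                   generate_noise("EM", signal_duration(pair$search), 257,
                                  seed = 1), snr_db = 6)
res <- estimate_sync_delay(preprocess(pair$reference), preprocess(noisy))
res
#> <sync_result> lag = 30.0000 s (7500 samples), peak r = 0.8920, mode = pearson
sync_error(res, pair)
#> [1] 0

q <- assess_quality(resample_signal(noisy, 250))
q$sample_sqi
#> [1] 0.8990826
```

The estimated lag lands exactly on the 30-s ground truth (a sync delay of
0 s) despite the added noise, and the dSQI reports that about 90% of beats
in the noisy search signal still match their rolling template.

The command-line wrapper exposes the same functionality:

```sh
inst/cli/ecgsync simulate --out sim --duration 120 --records 1 --seed 5
inst/cli/ecgsync sync --reference ref.csv --search search.csv --json-out lag.json
inst/cli/ecgsync benchmark --experiment noise --pairs-per-cell 20 --seed 1 --out bench
```

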