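#' Rhythm specification for the synthetic ECG generator
#'
#' Beat timing model: a base rate with AR(1) beat-to-beat variation
#' (coefficient 0.8), occasional premature (ectopic) beats that arrive at
#' 0.6 of the nominal interval and are followed by a compensatory pause, and
#' an optional atrial-fibrillation-like mode with i.i.d. RR intervals uniform
#' in `[0.4, 1.2]` s.  The defaults emulate recordings from patients with
#' largely sinus rhythm and occasional ectopy.
#'
#' @param mean_hr mean heart rate in bpm, in `[30, 200]`.
#' @param rr_jitter_sd standard deviation (s) of the AR(1) beat-to-beat
#'   variation.
#' @param ectopy_rate per-beat probability of a premature beat.
#' @param af_mode if `TRUE`, RR intervals are i.i.d. uniform on `[0.4, 1.2]` s
#'   and the other timing parameters are ignored.
#' @return an object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(mean_hr = 75, rr_jitter_sd = 0.03, ectopy_rate = 0.02,
                        af_mode = FALSE) {
  if (mean_hr < 30 || mean_hr > 200) abort_invalid("`mean_hr` must be in [30, 200]")
  if (ectopy_rate < 0 || ectopy_rate > 1) abort_invalid("`ectopy_rate` must be in [0, 1]")
  if (rr_jitter_sd < 0) abort_invalid("`rr_jitter_sd` must be >= 0")
  structure(
    list(mean_hr = mean_hr, rr_jitter_sd = rr_jitter_sd,
         ectopy_rate = ectopy_rate, af_mode = isTRUE(af_mode)),
    class = "rhythm_spec"
  )
}

#' Lead morphology presets
#'
#' Each beat is rendered as a sum of Gaussian bumps, one per wave (P, Q, R,
#' S, T), parameterized by center offset relative to the R peak (s), width
#' (s) and amplitude (mV).  The two presets share wave timing but differ in
#' amplitude profile, standing in for a wrist-watch-style limb Lead I and a
#' sternum-patch-style precordial Lead V2 (taller R, deeper S, taller T).
#'
#' @param preset `"lead_I"` or `"lead_V2"`, or a data.frame with columns
#'   `wave`, `center`, `width`, `amp` for a custom morphology.
#' @return a data.frame of wave parameters, class `lead_morphology`.
#' @export
lead_morphology <- function(preset = c("lead_I", "lead_V2")) {
  if (is.data.frame(preset)) {
    need <- c("wave", "center", "width", "amp")
    if (!all(need %in% names(preset))) {
      abort_invalid("custom morphology needs columns wave, center, width, amp")
    }
    if (any(preset$width <= 0)) abort_invalid("wave widths must be positive")
    if (max(abs(preset$amp)) != abs(preset$amp[preset$wave == "R"])) {
      abort_invalid("the R wave must have the dominant amplitude")
    }
    return(structure(preset, class = c("lead_morphology", "data.frame")))
  }
  preset <- match.arg(preset)
  m <- switch(preset,
    lead_I = data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      center = c(-0.200, -0.030, 0.000, 0.030, 0.250),
      width = c(0.025, 0.010, 0.012, 0.010, 0.045),
      amp = c(0.12, -0.10, 1.00, -0.18, 0.30)
    ),
    lead_V2 = data.frame(
      wave = c("P", "Q", "R", "S", "T"),
      center = c(-0.200, -0.030, 0.000, 0.035, 0.270),
      width = c(0.025, 0.010, 0.013, 0.012, 0.050),
      amp = c(0.06, -0.15, 1.60, -0.55, 0.55)
    )
  )
  structure(m, class = c("lead_morphology", "data.frame"))
}

# Draw beat times for `duration` seconds under a rhythm spec.  Returns beat
# times plus a per-beat amplitude factor stream consumed by the renderer.
draw_beat_times <- function(duration, rhythm) {
  base <- 60 / rhythm$mean_hr
  times <- numeric(0)
  t <- 0.5
  e <- 0
  phi <- 0.8
  innov_sd <- rhythm$rr_jitter_sd * sqrt(1 - phi^2)
  pending_pause <- 0
  while (t < duration) {
    times <- c(times, t)
    if (rhythm$af_mode) {
      rr <- stats::runif(1, 0.4, 1.2)
    } else {
      e <- phi * e + innov_sd * stats::rnorm(1)
      rr_nom <- max(0.3, base + e)
      if (pending_pause > 0) {
        rr <- pending_pause
        pending_pause <- 0
      } else if (stats::runif(1) < rhythm$ectopy_rate) {
        rr <- 0.6 * rr_nom            # premature beat ...
        pending_pause <- 1.4 * rr_nom # ... then compensatory pause
      } else {
        rr <- rr_nom
      }
    }
    t <- t + rr
  }
  times
}

# Render Gaussian-bump beats onto a sample grid.  `beat_gain` is an optional
# per-beat multiplicative factor (respiration + beat-to-beat variability).
render_lead <- function(beat_times, morph, n, fs, beat_gain = NULL) {
  x <- numeric(n)
  if (is.null(beat_gain)) beat_gain <- rep(1, length(beat_times))
  for (w in seq_len(nrow(morph))) {
    cen <- morph$center[w]
    wd <- morph$width[w]
    a <- morph$amp[w]
    half <- 4 * wd
    for (b in seq_along(beat_times)) {
      c0 <- beat_times[b] + cen
      i0 <- max(1L, floor((c0 - half) * fs) + 1L)
      i1 <- min(n, ceiling((c0 + half) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      tt <- (idx - 1) / fs
      x[idx] <- x[idx] + beat_gain[b] * a * exp(-0.5 * ((tt - c0) / wd)^2)
    }
  }
  x
}

#' Generate a synchronous two-lead synthetic ECG record
#'
#' Both leads share identical beat times drawn from the rhythm spec; each
#' beat is rendered as the lead's Gaussian-bump sum.  Realism touches shared
#' by real paired recordings: a slow respiration-like amplitude modulation
#' common to both leads (~0.25 Hz, 10% depth) and small independent per-beat
#' amplitude variability per lead (3%).  Deterministic given the seed;
#' ground-truth R times are returned.
#'
#' @param duration record length in seconds (>= 10).
#' @param rhythm a [rhythm_spec()].
#' @param fs native sampling rate in Hz (default 257, the source database
#'   rate being emulated).
#' @param seed integer seed.
#' @return list with `lead_I`, `lead_V2` (both `ecg_signal`) and `r_times`
#'   (seconds).
#' @export
generate_record_pair <- function(duration, rhythm = rhythm_spec(), fs = 257,
                                 seed = 1L) {
  if (duration < 10) abort_invalid("`duration` must be >= 10 s")
  if (!inherits(rhythm, "rhythm_spec")) abort_invalid("`rhythm` must be a `rhythm_spec`")
  with_seed(seed, {
    beat_times <- draw_beat_times(duration, rhythm)
    n <- round(duration * fs)
    resp_f <- stats::runif(1, 0.2, 0.3)
    resp_ph <- stats::runif(1, 0, 2 * pi)
    resp <- 1 + 0.10 * sin(2 * pi * resp_f * beat_times + resp_ph)
    gain_i <- resp * (1 + 0.03 * stats::rnorm(length(beat_times)))
    gain_v <- resp * (1 + 0.03 * stats::rnorm(length(beat_times)))
    lead_i <- render_lead(beat_times, lead_morphology("lead_I"), n, fs, gain_i)
    lead_v <- render_lead(beat_times, lead_morphology("lead_V2"), n, fs, gain_v)
    list(
      lead_I = new_signal(lead_i, fs, t0 = 0, label = "I"),
      lead_V2 = new_signal(lead_v, fs, t0 = 0, label = "V2"),
      r_times = beat_times
    )
  })
}

#' Select reference/search sample pairs from a two-lead record
#'
#' Emulates the study's sampling design: random `m`-second Lead I segments as
#' references, each matched with a Lead V2 segment over the same span plus
#' `margin` seconds of context before and after (so the search sample is
#' `2 * margin` seconds longer and the ground-truth lag is exactly `margin`).
#' Start positions are uniform over all feasible placements; overlaps between
#' samples are allowed.
#'
#' @param lead_I,lead_V2 the two `ecg_signal` leads of one record (same rate).
#' @param m reference duration in seconds.
#' @param n_samples number of pairs to draw.
#' @param margin context seconds on each side of the matched V2 span.
#' @param seed integer seed.
#' @return list of `sample_pair` objects, each with fields `reference`,
#'   `search`, `margin`, `true_lag` (= `margin`) and `meta`.
#' @export
select_samples <- function(lead_I, lead_V2, m, n_samples, margin = 30,
                           seed = 1L) {
  assert_signal(lead_I, "lead_I")
  assert_signal(lead_V2, "lead_V2")
  if (!isTRUE(all.equal(lead_I$fs, lead_V2$fs))) abort_invalid("leads must share fs")
  fs <- lead_I$fs
  dur <- min(signal_duration(lead_I), signal_duration(lead_V2))
  if (dur < m + 2 * margin) {
    abort_invalid(sprintf(
      "record too short: %.1f s; need at least m + 2*margin = %.1f s",
      dur, m + 2 * margin
    ))
  }
  n_ref <- round(m * fs)
  n_margin <- round(margin * fs)
  n_total <- length(lead_I$samples)
  with_seed(seed, {
    starts <- stats::runif(n_samples, margin, dur - m - margin)
    lapply(seq_len(n_samples), function(i) {
      i0 <- round(starts[i] * fs) # 0-based start of the reference
      i0 <- min(max(i0, n_margin), n_total - n_ref - n_margin)
      ref <- new_signal(lead_I$samples[(i0 + 1L):(i0 + n_ref)], fs,
                        t0 = i0 / fs, label = lead_I$label)
      srch <- new_signal(
        lead_V2$samples[(i0 - n_margin + 1L):(i0 + n_ref + n_margin)], fs,
        t0 = (i0 - n_margin) / fs, label = lead_V2$label
      )
      structure(
        list(reference = ref, search = srch, margin = margin,
             true_lag = margin,
             meta = list(sample_id = i, start_s = i0 / fs, seed = seed)),
        class = "sample_pair"
      )
    })
  })
}

#' @export
print.sample_pair <- function(x, ...) {
  cat(sprintf(
    "<sample_pair> reference %.0f s (%s) in search %.0f s (%s), true lag %.1f s\n",
    signal_duration(x$reference), x$reference$label,
    signal_duration(x$search), x$search$label, x$true_lag
  ))
  invisible(x)
}

# ---- noise synthesis --------------------------------------------------------

# white noise shaped to a 1/f envelope inside [flo, fhi] (unit RMS)
shaped_band_noise <- function(n, fs, flo, fhi, inv_f = FALSE) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f2 <- pmin(f, fs - f)
  gmask <- f2 >= flo & f2 <= fhi
  gain <- ifelse(gmask, if (inv_f) 1 / pmax(f2, flo) else 1, 0)
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  rms <- sqrt(mean(x^2))
  if (rms == 0) return(x)
  x / rms
}

# 0/1 burst envelope: bursts of duration U(0.5, 2) s arriving after
# exponential gaps, smoothed, with a quiescent floor.
burst_envelope <- function(n, fs, rate = 0.3, floor_level = 0.2) {
  env <- rep(floor_level, n)
  t <- 0
  while (t < n / fs) {
    gap <- stats::rexp(1, rate)
    dur <- stats::runif(1, 0.5, 2)
    i0 <- floor((t + gap) * fs) + 1
    i1 <- min(n, floor((t + gap + dur) * fs))
    if (i0 <= n && i0 <= i1) env[i0:i1] <- 1
    t <- t + gap + dur
  }
  w <- max(1L, round(0.1 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- floor_level
  env
}

#' Synthesize ECG noise of a given class
#'
#' Emulates the three canonical noise-stress classes:
#' \describe{
#'   \item{BW}{baseline wander: three sinusoids with random frequencies in
#'     `[0.05, 0.5]` Hz and phases, plus a low-pass-filtered random walk.}
#'   \item{EM}{electrode motion: Poisson step transients (rate 0.2/s,
#'     exponential decay with time constants of 0.05-0.3 s) superposed with
#'     bursty band-limited noise in 1-60 Hz carrying a 1/f spectral envelope,
#'     the low-frequency-heavy profile characteristic of electrode
#'     displacement artifacts.}
#'   \item{MA}{muscle artifact: white noise band-passed to
#'     `20-min(50, 0.45*fs)` Hz with 0.5-2 s amplitude-modulation bursts.}
#' }
#' Output is zero-mean with unit RMS and is deterministic given the seed.
#'
#' @param kind `"BW"`, `"EM"` or `"MA"`.
#' @param duration seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return an `ecg_signal` labelled with the noise kind.
#' @export
generate_noise <- function(kind, duration, fs, seed = 1L) {
  if (!is.character(kind) || !(kind %in% c("BW", "EM", "MA"))) {
    abort_invalid("`kind` must be one of \"BW\", \"EM\", \"MA\"")
  }
  if (duration <= 0) abort_invalid("`duration` must be positive")
  n <- round(duration * fs)
  x <- with_seed(seed, {
    switch(kind,
      BW = {
        tt <- (0:(n - 1)) / fs
        s <- numeric(n)
        for (i in 1:3) {
          s <- s + stats::runif(1, 0.5, 1) *
            sin(2 * pi * stats::runif(1, 0.05, 0.5) * tt + stats::runif(1, 0, 2 * pi))
        }
        rw <- cumsum(stats::rnorm(n))
        ba <- butter_coefs(2, 0.01, 0.5, fs) # keep only the slow drift
        rw <- signal::filtfilt(ba, rw)
        rms <- sqrt(mean(rw^2))
        if (rms > 0) s <- s + rw / rms
        s
      },
      EM = {
        steps <- numeric(n)
        n_steps <- stats::rpois(1, 0.2 * n / fs)
        if (n_steps > 0) {
          for (i in seq_len(n_steps)) {
            i0 <- sample.int(n, 1)
            tau <- stats::runif(1, 0.05, 0.3) * fs
            amp <- stats::rnorm(1)
            idx <- i0:min(n, i0 + ceiling(6 * tau))
            steps[idx] <- steps[idx] + amp * exp(-(idx - i0) / tau)
          }
        }
        srms <- sqrt(mean(steps^2))
        if (srms > 0) steps <- steps / srms
        bursts <- shaped_band_noise(n, fs, 1, min(60, 0.45 * fs), inv_f = TRUE) *
          burst_envelope(n, fs, rate = 0.3, floor_level = 0.2)
        brms <- sqrt(mean(bursts^2))
        if (brms > 0) bursts <- bursts / brms
        sqrt(0.5) * steps + sqrt(0.5) * bursts
      },
      MA = {
        shaped_band_noise(n, fs, 20, min(50, 0.45 * fs)) *
          burst_envelope(n, fs, rate = 0.4, floor_level = 0.25)
      }
    )
  })
  x <- x - mean(x)
  rms <- sqrt(mean(x^2))
  if (rms == 0) abort_degenerate("generated noise has zero power")
  new_signal(x / rms, fs, t0 = 0, label = kind)
}

#' Add noise at a controlled SNR
#'
#' Scales the noise so that `10 * log10(P_signal / P_noise)` equals the
#' requested SNR, with powers defined as mean squared deviation from the mean
#' over the full segment, and adds it to the signal.
#'
#' @param signal,noise `ecg_signal`s of equal length and rate.
#' @param snr_db requested signal-to-noise ratio in dB.
#' @return the noisy `ecg_signal` (metadata of `signal` preserved).
#' @export
add_noise <- function(signal, noise, snr_db) {
  assert_signal(signal)
  assert_signal(noise, "noise")
  if (length(signal$samples) != length(noise$samples)) {
    abort_invalid("signal and noise must have equal length")
  }
  if (!isTRUE(all.equal(signal$fs, noise$fs))) {
    abort_invalid("signal and noise must share fs")
  }
  if (!is.finite(snr_db)) abort_invalid("`snr_db` must be finite")
  p_sig <- stats::var(signal$samples) * (length(signal$samples) - 1) / length(signal$samples)
  p_noi <- stats::var(noise$samples) * (length(noise$samples) - 1) / length(noise$samples)
  if (p_sig == 0) abort_degenerate("signal has zero power")
  if (p_noi == 0) abort_degenerate("noise has zero power")
  alpha <- sqrt(p_sig / (p_noi * 10^(snr_db / 10)))
  new_signal(signal$samples + alpha * noise$samples, signal$fs,
             t0 = signal$t0, label = signal$label)
}

#' Sampling-plan arithmetic
#'
#' Size of a sample set drawn with the study's design: a fixed number of
#' random segments per record across a record collection.
#'
#' @param n_records number of records.
#' @param samples_per_record segments drawn per record.
#' @return total number of sample pairs.
#' @export
sampling_plan_size <- function(n_records = 75, samples_per_record = 100) {
  if (n_records < 1 || samples_per_record < 1) {
    abort_invalid("counts must be positive")
  }
  as.integer(n_records) * as.integer(samples_per_record)
}
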