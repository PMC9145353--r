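sine_signal <- function(freq, fs, duration, label = "sine") {
  t <- (0:(round(duration * fs) - 1)) / fs
  new_signal(sin(2 * pi * freq * t), fs, label = label)
}

# a clean preprocessed sample pair at the working rate, shared across tests
make_clean_pair <- function(m = 30, seed = 42, rhythm = rhythm_spec()) {
  rec <- generate_record_pair(m + 80, rhythm, seed = seed)
  select_samples(rec$lead_I, rec$lead_V2, m = m, n_samples = 1,
                 seed = seed + 1)[[1]]
}

# strictly periodic record: identical beats (no jitter, no ectopy, and the
# generator's shared modulation switched off by zero-depth respiration is not
# exposed, so build directly from the renderer via a regular rhythm)
regular_signal <- function(duration = 40, fs = 250, rr = 1.0, label = "I") {
  beat_t <- seq(0.5, duration - 0.5, by = rr)
  morph <- lead_morphology("lead_I")
  n <- round(duration * fs)
  x <- numeric(n)
  tt <- (0:(n - 1)) / fs
  for (w in seq_len(nrow(morph))) {
    for (b in beat_t) {
      c0 <- b + morph$center[w]
      idx <- which(abs(tt - c0) < 4 * morph$width[w])
      x[idx] <- x[idx] + morph$amp[w] * exp(-0.5 * ((tt[idx] - c0) / morph$width[w])^2)
    }
  }
  list(signal = new_signal(x, fs, label = label), beat_times = beat_t)
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("ecgsync")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
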