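test_that("beat detection recovers clean synthetic beats within 50 ms", {
  rec <- generate_record_pair(30, rhythm_spec(mean_hr = 60, ectopy_rate = 0),
                              seed = 20)
  sig <- resample_signal(rec$lead_I, 250)
  beats <- detect_beats(sig)
  expect_lte(abs(length(beats$r_samples) - length(rec$r_times)), 1)
  det_t <- (beats$r_samples - 1) / 250
  # recall and precision 1.0 at +-50 ms
  err <- sapply(rec$r_times, function(t) min(abs(det_t - t)))
  expect_true(all(err <= 0.05))
  err2 <- sapply(det_t, function(t) min(abs(rec$r_times - t)))
  expect_true(all(err2 <= 0.05))
  # inter-beat gaps respect the refractory period
  expect_true(all(diff(beats$r_samples) >= 0.2 * 250))
})

test_that("a flat signal yields an empty annotation with a warning", {
  expect_warning(
    beats <- detect_beats(new_signal(rep(0, 250 * 10), 250)),
    "no beats"
  )
  expect_length(beats$r_samples, 0)
})

test_that("one premature beat raises the detected count by exactly one", {
  base <- rhythm_spec(mean_hr = 60, rr_jitter_sd = 0, ectopy_rate = 0)
  rec <- generate_record_pair(30, base, seed = 21)
  sig <- resample_signal(rec$lead_I, 250)
  n0 <- length(detect_beats(sig)$r_samples)
  # inject one extra beat midway between two existing beats
  morph <- lead_morphology("lead_I")
  extra <- rec$r_times[15] + 0.45
  x <- rec$lead_I$samples
  tt <- (seq_along(x) - 1) / 257
  for (w in seq_len(nrow(morph))) {
    c0 <- extra + morph$center[w]
    idx <- which(abs(tt - c0) < 4 * morph$width[w])
    x[idx] <- x[idx] + morph$amp[w] * exp(-0.5 * ((tt[idx] - c0) / morph$width[w])^2)
  }
  sig1 <- resample_signal(new_signal(x, 257, label = "I"), 250)
  expect_equal(length(detect_beats(sig1)$r_samples), n0 + 1)
})

test_that("SPWVD localizes a pure tone and scales bilinearly", {
  fs <- 250
  t <- (0:(fs * 4 - 1)) / fs
  tone <- new_signal(sin(2 * pi * 10 * t), fs)
  tf <- beat_tfmap(tone, round(1.0 * fs))
  cfg <- sqi_config()
  freqs <- (0:(cfg$n_fft - 1)) * fs / (2 * cfg$n_fft)
  freqs <- freqs[freqs <= cfg$f_max]
  ridge <- apply(tf, 2, which.max)
  nonzero <- apply(tf, 2, max) > 0 # smoothing zeroes a few edge columns
  expect_gt(mean(nonzero), 0.95)
  expect_true(all(abs(freqs[ridge[nonzero]] - 10) < 2.5))
  # bilinearity: doubling the amplitude scales the map by 4
  tone2 <- new_signal(2 * sin(2 * pi * 10 * t), fs)
  tf2 <- beat_tfmap(tone2, round(1.0 * fs))
  expect_equal(tf2, 4 * tf, tolerance = 1e-9)
  # determinism
  expect_identical(tf, beat_tfmap(tone, round(1.0 * fs)))
  expect_error(beat_tfmap(tone, 5), class = "ecgsync_beat_window_oob")
})

test_that("identical beats score 1 and scores ignore global amplitude", {
  reg <- regular_signal(duration = 30, fs = 250)
  rep1 <- beat_scores(reg$signal)
  sc <- rep1$scores[!is.na(rep1$scores)]
  expect_gt(length(sc), 10)
  expect_true(all(abs(sc - 1) < 1e-8))
  expect_true(all(is.na(rep1$scores[1:3]))) # first three beats unscored
  # global scaling leaves every score unchanged
  scaled <- new_signal(reg$signal$samples * 3.7, 250, label = "I")
  rep2 <- beat_scores(scaled)
  expect_equal(rep2$scores, rep1$scores, tolerance = 1e-9)
})

test_that("a noise-replaced beat scores low while its neighbours stay high", {
  reg <- regular_signal(duration = 30, fs = 250)
  x <- reg$signal$samples
  # replace the window of beat 10 with broadband noise of equal RMS
  r <- round(reg$beat_times[10] * 250) + 1
  idx <- (r - 60):(r + 100)
  set.seed(30)
  x[idx] <- rnorm(length(idx)) * sqrt(mean(x[idx]^2))
  rep1 <- beat_scores(new_signal(x, 250), detect_beats(reg$signal))
  bad <- 10
  expect_lt(rep1$scores[bad], 0.5)
  ok <- setdiff(which(!is.na(rep1$scores)), bad:(bad + 3))
  expect_true(all(rep1$scores[ok] > 0.9))
})

test_that("sample_sqi is the thresholded fraction and is threshold-monotone", {
  rep1 <- structure(
    list(scores = c(NA, NA, NA, rep(0.95, 4), rep(0.5, 6)), n_scored = 10),
    class = "quality_report"
  )
  expect_equal(sample_sqi(rep1, 0.9), 0.4)
  expect_equal(sample_sqi(rep1, 0.4), 1.0)
  ths <- seq(0, 1, by = 0.1)
  vals <- sapply(ths, function(t) sample_sqi(rep1, t))
  expect_true(all(diff(vals) <= 0))
  empty <- structure(list(scores = rep(NA_real_, 3)), class = "quality_report")
  expect_error(sample_sqi(empty, 0.9), class = "ecgsync_quality_undefined")
})

test_that("clean records reach sample SQI 1.0 at the default threshold", {
  rec <- generate_record_pair(40, rhythm_spec(ectopy_rate = 0), seed = 22)
  q <- assess_quality(resample_signal(rec$lead_I, 250))
  expect_equal(q$sample_sqi, 1.0)
})

test_that("sqi_filter applies a >= threshold and reports the ratio", {
  f <- sqi_filter(c(1.0, 0.8, 1.0), 1)
  expect_equal(sum(f$retained), 2)
  expect_equal(f$ratio, 2 / 3)
  expect_equal(sqi_filter(c(0.49, 0.50), 0.5)$ratio, 0.5) # boundary: >= keeps 0.50
  expect_equal(sqi_filter(runif(10), 0)$ratio, 1)
  # retained count is monotone non-increasing in the threshold
  set.seed(8)
  sqis <- runif(50)
  ns <- sapply(seq(0, 1, by = 0.1), function(t) sum(sqi_filter(sqis, t)$retained))
  expect_true(all(diff(ns) <= 0))
})

test_that("mean sample SQI trends down as EM noise deepens", {
  msqi <- sapply(c(24, 0, -6), function(snr) {
    mean(sapply(1:4, function(i) {
      rec <- generate_record_pair(40, rhythm_spec(ectopy_rate = 0),
                                  seed = 40 + i)
      nz <- generate_noise("EM", 40, 257, seed = 80 + i)
      noisy <- add_noise(rec$lead_I, nz, snr)
      q <- tryCatch(assess_quality(resample_signal(noisy, 250)),
                    ecgsync_quality_undefined = function(e) NULL)
      if (is.null(q)) 0 else q$sample_sqi
    }))
  })
  expect_true(msqi[1] >= msqi[2])
  expect_gt(msqi[1], msqi[3])
  expect_lt(msqi[3], 0.5)
})
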