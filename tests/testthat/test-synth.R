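test_that("record pairs share beat timing and are seed-deterministic", {
  rec <- generate_record_pair(60, rhythm_spec(mean_hr = 60, rr_jitter_sd = 0),
                              seed = 1)
  expect_lte(abs(length(rec$r_times) - 60), 1)
  expect_equal(length(rec$lead_I$samples), 60 * 257)
  rec2 <- generate_record_pair(60, rhythm_spec(mean_hr = 60, rr_jitter_sd = 0),
                               seed = 1)
  expect_identical(rec$lead_I$samples, rec2$lead_I$samples)
  expect_identical(rec$lead_V2$samples, rec2$lead_V2$samples)
  expect_identical(rec$r_times, rec2$r_times)
  rec3 <- generate_record_pair(60, rhythm_spec(mean_hr = 60, rr_jitter_sd = 0),
                               seed = 2)
  expect_false(identical(rec$lead_I$samples, rec3$lead_I$samples))
})

test_that("ectopic beats come early and are followed by a pause", {
  rec <- generate_record_pair(300, rhythm_spec(mean_hr = 60, rr_jitter_sd = 0,
                                               ectopy_rate = 0.05), seed = 4)
  rr <- diff(rec$r_times)
  short <- which(rr < 0.75)
  expect_gt(length(short), 0)
  # each premature interval is followed by a compensatory long one
  expect_true(all(rr[pmin(short + 1, length(rr))] > 1.2))
})

test_that("af mode draws i.i.d. RR in [0.4, 1.2] s", {
  rec <- generate_record_pair(200, rhythm_spec(af_mode = TRUE), seed = 5)
  rr <- diff(rec$r_times)
  expect_true(all(rr >= 0.4 - 1e-9 & rr <= 1.2 + 1e-9))
  expect_gt(stats::sd(rr), 0.1)
})

test_that("sample selection builds the documented geometry", {
  rec <- generate_record_pair(180, rhythm_spec(), seed = 6)
  prs <- select_samples(rec$lead_I, rec$lead_V2, m = 30, n_samples = 5,
                        seed = 7)
  expect_length(prs, 5)
  for (p in prs) {
    expect_equal(signal_duration(p$reference), 30)
    expect_equal(signal_duration(p$search), 90) # 60 s longer
    expect_equal(p$true_lag, 30)
    expect_identical(p$reference$label, "I")
    expect_identical(p$search$label, "V2")
    # ground truth consistency: the reference window of lead V2 occupies
    # [true_lag, true_lag + m] of the search cut, same cut indices
    i0 <- round(p$true_lag * p$search$fs)
    v2win <- p$search$samples[(i0 + 1):(i0 + length(p$reference$samples))]
    full_v2 <- rec$lead_V2$samples[
      round(p$reference$t0 * 257) + seq_along(v2win)
    ]
    expect_identical(v2win, full_v2)
  }
  expect_error(
    select_samples(rec$lead_I, rec$lead_V2, m = 150, n_samples = 1),
    class = "ecgsync_invalid_argument"
  )
})

test_that("noise generators honour their spectral envelopes and unit RMS", {
  for (kind in c("BW", "EM", "MA")) {
    nz <- generate_noise(kind, 60, 257, seed = 9)
    expect_equal(sqrt(mean(nz$samples^2)), 1, tolerance = 1e-9)
    expect_equal(mean(nz$samples), 0, tolerance = 1e-12)
    expect_identical(generate_noise(kind, 60, 257, seed = 9)$samples,
                     nz$samples)
  }
  bw <- generate_noise("BW", 120, 257, seed = 10)
  expect_gt(band_power_fraction(bw$samples, 257, 0, 1), 0.95)
  ma <- generate_noise("MA", 120, 257, seed = 11)
  expect_gt(band_power_fraction(ma$samples, 257, 15, 128), 0.90)
  expect_error(generate_noise("XX", 10, 257), class = "ecgsync_invalid_argument")
})

test_that("add_noise achieves the requested SNR exactly", {
  rec <- generate_record_pair(30, rhythm_spec(), seed = 12)
  sig <- rec$lead_I
  for (snr in c(-6, 0, 24)) {
    nz <- generate_noise("EM", 30, 257, seed = 13)
    noisy <- add_noise(sig, nz, snr)
    added <- noisy$samples - sig$samples
    achieved <- 10 * log10(stats::var(sig$samples) / stats::var(added))
    expect_lt(abs(achieved - snr), 0.01)
    if (snr == 0) {
      expect_equal(stats::var(added), stats::var(sig$samples),
                   tolerance = 1e-6)
    }
    if (snr == -6) {
      expect_equal(stats::var(added) / stats::var(sig$samples), 10^0.6,
                   tolerance = 1e-6)
    }
  }
  expect_error(
    add_noise(new_signal(rep(1, 100), 257), generate_noise("BW", 100 / 257, 257), 0),
    class = "ecgsync_degenerate_signal"
  )
})

test_that("the sampling-plan arithmetic reproduces the study size", {
  expect_identical(sampling_plan_size(75, 100), 7500L)
  expect_identical(sampling_plan_size(1, 1), 1L)
  expect_error(sampling_plan_size(0, 10), class = "ecgsync_invalid_argument")
})

test_that("alignment degrades monotonically as EM noise deepens", {
  # small-n trend check; the full-grid version runs in the acceptance suite
  mean_err <- sapply(c(-6, 6, 24), function(snr) {
    errs <- sapply(1:8, function(i) {
      p <- make_clean_pair(m = 10, seed = 300 + i)
      ref <- add_noise(p$reference,
                       generate_noise("EM", signal_duration(p$reference),
                                      257, seed = 600 + i), snr)
      srch <- add_noise(p$search,
                        generate_noise("EM", signal_duration(p$search),
                                       257, seed = 700 + i), snr)
      sync_error(estimate_sync_delay(preprocess(ref), preprocess(srch)), p)
    })
    mean(errs)
  })
  expect_true(mean_err[1] >= mean_err[2] - 1 / 250)
  expect_true(mean_err[2] >= mean_err[3] - 1 / 250)
})
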