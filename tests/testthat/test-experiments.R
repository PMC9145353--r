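# The statistical machinery is validated on closed-form fixtures; the
# experiment runners themselves are exercised at small n for shape,
# determinism and degenerate-input handling (their scientific directions run
# at full size in the acceptance suite).

test_that("one-way ANOVA and Tukey agree with hand-computed sums of squares", {
  # tiny printed dataset: three groups, known F by hand
  g <- rep(c(10, 20, 30), each = 4)
  y <- c(5, 6, 7, 6, 8, 9, 10, 9, 12, 13, 14, 13)
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_hand <- (ss_between / 2) / (ss_within / 9)
  fit <- stats::aov(y ~ factor(g))
  an <- summary(fit)[[1]]
  expect_equal(an[["F value"]][1], f_hand, tolerance = 1e-12)
  # the runner wraps exactly this machinery
  tab <- data.frame(m_seconds = g, sync_delay_seconds = y)
  fit2 <- stats::aov(sync_delay_seconds ~ factor(m_seconds), data = tab)
  expect_equal(summary(fit2)[[1]][["F value"]][1], f_hand, tolerance = 1e-12)
})

test_that("duration experiment: table shape, grids and degenerate grid", {
  cfg <- benchmark_preset("clean", pairs_per_record = 4)
  out <- run_duration_experiment(durations = c(10, 30), config = cfg,
                                 pairs_per_group = 4, seed = 90)
  expect_equal(nrow(out$table), 8)
  expect_setequal(unique(out$table$m_seconds), c(10, 30))
  expect_true(all(out$table$sync_delay_seconds >= 0))
  expect_s3_class(out$stats, "stats_report")
  # bit-identical regeneration from (config, seed)
  out2 <- run_duration_experiment(durations = c(10, 30), config = cfg,
                                  pairs_per_group = 4, seed = 90)
  expect_identical(out$table, out2$table)
  # single group: ANOVA flagged inapplicable
  out1 <- run_duration_experiment(durations = 30, config = cfg,
                                  pairs_per_group = 4, seed = 91)
  expect_match(out1$stats$note, "inapplicable")
  expect_error(run_duration_experiment(durations = numeric(0), config = cfg),
               class = "ecgsync_invalid_argument")
  expect_error(run_duration_experiment(durations = c(10, 70), config = cfg),
               class = "ecgsync_invalid_argument")
})

test_that("sqi experiment reports one row per threshold with sane ratios", {
  cfg <- benchmark_preset("mixed", pairs_per_record = 8)
  out <- run_sqi_experiment(config = cfg, n_pairs = 8, seed = 92)
  expect_equal(nrow(out$summary), 11)
  expect_equal(out$summary$sqi_threshold, seq(0, 1, by = 0.1))
  expect_equal(out$summary$retaining_ratio[1], 1.0) # threshold 0 keeps all
  expect_true(all(diff(out$summary$retaining_ratio) <= 0))
  expect_true(all(out$table$sample_sqi >= 0 & out$table$sample_sqi <= 1))
})

test_that("noise experiment builds the full factorial and two-way report", {
  cfg <- benchmark_config(m = 10, pairs_per_record = 3, record_duration = 90)
  out <- run_noise_experiment(kinds = c("BW", "EM"), snrs = c(-6, 24),
                              config = cfg, pairs_per_cell = 3, seed = 93)
  expect_equal(nrow(out$table), 2 * 2 * 3)
  expect_setequal(unique(out$table$noise_kind), c("BW", "EM"))
  expect_setequal(unique(out$table$snr_db), c(-6, 24))
  expect_named(out$stats$statistic, c("kind", "snr", "interaction"))
  expect_true(all(out$stats$p_value >= 0 & out$stats$p_value <= 1, na.rm = TRUE))
  # single-level factor degrades to one-way with a note
  out1 <- run_noise_experiment(kinds = "EM", snrs = c(-6, 24), config = cfg,
                               pairs_per_cell = 3, seed = 94)
  expect_match(out1$stats$note, "single level|one factor")
})

test_that("fs experiment evaluates identical pairs at every rate", {
  cfg <- benchmark_preset("clean", pairs_per_record = 4)
  out <- run_fs_experiment(rates = c(150, 250), config = cfg, n_pairs = 4,
                           seed = 95)
  expect_equal(nrow(out$table), 8)
  expect_setequal(unique(out$table$fs_hz), c(150, 250))
  # clean pairs: exact recovery at every rate
  expect_true(all(out$table$sync_delay_seconds <= 1 / 150))
  expect_error(run_fs_experiment(rates = c(15, 250), config = cfg),
               class = "ecgsync_invalid_argument")
  expect_error(run_fs_experiment(rates = c(250, 300), config = cfg),
               class = "ecgsync_invalid_argument")
})

test_that("method comparison t-test: null case and degenerate n", {
  cfg <- benchmark_preset("clean", pairs_per_record = 4)
  null_out <- run_method_comparison(cfg, n_pairs = 4, seed = 96,
                                    methods = c("xcorr", "xcorr"))
  expect_gt(null_out$stats$p_value, 0.99)
  one <- run_method_comparison(cfg, n_pairs = 1, seed = 97)
  expect_match(one$stats$note, "inapplicable")
})
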