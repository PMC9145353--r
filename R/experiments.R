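#' Benchmark configuration
#'
#' Shared settings for the experiment harness: sample geometry, native and
#' working rates, the noise condition, and how many synthetic records back
#' the pair pool.
#'
#' @param m reference sample duration, seconds.
#' @param margin search-context seconds on each side (the true lag).
#' @param fs_native generator rate in Hz.
#' @param preprocess a [preprocess_config()].
#' @param noise `NULL` for clean, or `list(kind =, snr_db =)`; for mixed
#'   conditions a list of such lists with an optional `weight` each.
#' @param noise_on which signals receive noise: `"both"` (independently
#'   seeded, same SNR), `"search"` or `"reference"`.
#' @param pairs_per_record how many sample pairs are cut from each synthetic
#'   record.
#' @param record_duration length of each backing record, seconds; defaults to
#'   a value that comfortably fits the sample geometry.
#' @param rhythm a [rhythm_spec()].
#' @return an object of class `benchmark_config`.
#' @export
benchmark_config <- function(m = 30, margin = 30, fs_native = 257,
                             preprocess = preprocess_config(),
                             noise = NULL, noise_on = "both",
                             pairs_per_record = 20,
                             record_duration = NULL,
                             rhythm = rhythm_spec()) {
  if (is.null(record_duration)) record_duration <- max(180, m + 2 * margin + 60)
  if (record_duration < m + 2 * margin) {
    abort_invalid("`record_duration` too short for the sample geometry")
  }
  if (!noise_on %in% c("both", "search", "reference")) {
    abort_invalid('`noise_on` must be "both", "search" or "reference"')
  }
  structure(
    list(m = m, margin = margin, fs_native = fs_native,
         preprocess = preprocess, noise = noise, noise_on = noise_on,
         pairs_per_record = pairs_per_record,
         record_duration = record_duration, rhythm = rhythm),
    class = "benchmark_config"
  )
}

#' Named benchmark presets
#'
#' Noise conditions used by the experiment harness:
#' \describe{
#'   \item{clean}{no added noise.}
#'   \item{moderate}{electrode-motion noise at 0 dB SNR -- around the pivot
#'     where alignment of short samples starts to degrade while 30-s samples
#'     remain stable.}
#'   \item{stress}{electrode-motion noise at -6 dB SNR.}
#'   \item{mixed}{half the pairs at 24 dB, half at -6 dB electrode-motion
#'     noise -- a bimodal quality population for SQI-thresholding studies.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to [benchmark_config()].
#' @return a `benchmark_config`.
#' @export
benchmark_preset <- function(name = c("clean", "moderate", "stress", "mixed"),
                             ...) {
  name <- match.arg(name)
  noise <- switch(name,
    clean = NULL,
    moderate = list(kind = "EM", snr_db = 0),
    stress = list(kind = "EM", snr_db = -6),
    mixed = list(
      list(kind = "EM", snr_db = 24, weight = 0.5),
      list(kind = "EM", snr_db = -6, weight = 0.5)
    )
  )
  benchmark_config(noise = noise, ...)
}

# Is `noise` a single condition or a list of conditions?
noise_conditions <- function(noise) {
  if (is.null(noise)) return(list(NULL))
  if (!is.null(noise$kind)) return(list(noise))
  noise
}

# Assign one noise condition per pair (round-robin by weight).
assign_conditions <- function(noise, n) {
  conds <- noise_conditions(noise)
  if (length(conds) == 1L) return(rep(1L, n))
  w <- vapply(conds, function(c) if (is.null(c$weight)) 1 else c$weight, numeric(1))
  w <- w / sum(w)
  rep(seq_along(conds), times = diff(round(cumsum(c(0, w)) * n)))[seq_len(n)]
}

apply_noise <- function(sig, cond, seed) {
  if (is.null(cond)) return(sig)
  nz <- generate_noise(cond$kind, signal_duration(sig), sig$fs, seed = seed)
  add_noise(sig, nz, cond$snr_db)
}

# Build `n_pairs` noisy sample pairs under a config; returns the raw (native
# rate) pairs plus per-pair noise condition index.
build_pairs <- function(config, n_pairs, seed, m = config$m) {
  n_records <- ceiling(n_pairs / config$pairs_per_record)
  pairs <- vector("list", n_pairs)
  cond_of <- assign_conditions(config$noise, n_pairs)
  conds <- noise_conditions(config$noise)
  k <- 0L
  for (r in seq_len(n_records)) {
    rec <- generate_record_pair(config$record_duration, config$rhythm,
                                fs = config$fs_native,
                                seed = derive_seed(seed, r))
    n_here <- min(config$pairs_per_record, n_pairs - k)
    ps <- select_samples(rec$lead_I, rec$lead_V2, m = m, n_samples = n_here,
                         margin = config$margin,
                         seed = derive_seed(seed, 100000 + r))
    for (p in ps) {
      k <- k + 1L
      cond <- conds[[cond_of[k]]]
      if (!is.null(cond)) {
        if (config$noise_on %in% c("both", "reference")) {
          p$reference <- apply_noise(p$reference, cond,
                                     derive_seed(seed, 200000 + 2 * k))
        }
        if (config$noise_on %in% c("both", "search")) {
          p$search <- apply_noise(p$search, cond,
                                  derive_seed(seed, 200000 + 2 * k + 1))
        }
      }
      p$meta$record_id <- r
      p$meta$condition <- cond_of[k]
      pairs[[k]] <- p
    }
  }
  list(pairs = pairs, cond_of = cond_of, conds = conds)
}

# Align one raw pair: preprocess both signals and estimate the delay.
align_pair <- function(pair, preprocess_cfg, mode = "pearson") {
  ref <- preprocess(pair$reference, preprocess_cfg)
  srch <- preprocess(pair$search, preprocess_cfg)
  res <- estimate_sync_delay(ref, srch, mode)
  list(result = res, delay = sync_error(res, pair))
}

stats_report <- function(test, factors, statistic, p_value, posthoc = NULL,
                         note = NULL) {
  structure(
    list(test = test, factors = factors, statistic = statistic,
         p_value = p_value, posthoc = posthoc, alpha = 0.05, note = note),
    class = "stats_report"
  )
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> %s on %s: statistic = %s, p = %s\n",
              x$test, paste(x$factors, collapse = " x "),
              format(x$statistic, digits = 4), format(x$p_value, digits = 4)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

new_benchmark_table <- function(rows) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

benchmark_row <- function(pair, m, delay, method = "xcorr",
                          sqi_threshold = NA, noise_kind = NA, snr_db = NA,
                          fs_hz = NA, sample_sqi = NA, seed = NA) {
  data.frame(
    record_id = pair$meta$record_id, sample_id = pair$meta$sample_id,
    m_seconds = m, sqi_threshold = sqi_threshold,
    noise_kind = noise_kind, snr_db = snr_db, fs_hz = fs_hz,
    method = method, sync_delay_seconds = delay, sample_sqi = sample_sqi,
    seed = seed, stringsAsFactors = FALSE
  )
}

#' Experiment 1: sample-duration test
#'
#' Sweeps the reference duration over a grid, aligns a fresh pool of sample
#' pairs per duration under the configured noise condition, and compares the
#' groups with a one-way ANOVA plus Tukey HSD.
#'
#' @param durations grid of reference durations, seconds (within [5, 60]).
#' @param config a [benchmark_config()] (noise condition etc.).
#' @param pairs_per_group pairs aligned per duration.
#' @param seed integer seed.
#' @return list with `table` (tidy per-sample rows) and `stats` (a
#'   `stats_report`).
#' @export
run_duration_experiment <- function(durations = c(10, 20, 30, 40, 50),
                                    config = benchmark_preset("moderate"),
                                    pairs_per_group = 50, seed = 1L) {
  if (!length(durations)) abort_invalid("empty duration grid")
  if (any(durations < 5 | durations > 60)) {
    abort_invalid("durations must lie in [5, 60] s")
  }
  rows <- list()
  for (gi in seq_along(durations)) {
    m <- durations[gi]
    built <- build_pairs(config, pairs_per_group, derive_seed(seed, gi), m = m)
    for (p in built$pairs) {
      al <- align_pair(p, config$preprocess)
      cond <- built$conds[[p$meta$condition]]
      rows[[length(rows) + 1L]] <- benchmark_row(
        p, m, al$delay,
        noise_kind = if (is.null(cond)) NA else cond$kind,
        snr_db = if (is.null(cond)) NA else cond$snr_db,
        fs_hz = config$preprocess$target_fs, seed = seed
      )
    }
  }
  tab <- new_benchmark_table(rows)
  if (length(durations) < 2L) {
    st <- stats_report("one-way ANOVA", "m_seconds", NA_real_, NA_real_,
                       note = "single duration group: ANOVA inapplicable")
  } else {
    fit <- stats::aov(sync_delay_seconds ~ factor(m_seconds), data = tab)
    an <- summary(fit)[[1]]
    st <- stats_report("one-way ANOVA", "m_seconds",
                       an[["F value"]][1], an[["Pr(>F)"]][1],
                       posthoc = as.data.frame(
                         stats::TukeyHSD(fit)$`factor(m_seconds)`
                       ))
  }
  list(table = tab, stats = st)
}

#' Experiment 2: SQI-threshold integration
#'
#' Aligns a pool of pairs under a (typically mixed-quality) condition,
#' computes the sample-level SQI of each pair's noisy search signal, then
#' sweeps the SQI threshold: per threshold it reports the retained fraction
#' and the mean/SD sync delay of the retained samples, plus the Pearson
#' correlation between threshold and mean delay.
#'
#' @param thresholds SQI threshold grid in `[0, 1]`.
#' @param config a [benchmark_config()]; defaults to the mixed preset.
#' @param n_pairs number of pairs in the pool.
#' @param seed integer seed.
#' @param sqi_cfg an [sqi_config()].
#' @return list with `table` (per-pair rows), `summary` (per-threshold mean/SD
#'   delay and retaining ratio; thresholds that retain nothing get `NaN` delay
#'   and are flagged), and `stats` (Pearson correlation report).
#' @export
run_sqi_experiment <- function(thresholds = seq(0, 1, by = 0.1),
                               config = benchmark_preset("mixed"),
                               n_pairs = 100, seed = 1L,
                               sqi_cfg = sqi_config()) {
  if (any(thresholds < 0 | thresholds > 1)) {
    abort_invalid("thresholds must lie in [0, 1]")
  }
  built <- build_pairs(config, n_pairs, seed)
  delays <- numeric(n_pairs)
  sqis <- numeric(n_pairs)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    p <- built$pairs[[i]]
    al <- align_pair(p, config$preprocess)
    # quality is judged on the search signal at the working rate, without the
    # narrow alignment band-pass
    srch250 <- resample_signal(p$search, config$preprocess$target_fs)
    q <- tryCatch(assess_quality(srch250, sqi_cfg),
                  ecgsync_quality_undefined = function(e) NULL)
    sqis[i] <- if (is.null(q)) 0 else q$sample_sqi
    delays[i] <- al$delay
    cond <- built$conds[[p$meta$condition]]
    rows[[length(rows) + 1L]] <- benchmark_row(
      p, config$m, al$delay,
      noise_kind = if (is.null(cond)) NA else cond$kind,
      snr_db = if (is.null(cond)) NA else cond$snr_db,
      fs_hz = config$preprocess$target_fs, sample_sqi = sqis[i], seed = seed
    )
  }
  summ <- do.call(rbind, lapply(thresholds, function(th) {
    f <- sqi_filter(sqis, th)
    kept <- delays[f$retained]
    data.frame(
      sqi_threshold = th,
      mean_delay = if (length(kept)) mean(kept) else NaN,
      sd_delay = if (length(kept) > 1) stats::sd(kept) else NaN,
      retaining_ratio = f$ratio,
      n_retained = sum(f$retained),
      flagged = !length(kept)
    )
  }))
  usable <- !summ$flagged
  if (sum(usable) >= 3) {
    ct <- stats::cor.test(summ$sqi_threshold[usable], summ$mean_delay[usable])
    st <- stats_report("Pearson correlation", "sqi_threshold vs mean delay",
                       unname(ct$estimate), ct$p.value)
  } else {
    st <- stats_report("Pearson correlation", "sqi_threshold vs mean delay",
                       NA_real_, NA_real_, note = "too few usable thresholds")
  }
  list(table = new_benchmark_table(rows), summary = summ, stats = st)
}

#' Experiment 3: noise stress test
#'
#' Full factorial noise kinds x SNR levels; per-cell mean/SD delays; two-way
#' ANOVA with interaction, followed (when the interaction is significant at
#' 0.05) by simple-main-effects ANOVAs of each factor within the levels of
#' the other, and Tukey HSD per factor.
#'
#' @param kinds subset of `c("BW", "EM", "MA")`.
#' @param snrs SNR grid in dB.
#' @param config a [benchmark_config()] (its own `noise` field is ignored).
#' @param pairs_per_cell pairs aligned per kind x SNR cell.
#' @param seed integer seed.
#' @return list with `table`, `cells` (per-cell summaries) and `stats` (main
#'   two-way report with `posthoc` Tukey tables and `simple_effects`).
#' @export
run_noise_experiment <- function(kinds = c("BW", "EM", "MA"),
                                 snrs = c(-6, 0, 6, 12, 18, 24),
                                 config = benchmark_config(),
                                 pairs_per_cell = 30, seed = 1L) {
  if (!all(kinds %in% c("BW", "EM", "MA"))) abort_invalid("unknown noise kind")
  if (!all(is.finite(snrs))) abort_invalid("SNRs must be finite")
  rows <- list()
  cell_id <- 0L
  for (kind in kinds) {
    for (snr in snrs) {
      cell_id <- cell_id + 1L
      cfg <- config
      cfg$noise <- list(kind = kind, snr_db = snr)
      built <- build_pairs(cfg, pairs_per_cell, derive_seed(seed, cell_id))
      for (p in built$pairs) {
        al <- align_pair(p, config$preprocess)
        rows[[length(rows) + 1L]] <- benchmark_row(
          p, config$m, al$delay, noise_kind = kind, snr_db = snr,
          fs_hz = config$preprocess$target_fs, seed = seed
        )
      }
    }
  }
  tab <- new_benchmark_table(rows)
  cells <- stats::aggregate(
    sync_delay_seconds ~ noise_kind + snr_db, data = tab,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x))
  )
  one_level <- length(kinds) < 2L || length(unique(snrs)) < 2L
  if (one_level) {
    fac <- if (length(kinds) >= 2L) "noise_kind" else "snr_db"
    if (length(unique(tab[[fac]])) < 2L) {
      st <- stats_report("ANOVA", fac, NA_real_, NA_real_,
                         note = "single-level design: ANOVA inapplicable")
    } else {
      fit <- stats::aov(sync_delay_seconds ~ factor(tab[[fac]]), data = tab)
      an <- summary(fit)[[1]]
      st <- stats_report("one-way ANOVA (degraded from two-way)", fac,
                         an[["F value"]][1], an[["Pr(>F)"]][1],
                         note = "one factor had a single level")
    }
    return(list(table = tab, cells = cells, stats = st))
  }
  tab$kind_f <- factor(tab$noise_kind)
  tab$snr_f <- factor(tab$snr_db)
  fit <- stats::aov(sync_delay_seconds ~ kind_f * snr_f, data = tab)
  an <- summary(fit)[[1]]
  ia_row <- grep("kind_f:snr_f", rownames(an))
  st <- stats_report(
    "two-way ANOVA", c("noise_kind", "snr_db"),
    c(kind = an[["F value"]][1], snr = an[["F value"]][2],
      interaction = an[["F value"]][ia_row]),
    c(kind = an[["Pr(>F)"]][1], snr = an[["Pr(>F)"]][2],
      interaction = an[["Pr(>F)"]][ia_row])
  )
  tk <- stats::TukeyHSD(stats::aov(sync_delay_seconds ~ kind_f + snr_f, data = tab))
  st$posthoc <- list(kind = as.data.frame(tk$kind_f), snr = as.data.frame(tk$snr_f))
  if (is.finite(st$p_value[["interaction"]]) && st$p_value[["interaction"]] < 0.05) {
    st$simple_effects <- list(
      snr_within_kind = lapply(split(tab, tab$kind_f), function(d) {
        a <- summary(stats::aov(sync_delay_seconds ~ snr_f, data = d))[[1]]
        c(F = a[["F value"]][1], p = a[["Pr(>F)"]][1])
      }),
      kind_within_snr = lapply(split(tab, tab$snr_f), function(d) {
        a <- summary(stats::aov(sync_delay_seconds ~ kind_f, data = d))[[1]]
        c(F = a[["F value"]][1], p = a[["Pr(>F)"]][1])
      })
    )
  }
  tab$kind_f <- NULL
  tab$snr_f <- NULL
  list(table = tab, cells = cells, stats = st)
}

#' Experiment 4: sampling-rate test
#'
#' Builds one pool of pairs, then evaluates the identical pairs at each
#' working rate (the pair is preprocessed to that rate before alignment) and
#' compares rates with a one-way ANOVA.
#'
#' @param rates working rates in Hz; each must exceed twice the band-pass
#'   upper edge.
#' @param config a [benchmark_config()].
#' @param n_pairs pairs in the pool.
#' @param seed integer seed.
#' @return list with `table` and `stats`.
#' @export
run_fs_experiment <- function(rates = c(150, 200, 250),
                              config = benchmark_preset("moderate"),
                              n_pairs = 50, seed = 1L) {
  if (any(rates > config$fs_native)) {
    abort_invalid("rates must not exceed the native rate")
  }
  if (any(rates < 2 * config$preprocess$band_high)) {
    abort_invalid(sprintf(
      "rate below 2 x band_high (%g Hz): filter band infeasible",
      config$preprocess$band_high
    ))
  }
  built <- build_pairs(config, n_pairs, seed)
  rows <- list()
  for (rate in rates) {
    pc <- config$preprocess
    pc$target_fs <- rate
    for (p in built$pairs) {
      al <- align_pair(p, pc)
      cond <- built$conds[[p$meta$condition]]
      rows[[length(rows) + 1L]] <- benchmark_row(
        p, config$m, al$delay,
        noise_kind = if (is.null(cond)) NA else cond$kind,
        snr_db = if (is.null(cond)) NA else cond$snr_db,
        fs_hz = rate, seed = seed
      )
    }
  }
  tab <- new_benchmark_table(rows)
  if (length(rates) < 2L) {
    st <- stats_report("one-way ANOVA", "fs_hz", NA_real_, NA_real_,
                       note = "single rate: ANOVA inapplicable")
  } else {
    fit <- stats::aov(sync_delay_seconds ~ factor(fs_hz), data = tab)
    an <- summary(fit)[[1]]
    st <- stats_report("one-way ANOVA", "fs_hz",
                       an[["F value"]][1], an[["Pr(>F)"]][1])
  }
  list(table = tab, stats = st)
}

#' Experiment 5: comparison with the DTW-on-RR baseline
#'
#' Scores the same pool of pairs with the cross-correlation estimator and
#' with DTW on RR-interval series, then compares the two delay populations
#' with a two-sample Student's t-test.
#'
#' @param config a [benchmark_config()].
#' @param n_pairs pairs in the pool.
#' @param seed integer seed.
#' @param methods two method names from `c("xcorr", "dtw")`; the default
#'   compares the two, but the same method twice is allowed (null case).
#' @return list with `table` (one row per pair per method), `means` and
#'   `stats`.
#' @export
run_method_comparison <- function(config = benchmark_preset("moderate"),
                                  n_pairs = 50, seed = 1L,
                                  methods = c("xcorr", "dtw")) {
  if (length(methods) != 2L || !all(methods %in% c("xcorr", "dtw"))) {
    abort_invalid('`methods` must be two of "xcorr", "dtw"')
  }
  built <- build_pairs(config, n_pairs, seed)
  delay_of <- function(p, method) {
    if (method == "xcorr") return(align_pair(p, config$preprocess)$delay)
    # DTW route: beats are detected on the band-limited working-rate signal
    ref <- preprocess(p$reference, config$preprocess)
    srch <- preprocess(p$search, config$preprocess)
    res <- tryCatch(
      dtw_delay(extract_rr(ref), extract_rr(srch)),
      ecgsync_error = function(e) NULL,
      warning = function(w) suppressWarnings(
        dtw_delay(extract_rr(ref), extract_rr(srch))
      )
    )
    if (is.null(res)) return(NA_real_)
    sync_error(res, p)
  }
  labels <- methods
  if (labels[1] == labels[2]) labels[2] <- paste0(labels[2], "_2")
  rows <- list()
  for (mi in 1:2) {
    for (p in built$pairs) {
      d <- delay_of(p, methods[mi])
      cond <- built$conds[[p$meta$condition]]
      rows[[length(rows) + 1L]] <- benchmark_row(
        p, config$m, d, method = labels[mi],
        noise_kind = if (is.null(cond)) NA else cond$kind,
        snr_db = if (is.null(cond)) NA else cond$snr_db,
        fs_hz = config$preprocess$target_fs, seed = seed
      )
    }
  }
  tab <- new_benchmark_table(rows)
  g <- split(tab$sync_delay_seconds, factor(tab$method, levels = labels))
  g <- lapply(g, function(x) x[is.finite(x)])
  means <- vapply(g, mean, numeric(1))
  if (any(vapply(g, length, integer(1)) < 2L)) {
    st <- stats_report("two-sample t-test", "method", NA_real_, NA_real_,
                       note = "fewer than 2 delays per arm: t-test inapplicable")
  } else if (stats::sd(unlist(g)) == 0) {
    st <- stats_report("two-sample t-test", "method", 0, 1,
                       note = "identical delay populations")
  } else {
    tt <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)
    st <- stats_report("two-sample t-test", "method",
                       unname(tt$statistic), tt$p.value)
  }
  list(table = tab, means = means, stats = st)
}
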