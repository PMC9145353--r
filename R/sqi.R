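#' Dynamic signal-quality index configuration
#'
#' Parameters of the beat-level quality score.  Each detected beat is mapped
#' to a time-frequency magnitude map with a smoothed pseudo Wigner-Ville
#' distribution (SPWVD); a rolling template (mean map of the three preceding
#' beats) is correlated with the map of the current beat, and the sample-level
#' index is the fraction of scored beats whose correlation reaches
#' `good_beat_threshold`.
#'
#' @param window_pre,window_post beat window relative to the R peak, seconds;
#'   the default `(-0.25, +0.45)` covers P-QRS-T at normal rates.
#' @param f_max upper frequency bound of the map in Hz (ECG energy lives
#'   below ~40 Hz).
#' @param n_fft FFT length over the lag axis.
#' @param time_smooth,lag_smooth half-widths of the SPWVD smoothing windows,
#'   seconds; Hamming windows of `2*floor(w*fs)+1` samples are used.
#' @param good_beat_threshold per-beat correlation at or above which a beat
#'   counts as good quality.  Calibrated so clean synthetic records score a
#'   sample SQI of 1.0 while heavily corrupted (-6 dB) records score below
#'   0.5; recalibrate for other devices or settings.
#' @return an object of class `sqi_config`.
#' @export
sqi_config <- function(window_pre = 0.25, window_post = 0.45, f_max = 40,
                       n_fft = 128L, time_smooth = 0.01, lag_smooth = 0.03,
                       good_beat_threshold = 0.9) {
  if (window_pre <= 0 || window_post <= 0) abort_invalid("beat window must be positive")
  if (f_max <= 0) abort_invalid("`f_max` must be positive")
  structure(
    list(
      window_pre = window_pre, window_post = window_post, f_max = f_max,
      n_fft = as.integer(n_fft), time_smooth = time_smooth,
      lag_smooth = lag_smooth, good_beat_threshold = good_beat_threshold
    ),
    class = "sqi_config"
  )
}

# ---- beat detection ---------------------------------------------------------

#' Detect R peaks
#'
#' Energy-based QRS detector: band-pass 5-15 Hz (zero phase), differentiate,
#' square, 150 ms moving-window integration, adaptive threshold on the
#' integrated energy, 200 ms refractory period, then peak refinement on the
#' band-passed amplitude.
#'
#' @param signal an `ecg_signal`, at least 5 s long, `fs >= 100` Hz.
#' @return an object of class `beat_annotation` with fields `r_samples`
#'   (1-based, strictly increasing sample indices) and `fs`.  An empty
#'   annotation (with a warning) if no beats are found.
#' @export
detect_beats <- function(signal) {
  assert_signal(signal)
  fs <- signal$fs
  if (fs < 100) abort_invalid("`fs` must be >= 100 Hz for beat detection")
  if (signal_duration(signal) < 5) abort_invalid("signal must be >= 5 s long")
  cfg <- preprocess_config(target_fs = fs, band_low = 5, band_high = 15,
                           filter_order = 2, normalize = FALSE)
  f <- bandpass_zero_phase(signal, cfg)$samples
  d <- c(diff(f), 0) * fs
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ <- as.numeric(integ)
  integ[is.na(integ)] <- 0
  n <- length(integ)
  refractory <- round(0.2 * fs)
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  empty <- function() {
    warning("no beats detected; downstream SQI is undefined")
    structure(list(r_samples = integer(0), fs = fs), class = "beat_annotation")
  }
  if (!length(cand)) return(empty())
  h <- integ[cand]
  top <- h[h >= stats::quantile(h, 0.7)]
  thr <- 0.2 * stats::median(top)
  if (!is.finite(thr) || thr <= 0) return(empty())
  keep <- cand[h > thr]
  # greedy refractory enforcement, strongest peaks first
  keep <- keep[order(integ[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep) if (!length(sel) || all(abs(sel - i) >= refractory)) sel <- c(sel, i)
  sel <- sort(sel)
  # refine to the band-passed amplitude extremum within +-80 ms
  r <- round(0.08 * fs)
  out <- vapply(sel, function(i) {
    a <- max(1L, i - r)
    b <- min(n, i + r)
    as.integer(a - 1L + which.max(abs(f[a:b])))
  }, integer(1))
  out <- sort(unique(out))
  # refinement can merge neighbours; re-enforce the refractory gap
  if (length(out) > 1L) {
    keep2 <- c(TRUE, diff(out) >= refractory)
    out <- out[keep2]
  }
  structure(list(r_samples = out, fs = fs), class = "beat_annotation")
}

#' @export
print.beat_annotation <- function(x, ...) {
  cat(sprintf("<beat_annotation> %d beats at %g Hz\n", length(x$r_samples), x$fs))
  invisible(x)
}

# ---- SPWVD ------------------------------------------------------------------

# Analytic extension via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# centered moving-average smoothing of a complex sequence (stats::filter
# drops imaginary parts, so smooth the two parts separately)
smooth_complex <- function(z, g) {
  re <- stats::filter(Re(z), g, sides = 2)
  im <- stats::filter(Im(z), g, sides = 2)
  re <- as.numeric(re); im <- as.numeric(im)
  re[is.na(re)] <- 0; im[is.na(im)] <- 0
  complex(real = re, imaginary = im)
}

#' SPWVD time-frequency map of one beat
#'
#' Discrete smoothed pseudo Wigner-Ville distribution of the analytic
#' extension of the beat window `(R - window_pre, R + window_post)`, with a
#' separable Hamming time-smoothing window and Hamming lag window.  The
#' magnitude is kept and the frequency axis is truncated to `[0, f_max]` Hz.
#' Being bilinear, scaling the beat by `a` scales the map by `a^2`; the
#' normalized correlation score downstream is unaffected.
#'
#' @param signal an `ecg_signal`.
#' @param r_index 1-based sample index of the R peak.
#' @param cfg an [sqi_config()].
#' @return a non-negative matrix, frequency bins (rows, 0 to `f_max` Hz) by
#'   beat-window samples (columns).  Errors with a `ecgsync_beat_window_oob`
#'   condition when the window does not fit in the record.
#' @export
beat_tfmap <- function(signal, r_index, cfg = sqi_config()) {
  assert_signal(signal)
  fs <- signal$fs
  pre <- round(cfg$window_pre * fs)
  post <- round(cfg$window_post * fs)
  if (r_index - pre < 1 || r_index + post > length(signal$samples)) {
    abort_oob(sprintf("beat window around sample %d outside record", r_index))
  }
  xw <- signal$samples[(r_index - pre):(r_index + post)]
  z <- analytic_signal(xw - mean(xw))
  nw <- length(z)
  m_lag <- max(1L, floor(cfg$lag_smooth * fs))
  lg <- 2L * max(0L, floor(cfg$time_smooth * fs)) + 1L
  g <- signal::hamming(lg); g <- g / sum(g)
  hwin <- signal::hamming(2L * m_lag + 1L)
  nfft <- cfg$n_fft
  A <- matrix(0 + 0i, nrow = nfft, ncol = nw)
  for (tau in 0:m_lag) {
    zl <- c(rep(0i, tau), z[seq_len(nw - tau)])       # z[n - tau]
    zr <- c(z[(tau + 1):nw], rep(0i, tau))            # z[n + tau]
    k <- zr * Conj(zl)
    k <- if (lg > 1L) smooth_complex(k, g) else k
    k <- k * hwin[m_lag + 1L + tau]
    A[tau + 1L, ] <- A[tau + 1L, ] + k
    if (tau > 0L) A[nfft + 1L - tau, ] <- Conj(k)
  }
  W <- Re(stats::mvfft(A))
  freqs <- (0:(nfft - 1)) * fs / (2 * nfft)
  abs(W[freqs <= cfg$f_max, , drop = FALSE])
}

# ---- beat scoring -----------------------------------------------------------

#' Per-beat quality scores by rolling template matching
#'
#' For every beat `k >= 4`, the template is the elementwise mean of the SPWVD
#' maps of beats `k-3, k-2, k-1`; the score of beat `k` is the zero-lag 2-D
#' Pearson correlation between the template and its own map.  The first three
#' usable beats have no template and stay unscored.  Beats whose window does
#' not fit inside the record are skipped.
#'
#' @param signal an `ecg_signal`.
#' @param beats a `beat_annotation` (defaults to [detect_beats()] output).
#' @param cfg an [sqi_config()].
#' @return an object of class `quality_report` with fields `beat_index`,
#'   `r_samples`, `scores` (NA for the unscored leading beats), `n_scored`,
#'   `fs`.  Errors with `ecgsync_quality_undefined` if fewer than 4 usable
#'   beats exist.
#' @export
beat_scores <- function(signal, beats = detect_beats(signal), cfg = sqi_config()) {
  assert_signal(signal)
  if (!inherits(beats, "beat_annotation")) {
    abort_invalid("`beats` must be a `beat_annotation`")
  }
  tfs <- vector("list", length(beats$r_samples))
  ok <- logical(length(tfs))
  for (i in seq_along(tfs)) {
    tf <- tryCatch(beat_tfmap(signal, beats$r_samples[i], cfg),
                   ecgsync_beat_window_oob = function(e) NULL)
    tfs[i] <- list(tf) # keep NULLs in place
    ok[i] <- !is.null(tf)
  }
  r_use <- beats$r_samples[ok]
  tfs <- tfs[ok]
  if (length(r_use) < 4L) {
    abort_quality(sprintf(
      "quality undefined: %d usable beats (need >= 4)", length(r_use)
    ))
  }
  scores <- rep(NA_real_, length(r_use))
  for (k in 4:length(r_use)) {
    tmpl <- (tfs[[k - 3]] + tfs[[k - 2]] + tfs[[k - 1]]) / 3
    scores[k] <- stats::cor(as.vector(tmpl), as.vector(tfs[[k]]))
  }
  structure(
    list(
      beat_index = seq_along(r_use),
      r_samples = r_use,
      scores = scores,
      n_scored = sum(!is.na(scores)),
      fs = signal$fs
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  sc <- x$scores[!is.na(x$scores)]
  cat(sprintf(
    "<quality_report> %d beats, %d scored; score range [%.3f, %.3f]\n",
    length(x$r_samples), x$n_scored,
    if (length(sc)) min(sc) else NA, if (length(sc)) max(sc) else NA
  ))
  invisible(x)
}

#' Sample-level SQI: fraction of good-quality beats
#'
#' @param report a `quality_report` from [beat_scores()].
#' @param threshold_good per-beat score at or above which a beat counts as
#'   good.
#' @return fraction in `[0, 1]` of scored beats at or above the threshold.
#' @export
sample_sqi <- function(report, threshold_good = 0.9) {
  if (!inherits(report, "quality_report")) {
    abort_invalid("`report` must be a `quality_report`")
  }
  sc <- report$scores[!is.na(report$scores)]
  if (!length(sc)) abort_quality("no scored beats: sample SQI undefined")
  mean(sc >= threshold_good)
}

#' One-call quality assessment
#'
#' Beat detection, beat scoring and the sample-level SQI in one step.
#'
#' @param signal an `ecg_signal` (typically resampled to the working rate but
#'   not band-passed to the narrow alignment band, which would destroy the
#'   morphology being scored).
#' @param cfg an [sqi_config()].
#' @return the `quality_report` with an extra field `sample_sqi`.
#' @export
assess_quality <- function(signal, cfg = sqi_config()) {
  rep <- beat_scores(signal, detect_beats(signal), cfg)
  rep$sample_sqi <- sample_sqi(rep, cfg$good_beat_threshold)
  rep$threshold_good <- cfg$good_beat_threshold
  rep
}

#' Filter samples by SQI threshold
#'
#' Retains samples whose sample-level SQI is at or above the threshold and
#' reports the retained fraction (threshold 0 retains everything).
#'
#' @param sqis numeric vector of per-sample SQI values in `[0, 1]`.
#' @param sqi_threshold scalar threshold in `[0, 1]`.
#' @return list with `retained` (logical vector) and `ratio` (retained
#'   fraction).
#' @export
sqi_filter <- function(sqis, sqi_threshold) {
  if (!is.numeric(sqis)) abort_invalid("`sqis` must be numeric")
  if (sqi_threshold < 0 || sqi_threshold > 1) {
    abort_invalid("`sqi_threshold` must be in [0, 1]")
  }
  retained <- sqis >= sqi_threshold
  list(retained = retained, ratio = mean(retained))
}
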