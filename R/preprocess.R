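#' Preprocessing configuration
#'
#' Parameters of the three-step conditioning chain applied before alignment:
#' resample to a common working rate, band-pass with a zero-phase Butterworth
#' filter, min-max normalize.  The defaults (250 Hz working rate, 2-10 Hz
#' second-order band-pass) suppress baseline wander below the band and
#' muscle/powerline noise above it while keeping the QRS energy that carries
#' the alignment information.
#'
#' @param target_fs working sampling rate in Hz.
#' @param band_low,band_high band-pass edges in Hz; must satisfy
#'   `0 < band_low < band_high < target_fs / 2`.
#' @param filter_order Butterworth order of the single pass (the effective
#'   magnitude response after forward-backward application is the square).
#' @param normalize whether to min-max normalize after filtering.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 250, band_low = 2, band_high = 10,
                              filter_order = 2, normalize = TRUE) {
  if (!is.numeric(target_fs) || target_fs <= 0) {
    abort_invalid("`target_fs` must be positive")
  }
  if (!(band_low > 0 && band_low < band_high && band_high < target_fs / 2)) {
    abort_invalid("need 0 < band_low < band_high < target_fs/2")
  }
  if (filter_order < 1) abort_invalid("`filter_order` must be >= 1")
  structure(
    list(
      target_fs = as.double(target_fs),
      band_low = as.double(band_low),
      band_high = as.double(band_high),
      filter_order = as.integer(filter_order),
      normalize = isTRUE(normalize)
    ),
    class = "preprocess_config"
  )
}

# ---- rational polyphase resampling -----------------------------------------

# Express target_fs / fs as a reduced integer ratio p/q.  Non-integer rates are
# scaled by powers of ten (up to 1e3) before reduction.
rate_ratio <- function(fs, target_fs) {
  scale <- 1
  while (scale <= 1000 &&
         (abs(fs * scale - round(fs * scale)) > 1e-9 ||
          abs(target_fs * scale - round(target_fs * scale)) > 1e-9)) {
    scale <- scale * 10
  }
  a <- round(target_fs * scale)
  b <- round(fs * scale)
  g <- gcd_int(a, b)
  c(p = a / g, q = b / g)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Kaiser-windowed sinc low-pass for polyphase resampling, centered (zero
# phase), gain p in the passband.  Cached per (p, q).
.resample_cache <- new.env(parent = emptyenv())

resample_filter <- function(p, q, halfwidth = 10L, beta = 5.0) {
  key <- paste(p, q, sep = "/")
  if (!is.null(.resample_cache[[key]])) return(.resample_cache[[key]])
  m <- max(p, q)
  L <- 2L * halfwidth * m + 1L
  c0 <- (L - 1L) / 2
  k <- (0:(L - 1L)) - c0
  fc <- 1 / m # cutoff on the p-fold upsampled grid (Nyquist = 1)
  h <- ifelse(k == 0, fc, sin(pi * fc * k) / (pi * k))
  w <- besselI(beta * sqrt(pmax(0, 1 - (k / c0)^2)), 0) / besselI(beta, 0)
  h <- h * w * p
  .resample_cache[[key]] <- h
  h
}

resample_core <- function(x, p, q) {
  if (p == q) return(x)
  h <- resample_filter(p, q)
  L <- length(h)
  c0 <- (L - 1L) %/% 2L
  nx <- length(x)
  n_out <- ceiling(nx * p / q)
  m <- 0:(n_out - 1L)
  pos <- m * q + c0
  i_hi <- pmin(floor(pos / p), nx - 1L)
  K <- ceiling(L / p) + 1L
  y <- numeric(n_out)
  for (k in 0:(K - 1L)) {
    i <- i_hi - k
    j0 <- pos - i * p
    ok <- i >= 0L & j0 >= 0L & j0 < L
    if (!any(ok)) next
    y[ok] <- y[ok] + h[j0[ok] + 1L] * x[i[ok] + 1L]
  }
  y
}

#' Resample a signal to a new rate
#'
#' Polyphase rational resampling (e.g. 257 to 250 Hz via up-250 / down-257)
#' with a Kaiser-windowed sinc anti-aliasing low-pass.  The filter taps are
#' centered, so the operation is zero-phase and sample 0 stays at `t0`.
#'
#' @param signal an `ecg_signal`.
#' @param target_fs new sampling rate in Hz (> 0).
#' @return an `ecg_signal` at `target_fs` spanning the same duration (within
#'   one output sample); metadata preserved.
#' @export
resample_signal <- function(signal, target_fs) {
  assert_signal(signal)
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      !is.finite(target_fs) || target_fs <= 0) {
    abort_invalid("`target_fs` must be a single positive number")
  }
  if (isTRUE(all.equal(target_fs, signal$fs))) return(signal)
  pq <- rate_ratio(signal$fs, target_fs)
  y <- resample_core(signal$samples, pq[["p"]], pq[["q"]])
  new_signal(y, target_fs, t0 = signal$t0, label = signal$label)
}

# ---- zero-phase Butterworth band-pass --------------------------------------

.butter_cache <- new.env(parent = emptyenv())

butter_coefs <- function(order, low, high, fs) {
  key <- paste(order, low, high, fs, sep = "/")
  if (is.null(.butter_cache[[key]])) {
    .butter_cache[[key]] <- signal::butter(order, c(low, high) / (fs / 2),
                                           type = "pass")
  }
  .butter_cache[[key]]
}

# Effective impulse-response length from the slowest pole (decay to 0.1%).
filter_startup_len <- function(ba) {
  r <- max(Mod(polyroot(rev(ba$a))))
  if (r >= 1) return(length(ba$a) * 100L)
  max(length(ba$a), ceiling(log(1e-3) / log(r)))
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the configured Butterworth band-pass forward and then backward so
#' the net phase shift is zero -- filtering must not be able to bias the
#' estimated lag.  Startup transients are suppressed by odd-reflection padding
#' of three effective impulse-response lengths at each end; the padding is
#' discarded after filtering.
#'
#' @param signal an `ecg_signal`.
#' @param cfg a [preprocess_config()].
#' @return filtered `ecg_signal`, same length and rate as the input.
#' @export
bandpass_zero_phase <- function(signal, cfg = preprocess_config()) {
  assert_signal(signal)
  fs <- signal$fs
  if (cfg$band_high >= fs / 2) {
    abort_invalid(sprintf(
      "band edge %g Hz is at or above the Nyquist rate %g Hz",
      cfg$band_high, fs / 2
    ))
  }
  ba <- butter_coefs(cfg$filter_order, cfg$band_low, cfg$band_high, fs)
  n_ir <- filter_startup_len(ba)
  x <- signal$samples
  n <- length(x)
  if (n <= 3L * min(n_ir, n)) {
    # allow short-but-workable inputs by shrinking the pad, refuse tiny ones
    if (n < 12L * length(ba$a)) {
      abort_length(sprintf(
        "signal too short for zero-phase filtering (%d samples; need > %d)",
        n, 12L * length(ba$a)
      ))
    }
  }
  np <- min(3L * n_ir, n - 1L)
  xs <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  y <- signal::filtfilt(ba, xs)
  new_signal(y[(np + 1L):(np + n)], fs, t0 = signal$t0, label = signal$label)
}

#' Min-max normalization
#'
#' Maps the sample range to `[0, 1]` so that samples from leads with
#' different gains are on an equal footing.  Invariant under positive affine
#' transforms of the input.
#'
#' @param signal an `ecg_signal` with non-zero dynamic range.
#' @return normalized `ecg_signal`.
#' @export
minmax_normalize <- function(signal) {
  assert_signal(signal)
  rng <- range(signal$samples)
  if (rng[2] == rng[1]) {
    abort_degenerate("constant signal: min-max normalization undefined")
  }
  new_signal((signal$samples - rng[1]) / (rng[2] - rng[1]),
             signal$fs, t0 = signal$t0, label = signal$label)
}

#' Full preprocessing chain
#'
#' Resample to the working rate, band-pass zero-phase, min-max normalize --
#' in that order.  Metadata (`t0`, `label`) is preserved.
#'
#' @param signal an `ecg_signal`.
#' @param cfg a [preprocess_config()].
#' @return preprocessed `ecg_signal` at `cfg$target_fs`.
#' @export
preprocess <- function(signal, cfg = preprocess_config()) {
  assert_signal(signal)
  out <- resample_signal(signal, cfg$target_fs)
  out <- bandpass_zero_phase(out, cfg)
  if (cfg$normalize) out <- minmax_normalize(out)
  out
}
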