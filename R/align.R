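#' Correlation-versus-lag curve
#'
#' Slides the reference over the search signal one sample at a time and
#' records one correlation value per integer lag `k` in
#' `0 .. length(search) - length(reference)` ("valid" overlap only: the
#' reference window always lies fully inside the search signal).
#'
#' Mode `"pearson"` computes the Pearson coefficient between the reference and
#' the equally long search window starting at lag `k`; a zero-variance window
#' yields the sentinel `-Inf` so it can never be selected as the peak.  Mode
#' `"raw"` computes the plain inner product of the two windows (unnormalized
#' cross-correlation).
#'
#' The implementation uses FFT cross-correlation plus cumulative window sums;
#' it is pinned by tests to a brute-force per-lag loop at 1e-10.
#'
#' @param reference an `ecg_signal`, the short sample.
#' @param search an `ecg_signal` at the same rate, at least as long.
#' @param mode `"pearson"` (default) or `"raw"`.
#' @return a `data.frame` with columns `lag_samples`, `lag_seconds`, `r`.
#' @export
correlation_curve <- function(reference, search, mode = c("pearson", "raw")) {
  assert_signal(reference, "reference")
  assert_signal(search, "search")
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(reference$fs, search$fs))) {
    abort_invalid(sprintf(
      "sampling rates differ: reference %g Hz vs search %g Hz",
      reference$fs, search$fs
    ))
  }
  ref <- reference$samples
  srch <- search$samples
  n <- length(ref)
  N <- length(srch)
  if (n > N) abort_invalid("reference is longer than search signal")
  K <- N - n
  L <- stats::nextn(N + n, c(2, 3, 5))
  fr <- stats::fft(c(ref, numeric(L - n)))
  fsrch <- stats::fft(c(srch, numeric(L - N)))
  cc <- Re(stats::fft(fsrch * Conj(fr), inverse = TRUE)) / L
  num <- cc[1:(K + 1)] # num[k+1] = sum_j search[j+k] * ref[j]
  if (mode == "raw") {
    r <- num
  } else {
    cs1 <- cumsum(c(0, srch))
    cs2 <- cumsum(c(0, srch^2))
    s1 <- cs1[(n + 1):(N + 1)] - cs1[1:(K + 1)]
    s2 <- cs2[(n + 1):(N + 1)] - cs2[1:(K + 1)]
    mr <- mean(ref)
    ssr <- sum((ref - mr)^2)
    den2 <- pmax(s2 - s1^2 / n, 0) * ssr
    r <- ifelse(den2 > 0, (num - mr * s1) / sqrt(den2), -Inf)
  }
  data.frame(
    lag_samples = 0:K,
    lag_seconds = (0:K) / reference$fs,
    r = r
  )
}

#' Estimate the sync delay between two signals
#'
#' The estimated lag is the position of the correlation peak: the time offset
#' from the start of the search signal at which the reference matches best.
#' Ties at the maximum break toward the smallest lag.
#'
#' @inheritParams correlation_curve
#' @return an object of class `sync_result` with fields `lag_seconds`,
#'   `lag_samples`, `peak_r`, `curve` (the full data.frame from
#'   [correlation_curve()]) and `mode`.
#' @export
estimate_sync_delay <- function(reference, search, mode = c("pearson", "raw")) {
  mode <- match.arg(mode)
  curve <- correlation_curve(reference, search, mode)
  i <- which.max(curve$r) # first index at ties -> smallest lag
  structure(
    list(
      lag_seconds = curve$lag_seconds[i],
      lag_samples = curve$lag_samples[i],
      peak_r = curve$r[i],
      curve = curve,
      mode = mode
    ),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "<sync_result> lag = %.4f s (%d samples), peak r = %.4f, mode = %s\n",
    x$lag_seconds, x$lag_samples, x$peak_r, x$mode
  ))
  invisible(x)
}

#' Sync-delay error against ground truth
#'
#' Absolute deviation of the estimated lag from the known true lag of a
#' sample pair -- the study's performance metric.
#'
#' @param result a `sync_result`.
#' @param pair a `sample_pair` (see [select_samples()]), or a number giving
#'   the true lag in seconds.
#' @return non-negative numeric scalar (seconds).
#' @export
sync_error <- function(result, pair) {
  if (!inherits(result, "sync_result")) {
    abort_invalid("`result` must be a `sync_result`")
  }
  true_lag <- if (inherits(pair, "sample_pair")) pair$true_lag else as.double(pair)
  abs(result$lag_seconds - true_lag)
}
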