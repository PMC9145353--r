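#' Extract the RR-interval series of an ECG signal
#'
#' Detects R peaks and returns successive inter-beat intervals together with
#' the time of the first beat of each interval (on the record's clock).
#'
#' @param signal an `ecg_signal`.
#' @return an object of class `rr_series` with fields `intervals` (seconds),
#'   `beat_times` (seconds, same length) and `t0` (the signal's start time,
#'   kept so delay estimates can be referred to the signal's own clock).
#' @export
extract_rr <- function(signal) {
  assert_signal(signal)
  beats <- detect_beats(signal)
  if (length(beats$r_samples) < 3L) {
    abort_invalid(sprintf(
      "need >= 3 detected beats for an RR series (got %d)",
      length(beats$r_samples)
    ))
  }
  times <- signal$t0 + (beats$r_samples - 1) / signal$fs
  structure(
    list(intervals = diff(times), beat_times = times[-length(times)],
         t0 = signal$t0),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d intervals, mean RR %.3f s\n",
    length(x$intervals), mean(x$intervals)
  ))
  invisible(x)
}

# subsequence DTW: every reference interval must be matched; the path may
# start and end anywhere on the search side.  Euclidean local cost, symmetric
# steps (diagonal / down / right).
dtw_subsequence <- function(a, b) {
  n <- length(a)
  m <- length(b)
  cost <- outer(a, b, function(x, y) abs(x - y))
  D <- matrix(Inf, n, m)
  D[1, ] <- cost[1, ] # open begin: free start column
  for (i in 2:n) {
    # D[i, j] = cost[i, j] + min(D[i-1, j], D[i-1, j-1], D[i, j-1])
    up <- D[i - 1, ]
    diag_ <- c(Inf, D[i - 1, -m])
    best <- pmin(up, diag_)
    row <- numeric(m)
    prev_left <- Inf
    for (j in 1:m) {
      row[j] <- cost[i, j] + min(best[j], prev_left)
      prev_left <- row[j]
    }
    D[i, ] <- row
  }
  j_end <- which.min(D[n, ]) # open end
  # traceback
  path_i <- integer(0)
  path_j <- integer(0)
  i <- n
  j <- j_end
  repeat {
    path_i <- c(i, path_i)
    path_j <- c(j, path_j)
    if (i == 1L) break
    choices <- c(
      if (j > 1L) D[i - 1L, j - 1L] else Inf, # diagonal
      D[i - 1L, j],                            # up
      if (j > 1L) D[i, j - 1L] else Inf        # left
    )
    k <- which.min(choices)
    if (k == 1L) { i <- i - 1L; j <- j - 1L }
    else if (k == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(i = path_i, j = path_j, distance = D[n, j_end])
}

#' Delay estimation by DTW on RR intervals
#'
#' The comparator method: z-normalized RR sequences of the two signals are
#' aligned with open-begin/open-end (subsequence) dynamic time warping using
#' Euclidean local cost; the estimated lag is the median, over warping-path
#' pairs `(p, q)`, of the beat-time offset
#' `search_time(q) - ref_time(p)`, reported in the same convention as
#' [estimate_sync_delay()] (position of the reference's start within the
#' search signal).
#'
#' Both leads record the same heart, so RR intervals are directly comparable
#' in seconds and the default cost works on raw intervals.  `normalize = "z"`
#' additionally z-scores each sequence first; note that with a subsequence
#' search the surrounding rhythm shifts the search sequence's mean and SD, so
#' z-scoring can distort the match and is kept only as an option.
#'
#' @param ref_rr `rr_series` of the reference signal.
#' @param search_rr `rr_series` of the search signal; must span more time
#'   than the reference.
#' @param normalize `"none"` (default) or `"z"`.
#' @return a `sync_result` with `mode = "dtw"` (no correlation curve).
#' @export
dtw_delay <- function(ref_rr, search_rr, normalize = c("none", "z")) {
  normalize <- match.arg(normalize)
  if (!inherits(ref_rr, "rr_series") || !inherits(search_rr, "rr_series")) {
    abort_invalid("inputs must be `rr_series`")
  }
  span_ref <- diff(range(ref_rr$beat_times))
  span_srch <- diff(range(search_rr$beat_times))
  if (span_ref > span_srch) {
    abort_invalid("reference RR series spans more time than the search series")
  }
  a <- ref_rr$intervals
  b <- search_rr$intervals
  if (normalize == "z") {
    sa <- stats::sd(a)
    sb <- stats::sd(b)
    if (!is.finite(sa) || sa == 0 || !is.finite(sb) || sb == 0) {
      warning("constant RR series; DTW falls back to unnormalized cost")
    } else {
      a <- (a - mean(a)) / sa
      b <- (b - mean(b)) / sb
    }
  }
  path <- dtw_subsequence(a, b)
  # beat times are referred to each signal's own start so that the lag shares
  # the cross-correlation convention: offset of the reference's start from the
  # start of the search signal
  t_ref <- ref_rr$beat_times - ref_rr$t0
  t_srch <- search_rr$beat_times - search_rr$t0
  lag <- stats::median(t_srch[path$j] - t_ref[path$i])
  structure(
    list(
      lag_seconds = lag,
      lag_samples = NA_integer_,
      peak_r = NA_real_,
      curve = NULL,
      mode = "dtw",
      path = path
    ),
    class = "sync_result"
  )
}
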