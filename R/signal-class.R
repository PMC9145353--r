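#' Uniformly sampled signal
#'
#' The basic container used throughout the package: a real-valued amplitude
#' sequence with a sampling rate, a start time on the record's clock, and a
#' free-text channel label.  The time of sample `n` (0-based) is
#' `t0 + n / fs`.
#'
#' @param samples numeric vector of amplitudes (mV or normalized units); must
#'   be finite and non-empty.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time in seconds on the record's clock.
#' @param label free-text channel name, e.g. `"I"` or `"V2"`.
#' @return an object of class `ecg_signal` with fields `samples`, `fs`, `t0`,
#'   `label`.
#' @examples
#' s <- new_signal(sin(2 * pi * 5 * (0:999) / 250), fs = 250, label = "I")
#' signal_duration(s)
#' @export
new_signal <- function(samples, fs, t0 = 0, label = "") {
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort_invalid("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) abort_invalid("`samples` must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort_invalid("`fs` must be a single positive number (Hz)")
  }
  structure(
    list(
      samples = as.double(samples),
      fs = as.double(fs),
      t0 = as.double(t0),
      label = as.character(label)[1L]
    ),
    class = "ecg_signal"
  )
}

is_signal <- function(x) inherits(x, "ecg_signal")

assert_signal <- function(x, arg = "signal") {
  if (!is_signal(x)) abort_invalid(sprintf("`%s` must be an `ecg_signal`", arg))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param x an `ecg_signal`.
#' @export
signal_duration <- function(x) {
  assert_signal(x, "x")
  length(x$samples) / x$fs
}

#' Sample times of a signal
#'
#' Returns the time of every sample on the record's clock,
#' `t0 + (0:(n-1)) / fs`.
#' @param x an `ecg_signal`.
#' @export
signal_times <- function(x) {
  assert_signal(x, "x")
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Cut a window out of a signal
#'
#' Half-open window `[from, to)` in seconds on the record's clock.
#' @param x an `ecg_signal`.
#' @param from,to window bounds in seconds (record clock).
#' @return an `ecg_signal` whose `t0` is the time of its first sample.
#' @export
signal_window <- function(x, from, to) {
  assert_signal(x, "x")
  if (to <= from) abort_invalid("`to` must be greater than `from`")
  i0 <- round((from - x$t0) * x$fs)
  i1 <- round((to - x$t0) * x$fs) # exclusive
  if (i0 < 0 || i1 > length(x$samples)) {
    abort_invalid(sprintf(
      "window [%g, %g) outside record span [%g, %g)",
      from, to, x$t0, x$t0 + signal_duration(x)
    ))
  }
  new_signal(x$samples[(i0 + 1L):i1], x$fs, t0 = x$t0 + i0 / x$fs, label = x$label)
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf(
    "<ecg_signal> label=%s fs=%g Hz n=%d duration=%.3f s t0=%.3f s\n",
    if (nzchar(x$label)) x$label else "?", x$fs, length(x$samples),
    signal_duration(x), x$t0
  ))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)
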