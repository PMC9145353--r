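# Independent brute-force oracles, deliberately written as plain per-lag /
# closed-form computations so they share no code with the package fast paths.

# Pearson / raw correlation at every valid lag by direct loop.
brute_curve <- function(ref, search, mode = "pearson") {
  n <- length(ref)
  K <- length(search) - n
  vapply(0:K, function(k) {
    win <- search[(k + 1):(k + n)]
    if (mode == "raw") return(sum(ref * win))
    if (stats::sd(win) == 0) return(-Inf)
    suppressWarnings(stats::cor(ref, win))
  }, numeric(1))
}

# squared magnitude response of an analog-prototype Butterworth band-pass
# digitized by the bilinear transform, evaluated at frequency f (Hz):
# computed from the digital coefficients via the transfer function, which is
# closed-form and independent of any filtering code path.
butter_bp_mag2 <- function(f, fs, low = 2, high = 10, order = 2) {
  ba <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  z <- exp(1i * w)
  H <- sum(ba$b * z^-(seq_along(ba$b) - 1)) /
    sum(ba$a * z^-(seq_along(ba$a) - 1))
  Mod(H)^2 # forward-backward filtering applies |H|^2
}

# power fraction of a signal inside [flo, fhi] Hz from the periodogram
band_power_fraction <- function(x, fs, flo, fhi) {
  sp <- Mod(stats::fft(x))^2
  f <- (0:(length(x) - 1)) * fs / length(x)
  half <- f <= fs / 2 & f > 0
  sum(sp[half & f >= flo & f <= fhi]) / sum(sp[half])
}
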