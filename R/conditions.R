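# Classed conditions so callers (and tests) can distinguish failure modes.

abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ecgsync_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_invalid <- function(msg) abort(msg, "ecgsync_invalid_argument")
abort_degenerate <- function(msg) abort(msg, "ecgsync_degenerate_signal")
abort_length <- function(msg) abort(msg, "ecgsync_length_error")
abort_quality <- function(msg) abort(msg, "ecgsync_quality_undefined")
abort_oob <- function(msg) abort(msg, "ecgsync_beat_window_oob")
abort_io <- function(msg) abort(msg, "ecgsync_io_error")

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.  All generators funnel through this so that every
# artifact is a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_invalid("`seed` must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic sub-seed streams (kept below 2^31).
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647)
}
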