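#' Read a physiological record
#'
#' Two on-disk layouts are supported.
#'
#' \strong{WFDB}: a text header `<record>.hea` plus an interleaved 16-bit
#' little-endian `<record>.dat` (signal format 16).  Amplitudes are converted
#' to physical units with each channel's gain and baseline from the header.
#'
#' \strong{CSV}: one file per channel with header `t_seconds,amplitude`
#' (UTF-8, "." decimal); the sampling rate is inferred from the median time
#' step and `t0` from the first row.
#'
#' @param path record path: for WFDB the header path or the path without
#'   extension; for CSV a single file.
#' @param format `"wfdb"` or `"csv"`.
#' @param channels channel names to return (WFDB only); `NULL` for all.
#' @return a named list of `ecg_signal`, one per channel.
#' @export
read_record <- function(path, format = c("wfdb", "csv"), channels = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
    df <- utils::read.csv(path)
    if (!all(c("t_seconds", "amplitude") %in% names(df))) {
      abort_io("CSV must have columns t_seconds,amplitude")
    }
    if (nrow(df) < 2L) abort_io("CSV needs at least two samples")
    dt <- stats::median(diff(df$t_seconds))
    if (!is.finite(dt) || dt <= 0) abort_io("non-increasing time column")
    label <- sub("\\.csv$", "", basename(path))
    sig <- new_signal(df$amplitude, fs = 1 / dt, t0 = df$t_seconds[1],
                      label = label)
    out <- list(sig)
    names(out) <- label
    return(out)
  }
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort_io(sprintf("no such header: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) abort_io(sprintf("%s: empty header", hea))
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3L) abort_io(sprintf("%s line 1: need 'name nsig fs [n]'", hea))
  nsig <- suppressWarnings(as.integer(top[2]))
  fs <- suppressWarnings(as.numeric(top[3]))
  if (is.na(nsig) || is.na(fs) || fs <= 0) {
    abort_io(sprintf("%s line 1: bad signal count or sampling rate", hea))
  }
  if (length(lines) < 1L + nsig) {
    abort_io(sprintf("%s: header declares %d signals but has %d signal lines",
                     hea, nsig, length(lines) - 1L))
  }
  specs <- lapply(seq_len(nsig), function(i) {
    ln <- strsplit(trimws(lines[1L + i]), "\\s+")[[1]]
    if (length(ln) < 3L) {
      abort_io(sprintf("%s line %d: malformed signal line", hea, 1L + i))
    }
    fmt <- sub("x.*", "", ln[2])
    if (fmt != "16") {
      abort_io(sprintf("%s line %d: only signal format 16 is supported (got %s)",
                       hea, 1L + i, ln[2]))
    }
    gb <- ln[3] # gain(baseline)/units
    gain <- suppressWarnings(as.numeric(sub("[(/].*$", "", gb)))
    baseline <- 0
    if (grepl("\\(", gb)) {
      baseline <- suppressWarnings(as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gb)))
    }
    if (is.na(gain) || gain == 0) {
      abort_io(sprintf("%s line %d: bad gain field '%s'", hea, 1L + i, gb))
    }
    desc <- if (length(ln) >= 9L) paste(ln[9:length(ln)], collapse = " ") else
      sprintf("ch%d", i)
    list(file = ln[1], gain = gain, baseline = baseline, label = desc)
  })
  labels <- vapply(specs, `[[`, character(1), "label")
  dat <- file.path(dirname(hea), specs[[1]]$file)
  if (!file.exists(dat)) abort_io(sprintf("no such signal file: %s", dat))
  raw_n <- file.info(dat)$size %/% 2L
  adc <- readBin(dat, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  n_per <- length(adc) %/% nsig
  adc <- matrix(adc[seq_len(n_per * nsig)], nrow = nsig)
  want <- if (is.null(channels)) labels else channels
  missing_ch <- setdiff(want, labels)
  if (length(missing_ch)) {
    abort_io(sprintf("channel(s) %s not found; available: %s",
                     paste(missing_ch, collapse = ", "),
                     paste(labels, collapse = ", ")))
  }
  out <- lapply(want, function(ch) {
    i <- match(ch, labels)
    new_signal((adc[i, ] - specs[[i]]$baseline) / specs[[i]]$gain, fs,
               t0 = 0, label = ch)
  })
  names(out) <- want
  out
}

#' Write a physiological record
#'
#' WFDB output uses signal format 16 with a per-channel gain chosen so the
#' amplitude range spans the 16-bit ADC range (round-trip error is bounded by
#' one ADC quantum, i.e. `1/gain`).  CSV output writes one
#' `t_seconds,amplitude` file per channel, named `<path>_<label>.csv`.
#'
#' @param signals named list of `ecg_signal` sharing fs and length.
#' @param path output record path (without extension).
#' @param format `"wfdb"` or `"csv"`.
#' @return invisibly, the paths written.
#' @export
write_record <- function(signals, path, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  if (!length(signals)) abort_invalid("empty channel list")
  lapply(signals, assert_signal)
  fs <- signals[[1]]$fs
  n <- length(signals[[1]]$samples)
  for (s in signals) {
    if (!isTRUE(all.equal(s$fs, fs))) abort_invalid("channels must share fs")
    if (length(s$samples) != n) abort_invalid("channels must share length")
  }
  labels <- vapply(seq_along(signals), function(i) {
    lb <- signals[[i]]$label
    if (nzchar(lb)) lb else sprintf("ch%d", i)
  }, character(1))
  if (format == "csv") {
    paths <- character(0)
    for (i in seq_along(signals)) {
      s <- signals[[i]]
      p <- sprintf("%s_%s.csv", path, labels[i])
      utils::write.csv(
        data.frame(t_seconds = signal_times(s), amplitude = s$samples),
        p, row.names = FALSE
      )
      paths <- c(paths, p)
    }
    return(invisible(paths))
  }
  rec <- basename(path)
  hea <- paste0(path, ".hea")
  datname <- paste0(rec, ".dat")
  gains <- vapply(signals, function(s) {
    amax <- max(abs(s$samples))
    if (amax == 0) 200 else floor(32000 / amax)
  }, numeric(1))
  gains[gains < 1] <- 1
  adc <- matrix(0L, nrow = length(signals), ncol = n)
  for (i in seq_along(signals)) {
    adc[i, ] <- as.integer(round(signals[[i]]$samples * gains[i]))
  }
  hdr <- c(
    sprintf("%s %d %g %d", rec, length(signals), fs, n),
    vapply(seq_along(signals), function(i) {
      sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s", datname, gains[i], labels[i])
    }, character(1))
  )
  writeLines(hdr, hea)
  writeBin(as.integer(adc), file.path(dirname(path), datname),
           size = 2L, endian = "little")
  invisible(c(hea, file.path(dirname(path), datname)))
}

#' Write ground-truth R times as a CSV sidecar
#'
#' @param r_times numeric vector of R-peak times in seconds.
#' @param record record identifier string.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_truth_csv <- function(r_times, record, path) {
  utils::write.csv(
    data.frame(record = record, beat_index = seq_along(r_times),
               t_seconds = r_times),
    path, row.names = FALSE
  )
  invisible(path)
}
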