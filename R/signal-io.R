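#' Construct an ECG signal object
#'
#' Container for one fixed-rate single-lead ECG segment: a numeric sample
#' vector, its sampling rate in Hz, an optional rhythm-class label and an
#' opaque record identifier.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units). Must be
#'   finite (no `NA`/`NaN`/`Inf`).
#' @param fs Sampling rate in Hz (default 250).
#' @param label Optional class label, one of `"AF"`, `"CHF"`, `"NSR"`.
#' @param record_id Optional identifier carried through the pipeline.
#' @return An object of class `ecg_signal`.
#' @examples
#' x <- ecg_signal(sin(2 * pi * 5 * seq(0, 2, by = 1 / 250)), fs = 250)
#' length(x$samples)
#' @export
ecg_signal <- function(samples, fs = 250, label = NULL, record_id = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    esb_abort("esb_empty_signal", "ECG signal has zero samples")
  if (!all(is.finite(samples)))
    esb_abort("esb_bad_argument", "ECG samples must be finite (no NA/NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    esb_abort("esb_bad_argument", "sampling rate fs must be a positive number")
  if (!is.null(label)) {
    label <- match.arg(label, c("AF", "CHF", "NSR"))
  }
  structure(list(samples = samples, fs = fs, label = label,
                 record_id = record_id),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.3f s)%s%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$label)) "" else paste0(", label=", x$label),
              if (is.null(x$record_id)) "" else paste0(", id=", x$record_id)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

# Coerce an ecg_signal / normalized signal / bare numeric to a sample vector.
as_samples <- function(x) {
  if (inherits(x, "ecg_signal")) x$samples else as.numeric(x)
}

#' Read an ECG record from disk
#'
#' Reads a single-channel ECG trace from a plain-text CSV file (one sample
#' per row, or a single comma-separated row) or from a WFDB header/signal
#' pair (see [read_wfdb()]).
#'
#' @param path File path. For `format = "wfdb"` this is the `.hea` file or
#'   the record name without extension.
#' @param format Either `"csv"` or `"wfdb"`.
#' @param fs Sampling rate assumed for CSV input (Hz); ignored for WFDB,
#'   whose header states the rate.
#' @param header Logical; skip a single header line in CSV input.
#' @param channel 1-based signal channel for WFDB input (default 1).
#' @param label,record_id Optional metadata attached to the result.
#' @return An [ecg_signal()].
#' @details Errors are classed: a nonexistent file raises
#'   `esb_missing_file`, unparseable content raises `esb_parse_error` naming
#'   the offending line, and a file with no samples raises
#'   `esb_empty_signal`.
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs = 250,
                        header = FALSE, channel = 1L,
                        label = NULL, record_id = NULL) {
  format <- match.arg(format)
  if (format == "wfdb")
    return(read_wfdb(path, channel = channel, label = label,
                     record_id = record_id))
  if (!file.exists(path))
    esb_abort("esb_missing_file", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    esb_abort("esb_empty_signal", sprintf("no samples in file: %s", path))
  vals <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- trimws(strsplit(lines[[i]], ",", fixed = TRUE)[[1]])
    tok <- tok[nzchar(tok)]
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v))
      esb_abort("esb_parse_error",
                sprintf("non-numeric token on line %d of %s: '%s'",
                        i, path, tok[which(is.na(v))[1]]))
    vals[[i]] <- v
  }
  samples <- unlist(vals, use.names = FALSE)
  if (length(samples) == 0L)
    esb_abort("esb_empty_signal", sprintf("no samples in file: %s", path))
  if (is.null(record_id))
    record_id <- tools::file_path_sans_ext(basename(path))
  ecg_signal(samples, fs = fs, label = label, record_id = record_id)
}

#' Write an ECG record to CSV
#'
#' One sample per row, full double precision, so that
#' `read_record(write_record(x))` round-trips exactly.
#'
#' @param x An [ecg_signal()] or numeric vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(x, path) {
  writeLines(sprintf("%.17g", as_samples(x)), path)
  invisible(path)
}

#' Read a WFDB record (minimal reader)
#'
#' Parses a PhysioNet WFDB `.hea` header and its `.dat` signal file.
#' Supports the common storage formats 16 (16-bit little-endian) and 212
#' (paired 12-bit samples); values are converted to physical units via the
#' per-signal gain and baseline. Intended for spot-loading PhysioNet
#' records; the package's tests and pipeline use CSV and the synthetic
#' generator instead.
#'
#' @param path Record name, with or without the `.hea` extension.
#' @param channel 1-based channel index (default 1, the first signal).
#' @param label,record_id Optional metadata.
#' @return An [ecg_signal()] with the header's sampling rate.
#' @export
read_wfdb <- function(path, channel = 1L, label = NULL, record_id = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea))
    esb_abort("esb_missing_file", sprintf("WFDB header not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  rec <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(rec) < 4L)
    esb_abort("esb_parse_error", sprintf("malformed WFDB record line in %s", hea))
  nsig <- as.integer(rec[2])
  fs <- as.numeric(strsplit(rec[3], "/", fixed = TRUE)[[1]][1])
  nsamp <- as.integer(rec[4])
  if (channel < 1L || channel > nsig)
    esb_abort("esb_bad_argument",
              sprintf("channel %d out of range (record has %d signals)",
                      channel, nsig))
  sig <- strsplit(trimws(lines[1L + seq_len(nsig)]), "\\s+")
  dat_file <- file.path(dirname(hea), sig[[1]][1])
  fmt <- as.integer(sub("x.*", "", sig[[1]][2]))
  # gain spec looks like "200", "200(0)", or "200(0)/mV"
  gain_tok <- if (length(sig[[channel]]) >= 3L) sig[[channel]][3] else "200"
  gain <- as.numeric(sub("[(/].*", "", gain_tok))
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gain_tok))
    as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_tok)) else 0
  if (!file.exists(dat_file))
    esb_abort("esb_missing_file", sprintf("WFDB signal file not found: %s", dat_file))
  raw_bytes <- readBin(dat_file, "raw", n = file.size(dat_file))
  adc <- switch(as.character(fmt),
    "16" = {
      v <- readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2L,
                   size = 2L, signed = TRUE, endian = "little")
      matrix(v, nrow = nsig)[channel, ]
    },
    "212" = {
      b <- as.integer(raw_bytes)
      ntrip <- length(b) %/% 3L
      b1 <- b[seq(1, by = 3, length.out = ntrip)]
      b2 <- b[seq(2, by = 3, length.out = ntrip)]
      b3 <- b[seq(3, by = 3, length.out = ntrip)]
      s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8L)
      s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      v <- as.vector(rbind(s1, s2))
      matrix(v[seq_len((length(v) %/% nsig) * nsig)], nrow = nsig)[channel, ]
    },
    esb_abort("esb_parse_error",
              sprintf("unsupported WFDB storage format %s", fmt))
  )
  if (nsamp > 0L && length(adc) >= nsamp) adc <- adc[seq_len(nsamp)]
  if (length(adc) == 0L)
    esb_abort("esb_empty_signal", sprintf("no samples in %s", dat_file))
  if (is.null(record_id))
    record_id <- tools::file_path_sans_ext(basename(hea))
  ecg_signal((adc - baseline) / gain, fs = fs, label = label,
             record_id = record_id)
}

#' Resample an ECG signal to a target rate
#'
#' Rational-factor polyphase resampling with an anti-aliasing FIR low-pass
#' (via [signal::resample()]). The output has exactly
#' `round(length(x) * target_fs / fs)` samples; when `target_fs == fs` the
#' samples are returned unchanged.
#'
#' @param x An [ecg_signal()].
#' @param target_fs Target sampling rate in Hz.
#' @return An [ecg_signal()] at `target_fs`.
#' @export
resample_signal <- function(x, target_fs) {
  stopifnot(inherits(x, "ecg_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      !is.finite(target_fs) || target_fs <= 0)
    esb_abort("esb_bad_argument", "target_fs must be a positive number")
  if (target_fs == x$fs) return(x)
  # reduce target_fs/fs to an integer ratio p/q
  scale <- 10^6
  p <- round(target_fs * scale)
  q <- round(x$fs * scale)
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  y <- signal::resample(x$samples, p = p, q = q)
  n_out <- round(length(x$samples) * target_fs / x$fs)
  if (length(y) >= n_out) y <- y[seq_len(n_out)]
  else y <- c(y, rep(y[length(y)], n_out - length(y)))
  ecg_signal(y, fs = target_fs, label = x$label, record_id = x$record_id)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Cut a signal into fixed-length windows
#'
#' Splits an ECG record into windows of `window_s` seconds taken every
#' `hop_s` seconds. Trailing partial windows are dropped; windows inherit
#' the parent label. The defaults (2-second non-overlapping windows at
#' 250 Hz) give 500-sample segments spanning 2-3 QRS cycles at typical
#' heart rates.
#'
#' @param x An [ecg_signal()].
#' @param window_s Window length in seconds (default 2).
#' @param hop_s Hop between window starts in seconds (default `window_s`).
#' @return A list of [ecg_signal()] windows (possibly empty, with a warning,
#'   when the signal is shorter than one window).
#' @export
segment_signal <- function(x, window_s = 2, hop_s = window_s) {
  stopifnot(inherits(x, "ecg_signal"))
  w <- round(window_s * x$fs)
  h <- round(hop_s * x$fs)
  if (w < 2L) esb_abort("esb_bad_argument", "window must span at least 2 samples")
  if (h < 1L) esb_abort("esb_bad_argument", "hop must be positive")
  n <- length(x$samples)
  if (n < w) {
    esb_warn("esb_short_signal",
             sprintf("signal %s shorter (%d) than one window (%d); no segments",
                     x$record_id %||% "<unnamed>", n, w))
    return(list())
  }
  starts <- seq.int(1L, n - w + 1L, by = h)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    ecg_signal(x$samples[s:(s + w - 1L)], fs = x$fs, label = x$label,
               record_id = paste0(x$record_id %||% "seg", "_w", i))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Amplitude-normalize an ECG segment
#'
#' Two-step normalization: subtract the segment mean, then divide by the
#' maximum absolute deviation, so the output lies in \[-1, +1\] with at
#' least one sample of absolute value exactly 1:
#' \deqn{y(n) = x(n) - \bar{x}, \qquad z(n) = y(n) / \max |y(n)|.}
#' The map removes inter-record amplitude/offset differences without
#' altering waveform morphology; it is idempotent and invariant (up to
#' sign) under affine rescaling of the input.
#'
#' @param x An [ecg_signal()] or numeric vector.
#' @return An object of class `c("ecg_normalized", "ecg_signal")` whose
#'   `provenance` field records the source `record_id`.
#' @details A constant segment has `max |y| = 0` and the second step is
#'   undefined; it raises an `esb_degenerate_signal` error rather than
#'   returning zeros (which would silently poison downstream variance
#'   ratios).
#' @examples
#' normalize_signal(c(1, 2, 3))$samples  # -1 0 1
#' @export
normalize_signal <- function(x) {
  s <- as_samples(x)
  if (length(s) < 2L)
    esb_abort("esb_short_signal", "need at least 2 samples to normalize")
  y <- s - mean(s)
  m <- max(abs(y))
  if (m == 0)
    esb_abort("esb_degenerate_signal",
              "constant signal: max|x - mean(x)| is zero, normalization undefined")
  z <- y / m
  fs <- if (inherits(x, "ecg_signal")) x$fs else 250
  out <- ecg_signal(z, fs = fs,
                    label = if (inherits(x, "ecg_signal")) x$label else NULL,
                    record_id = if (inherits(x, "ecg_signal")) x$record_id else NULL)
  out$provenance <- out$record_id
  class(out) <- c("ecg_normalized", class(out))
  out
}
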