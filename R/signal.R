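#' Sampled signal container
#'
#' A minimal container for a uniformly sampled real signal: a numeric vector
#' of samples plus a sampling rate in Hz. Most low-level operators in the
#' package also accept a bare numeric vector; the container matters wherever
#' frequencies in Hz are involved (band plans, instantaneous frequency,
#' trend timescales, file I/O).
#'
#' @param samples numeric vector of samples, length at least 2, all finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @return An object of class `fq_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' s <- fq_signal(sin(2 * pi * 5 * (0:99) / 100), fs = 100)
#' s
#' @export
fq_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 2)
    stop("a signal needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive finite scalar (Hz)")
  structure(list(samples = samples, fs = fs), class = "fq_signal")
}

#' @export
print.fq_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<fq_signal> %d samples @ %g Hz (%.4g s)\n", n, x$fs, n / x$fs))
  cat("  range: [", format(min(x$samples), digits = 4), ", ",
      format(max(x$samples), digits = 4), "]\n", sep = "")
  invisible(x)
}

# Accept either an fq_signal or a bare numeric vector.
.samples <- function(x) {
  if (inherits(x, "fq_signal")) x$samples else as.numeric(x)
}

.fs <- function(x, fs = NULL) {
  if (!is.null(fs)) return(fs)
  if (inherits(x, "fq_signal")) return(x$fs)
  stop("sampling rate 'fs' is required (pass fs= or an fq_signal)")
}

#' Read a signal from CSV or WAV
#'
#' CSV files may have one column (values; `fs` must then be supplied) or two
#' columns (time in seconds, value; `fs` is inferred from the median sampling
#' interval, with a warning when the timing jitter exceeds 1%). WAV files
#' (PCM 8/16/32-bit integer or IEEE float) carry their own rate; the first
#' channel is used.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"wav"`.
#' @param fs sampling rate override in Hz; required for value-only CSV.
#' @return An [fq_signal].
#' @export
read_signal <- function(path, format = c("auto", "csv", "wav"), fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "wav") "wav" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "wav") {
    w <- read_wav(path)
    if (!is.null(fs) && fs != w$fs)
      warning("fs override (", fs, ") differs from WAV header (", w$fs, "); using override")
    return(fq_signal(w$samples, if (is.null(fs)) w$fs else fs))
  }
  d <- utils::read.csv(path)
  if (ncol(d) == 1L) {
    if (is.null(fs)) stop("value-only CSV: sampling rate 'fs' must be supplied")
    v <- d[[1]]
  } else {
    tm <- as.numeric(d[[1]])
    v <- d[[2]]
    dt <- diff(tm)
    if (any(!is.finite(dt)) || any(dt <= 0))
      stop("time column is not strictly increasing")
    med <- stats::median(dt)
    if (max(abs(dt - med)) / med > 0.01)
      warning("sampling interval jitter exceeds 1%; fs taken from median interval")
    if (is.null(fs)) fs <- 1 / med
  }
  if (any(!is.finite(v))) stop("CSV contains non-finite values (NA/NaN/Inf)")
  fq_signal(v, fs)
}

#' Write a signal to CSV or WAV
#'
#' CSV output has a header and two columns `time_s,value`. WAV output is
#' 32-bit IEEE float, one channel.
#'
#' @param x an [fq_signal].
#' @param path output path.
#' @param format `"auto"` (by extension), `"csv"` or `"wav"`.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("auto", "csv", "wav")) {
  stopifnot(inherits(x, "fq_signal"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "wav") "wav" else "csv"
  }
  if (format == "wav") {
    write_wav(x$samples, x$fs, path)
  } else {
    n <- length(x$samples)
    utils::write.csv(
      data.frame(time_s = (seq_len(n) - 1) / x$fs, value = x$samples),
      path, row.names = FALSE)
  }
  invisible(path)
}

# --- minimal RIFF/WAVE reader and writer -----------------------------------
# No WAV package is available in the target library, so the canonical chunk
# layout is parsed directly. Supports PCM (8/16/32-bit int) and IEEE float
# (32/64-bit), mono or the first channel of multichannel files.

read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels     = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little"))
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)  # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt/data chunk in ", path)
  bytes <- fmt$bits / 8
  n_tot <- length(data) %/% bytes
  v <- switch(as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 8) {
        (readBin(data, "integer", n_tot, 1, signed = FALSE) - 128) / 128
      } else if (fmt$bits == 16) {
        readBin(data, "integer", n_tot, 2, endian = "little") / 32768
      } else if (fmt$bits == 32) {
        readBin(data, "integer", n_tot, 4, endian = "little") / 2147483648
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data, "double", n_tot, bytes, endian = "little"),  # IEEE float
    stop("unsupported WAV audio format code: ", fmt$audio_format))
  if (fmt$channels > 1L) v <- v[seq(1, length(v), by = fmt$channels)]
  list(samples = v, fs = fmt$sample_rate)
}

write_wav <- function(samples, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_size <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(3L, con, 2, endian = "little")              # IEEE float
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(as.integer(round(fs)), con, 4, endian = "little")
  writeBin(as.integer(round(fs)) * 4L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(32L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}
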