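#' Respiratory sound recording
#'
#' A `resp_recording` holds a mono waveform normalized to peak amplitude 1,
#' its sample rate and an identifier. All analysis in this package operates
#' on this container.
#'
#' @param samples numeric vector of finite samples, length >= 1.
#' @param sample_rate sampling frequency in Hz (> 0).
#' @param id text label for the recording.
#' @return an object of class `resp_recording` with fields `samples`,
#'   `sample_rate`, `id`.
#' @export
resp_recording <- function(samples, sample_rate, id = "recording") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(list(samples = samples, sample_rate = sample_rate, id = id),
            class = "resp_recording")
}

#' @export
print.resp_recording <- function(x, ...) {
  cat(sprintf("<resp_recording '%s': %d samples @ %g Hz (%.2f s)>\n",
              x$id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
duration.resp_recording <- function(x, ...) length(x$samples) / x$sample_rate

#' Duration of an object in seconds
#' @param x object with a duration.
#' @param ... unused.
#' @return duration in seconds.
#' @export
duration <- function(x, ...) UseMethod("duration")

# --- minimal RIFF/WAVE PCM I/O ----------------------------------------------
# No WAV reader ships with the R distribution in use, so a minimal PCM
# parser is provided: canonical RIFF/WAVE, integer PCM (8/16/24/32-bit),
# mono or multi-channel. Chunks other than "fmt " and "data" are skipped.

read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (is.na(size) || size == 0) stop("empty file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", len)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", len)
    } else {
      invisible(readBin(con, "raw", len))
    }
    if (len %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk word padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("malformed WAV (no fmt chunk): ", path)
  if (is.null(data_raw) || length(data_raw) == 0)
    stop("empty WAV data chunk: ", path)
  if (fmt$audio_format != 1L)
    stop("unsupported WAV encoding (only integer PCM supported): ", path)

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- switch(as.character(fmt$bits),
    "8"  = as.numeric(readBin(data_raw, "integer", n, 1, signed = FALSE)) - 128,
    "16" = as.numeric(readBin(data_raw, "integer", n, 2, signed = TRUE,
                              endian = "little")),
    "24" = {
      m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      ifelse(v >= 8388608, v - 16777216, v)
    },
    "32" = as.numeric(readBin(data_raw, "integer", n, 4, signed = TRUE,
                              endian = "little")),
    stop("unsupported PCM bit depth: ", fmt$bits))
  x <- x / (2^(fmt$bits - 1))
  if (fmt$channels > 1L) {
    nf <- length(x) %/% fmt$channels
    x <- matrix(x[seq_len(nf * fmt$channels)], nrow = fmt$channels)
  }
  list(samples = x, sample_rate = fmt$sample_rate, channels = fmt$channels)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param samples numeric vector in \[-1, 1\] (clipped if outside).
#' @param sample_rate sampling frequency in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  x <- pmax(-1, pmin(1, as.numeric(samples)))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")                 # block align
  writeBin(16L, con, 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Load a recording from a PCM WAV file
#'
#' Reads a PCM WAV file, downmixes stereo to mono by channel mean, resamples
#' to `target_rate` with a polyphase rational resampler, and normalizes the
#' waveform to peak amplitude 1. Normalization discards the hardware gain
#' chain, so classifier thresholds are trained on the normalized scale.
#'
#' @param path path to a PCM WAV file (integer PCM, mono or multi-channel).
#' @param target_rate internal analysis rate in Hz; default 8000.
#' @param id recording label; defaults to the file name.
#' @return a [resp_recording()].
#' @export
load_recording <- function(path, target_rate = 8000,
                           id = tools::file_path_sans_ext(basename(path))) {
  w <- read_wav(path)
  x <- if (is.matrix(w$samples)) colMeans(w$samples) else w$samples
  if (length(x) == 0) stop("empty WAV data: ", path)
  if (w$sample_rate != target_rate) {
    g <- pracma_gcd(target_rate, w$sample_rate)
    x <- signal::resample(x, target_rate / g, w$sample_rate / g)
  }
  peak <- max(abs(x))
  if (peak == 0) stop("recording is all-zero, cannot normalize: ", path)
  resp_recording(x / peak, target_rate, id = id)
}

pracma_gcd <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

# --- framing -----------------------------------------------------------------

#' Slice a recording into fixed overlapped segments
#'
#' Segments of `N` samples at hop `round(N * (1 - overlap))`; trailing
#' samples that do not fill a whole segment are discarded. Segment `m`
#' (0-based) starts at time `m * hop / sample_rate`.
#'
#' @param rec a [resp_recording()].
#' @param N segment length in samples (default 512, i.e. 64 ms at 8 kHz).
#' @param overlap fractional overlap in \[0, 1); default 0.5.
#' @return object of class `segment_frames`: list with `samples` (N x n
#'   matrix, one column per segment), `m` (0-based indices), `start_time`
#'   (seconds), `N`, `hop`, `sample_rate`.
#' @export
frame_segments <- function(rec, N = 512L, overlap = 0.5) {
  stopifnot(inherits(rec, "resp_recording"))
  if (N <= 0) stop("N must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  hop <- as.integer(round(N * (1 - overlap)))
  if (hop <= 0) stop("hop rounds to zero; decrease overlap")
  len <- length(rec$samples)
  n_seg <- if (len >= N) (len - N) %/% hop + 1L else 0L
  samples <- if (n_seg > 0) {
    idx <- outer(seq_len(N), (seq_len(n_seg) - 1L) * hop, `+`)
    matrix(rec$samples[idx], nrow = N)
  } else matrix(numeric(0), nrow = N)
  structure(list(samples = samples,
                 m = seq_len(n_seg) - 1L,
                 start_time = (seq_len(n_seg) - 1L) * hop / rec$sample_rate,
                 N = as.integer(N), hop = hop,
                 sample_rate = rec$sample_rate),
            class = "segment_frames")
}

# --- annotations -------------------------------------------------------------

#' Annotation of a respiratory recording
#'
#' Holds expert (or simulated ground-truth) labels: intervals marked wheeze
#' (`W`) or normal (`N`), and respiratory-phase boundaries (`insp`, `exp`,
#' `pause`).
#'
#' @param intervals data.frame with columns `start_s`, `end_s`, `label`
#'   (values `"W"` or `"N"`).
#' @param phases data.frame with columns `start_s`, `end_s`, `phase`
#'   (values `"insp"`, `"exp"`, `"pause"`).
#' @return an object of class `resp_annotation`.
#' @export
resp_annotation <- function(intervals = empty_intervals(),
                            phases = empty_phases()) {
  intervals <- validate_spans(intervals, "label", c("W", "N"))
  phases <- validate_spans(phases, "phase", c("insp", "exp", "pause"))
  structure(list(intervals = intervals, phases = phases),
            class = "resp_annotation")
}

empty_intervals <- function()
  data.frame(start_s = numeric(0), end_s = numeric(0),
             label = character(0), stringsAsFactors = FALSE)

empty_phases <- function()
  data.frame(start_s = numeric(0), end_s = numeric(0),
             phase = character(0), stringsAsFactors = FALSE)

validate_spans <- function(df, value_col, valid) {
  stopifnot(is.data.frame(df),
            all(c("start_s", "end_s", value_col) %in% names(df)))
  if (nrow(df) == 0) return(df[c("start_s", "end_s", value_col)])
  if (any(df$end_s <= df$start_s))
    stop("annotation interval with end <= start")
  if (!all(df[[value_col]] %in% valid))
    stop("invalid annotation value(s): ",
         paste(setdiff(df[[value_col]], valid), collapse = ", "))
  df <- df[order(df$start_s), c("start_s", "end_s", value_col)]
  if (nrow(df) > 1 &&
      any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9))
    stop("overlapping annotation intervals")
  rownames(df) <- NULL
  df
}

#' Read an annotation TSV file
#'
#' Format: a header line `start_s  end_s  kind  value`, then one tab-separated
#' row per span, `kind` either `label` (value `W`/`N`) or `phase`
#' (value `insp`/`exp`/`pause`).
#'
#' @param path path to the TSV file.
#' @return a [resp_annotation()].
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty annotation file: ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      stop(sprintf("parse error at line %d of %s: expected 4 tab-separated fields",
                   i + 1L, path))
    start_s <- suppressWarnings(as.numeric(f[1]))
    end_s <- suppressWarnings(as.numeric(f[2]))
    if (is.na(start_s) || is.na(end_s))
      stop(sprintf("parse error at line %d of %s: non-numeric time", i + 1L, path))
    if (end_s <= start_s)
      stop(sprintf("parse error at line %d of %s: end_s <= start_s", i + 1L, path))
    if (!f[3] %in% c("label", "phase"))
      stop(sprintf("parse error at line %d of %s: unknown kind '%s'",
                   i + 1L, path, f[3]))
    rows[[i]] <- data.frame(start_s = start_s, end_s = end_s,
                            kind = f[3], value = f[4],
                            stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               kind = character(0), value = character(0))
  iv <- df[df$kind == "label", c("start_s", "end_s", "value")]
  ph <- df[df$kind == "phase", c("start_s", "end_s", "value")]
  names(iv)[3] <- "label"; names(ph)[3] <- "phase"
  resp_annotation(intervals = iv, phases = ph)
}

#' Write an annotation TSV file
#'
#' @param annot a [resp_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  stopifnot(inherits(annot, "resp_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("start_s\tend_s\tkind\tvalue", con)
  iv <- annot$intervals; ph <- annot$phases
  if (nrow(iv))
    writeLines(sprintf("%.6f\t%.6f\tlabel\t%s", iv$start_s, iv$end_s, iv$label),
               con)
  if (nrow(ph))
    writeLines(sprintf("%.6f\t%.6f\tphase\t%s", ph$start_s, ph$end_s, ph$phase),
               con)
  invisible(path)
}
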