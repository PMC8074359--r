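# Audio clips and RIFF/PCM WAV I/O.
#
# Clips are plain S3 objects holding a mono waveform in [-1, 1] at a fixed
# sampling rate (4 kHz for this application). WAV files are 16-bit PCM mono;
# samples are read as s/32768 and written as round(x*32768) clamped to the
# int16 range, so a read-write-read cycle is bitwise exact.

#' Construct an audio clip
#'
#' @param samples Numeric waveform with amplitudes in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (default 4000).
#' @param label Optional class label, one of [lung_classes()].
#' @param source_id Optional provenance string (file path or synth id).
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate = 4000, label = NULL, source_id = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("samples must be finite and free of NA/NaN")
  if (length(samples) && max(abs(samples)) > 1 + 1e-9)
    stop("sample amplitudes must lie in [-1, 1]")
  if (!is.null(label)) {
    label <- match.arg(label, lung_classes())
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         label = label, source_id = as.character(source_id)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.3f s)%s%s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (!is.null(x$label)) paste0(", label=", x$label) else "",
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

# --- low-level WAV (RIFF, PCM 16-bit) ---------------------------------------

read_wav_pcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing chunk): ", path)
  if (fmt$audio_format != 1L) stop("unsupported WAV encoding (not PCM): ", path)
  if (fmt$bits != 16L) stop("unsupported bit depth (expected 16-bit PCM): ", path)
  pcm <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2,
                 signed = TRUE, endian = "little")
  list(pcm = pcm, channels = fmt$channels, sample_rate = fmt$sample_rate)
}

write_wav_pcm16 <- function(pcm, sample_rate, path) {
  pcm <- as.integer(pcm)
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Load a mono PCM WAV file as an audio clip
#'
#' The file must be mono 16-bit PCM at exactly `expected_rate`; mismatched
#' rates are refused rather than silently resampled.
#'
#' @param path Path to a WAV file.
#' @param expected_rate Required sampling rate in Hz (default 4000).
#' @param label Optional class label attached to the clip.
#' @return An [audio_clip()] with samples in `[-1, 1)`.
#' @export
load_clip <- function(path, expected_rate = 4000, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  w <- read_wav_pcm16(path)
  if (w$channels != 1L)
    stop("expected mono audio, got ", w$channels, " channels: ", path)
  if (w$sample_rate != expected_rate)
    stop(sprintf("sample-rate mismatch: file is %d Hz, expected %g Hz (%s); refusing to resample",
                 w$sample_rate, expected_rate, path))
  audio_clip(w$pcm / 32768, sample_rate = w$sample_rate, label = label,
             source_id = path)
}

#' Write an audio clip as a 16-bit PCM mono WAV file
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clip <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  pcm <- pmax(pmin(round(clip$samples * 32768), 32767), -32768)
  write_wav_pcm16(pcm, clip$sample_rate, path)
  invisible(path)
}

#' Normalize a clip to a fixed duration
#'
#' Clips shorter than the target are zero-padded at the end; longer clips
#' keep their first `round(target_seconds * sample_rate)` samples (the onset
#' of a respiratory cycle carries the adventitious event). Idempotent.
#'
#' @param clip An [audio_clip()].
#' @param target_seconds Target duration in seconds (default 1.25).
#' @return An [audio_clip()] of exactly `round(target_seconds * sample_rate)`
#'   samples.
#' @export
pad_or_truncate <- function(clip, target_seconds = 1.25) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!length(clip$samples)) stop("cannot normalize an empty clip")
  if (target_seconds <= 0) stop("target_seconds must be positive")
  n_target <- round(target_seconds * clip$sample_rate)
  x <- clip$samples
  if (length(x) >= n_target) {
    x <- x[seq_len(n_target)]
  } else {
    x <- c(x, numeric(n_target - length(x)))
  }
  audio_clip(x, clip$sample_rate, clip$label, clip$source_id)
}
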