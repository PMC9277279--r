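#' Construct an audio segment
#'
#' A bounded, time-stamped mono waveform in full-scale units. Samples are
#' floating point on the nominal range \[-1, 1\]; 0 dBFS corresponds to an
#' amplitude of 1 before any 16-bit quantization.
#'
#' @param samples numeric vector of samples in \[-1, 1\] (values outside are
#'   permitted in memory; they are clipped, with a warning, on WAV export).
#' @param sample_rate_hz sampling rate in Hz.
#' @param start_s time of the first sample, in seconds relative to the
#'   enclosing recording (default 0).
#' @return an object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate_hz, start_s = 0) {
  stopifnot(is.numeric(samples), length(sample_rate_hz) == 1L,
            sample_rate_hz > 0, is.finite(start_s))
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = as.numeric(sample_rate_hz),
         start_s = as.numeric(start_s)),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment: %.2f s @ %g Hz, start %.2f s, peak %.3f>\n",
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz,
              x$start_s, if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of an audio segment in seconds
#' @param audio an `audio_segment`.
#' @return duration in seconds.
#' @export
audio_duration_s <- function(audio) {
  length(audio$samples) / audio$sample_rate_hz
}

#' Extract a time slice of an audio segment
#'
#' @param audio an `audio_segment`.
#' @param from_s,to_s slice bounds in the segment's own time coordinates
#'   (seconds); clamped to the segment extent.
#' @return an `audio_segment` whose `start_s` reflects the slice position.
#' @export
audio_slice <- function(audio, from_s, to_s) {
  stopifnot(from_s < to_s)
  fs <- audio$sample_rate_hz
  n <- length(audio$samples)
  i0 <- max(1L, floor((from_s - audio$start_s) * fs) + 1L)
  i1 <- min(n, ceiling((to_s - audio$start_s) * fs))
  if (i1 < i0) stop("slice does not intersect the audio extent")
  audio_segment(audio$samples[i0:i1], fs, audio$start_s + (i0 - 1L) / fs)
}

# Clip samples to [-1, 1], warning if any sample is altered.
clip_full_scale <- function(samples) {
  n_out <- sum(samples > 1 | samples < -1)
  if (n_out > 0L) {
    warning(sprintf("%d sample(s) clipped to full scale [-1, 1]", n_out))
    samples <- pmin(1, pmax(-1, samples))
  }
  samples
}

#' Write an audio segment as a 16-bit PCM mono WAV file
#'
#' Float samples are clipped to \[-1, 1\] (with a warning) and scaled by
#' 32767 before quantization, so the dBFS reference of 1.0 full scale is
#' defined pre-quantization.
#'
#' @param audio an `audio_segment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_segment"))
  x <- clip_full_scale(audio$samples)
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(round(audio$sample_rate_hz))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")       # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @return an `audio_segment` with samples rescaled to \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV supported")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(fs) || is.null(samples)) stop("malformed WAV: ", path)
  if (channels != 1L) stop("only mono WAV supported")
  if (bits != 16L) stop("only 16-bit WAV supported")
  audio_segment(samples / 32767, fs)
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
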