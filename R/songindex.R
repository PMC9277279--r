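#' Song intensity index series at 1-minute resolution
#'
#' The New Zealand blue whale song chorus often prevents isolating
#' individual song calls, so chorus level is summarized as a band-energy
#' ratio: mean spectral power in the predominant song band (23-24 Hz)
#' divided by the mean power at background frequencies (the single
#' spectrogram bins nearest 11 and 39 Hz). The ratio is computed on linear
#' power from the `detection`-preset spectrogram, averaged over each
#' 60-second bin; it is dimensionless, non-negative, and invariant to a
#' global waveform gain.
#'
#' @param audio an `audio_segment` at least one bin long.
#' @param song_band numeric `c(f_low, f_high)` of the song band in Hz.
#' @param background_freqs background frequencies in Hz.
#' @param bin_s bin width in seconds; bins are anchored at the segment start
#'   and a final partial bin is dropped.
#' @param background_halfwidth_hz if > 0, average narrow bands of this
#'   half-width around each background frequency instead of single bins.
#' @return data frame of class `song_intensity_series` with `bin_start_s`
#'   and `index` (`NA`, with a warning, for bins with zero background
#'   power).
#' @export
song_intensity_series <- function(audio, song_band = c(23, 24),
                                  background_freqs = c(11, 39),
                                  bin_s = 60,
                                  background_halfwidth_hz = 0) {
  stopifnot(inherits(audio, "audio_segment"))
  if (audio_duration_s(audio) < bin_s) {
    stop("audio shorter than one bin (", bin_s, " s)")
  }
  preset <- spectrogram_preset("detection")
  sp <- compute_spectrogram(audio, preset$n_fft, preset$window,
                            preset$overlap_frac)
  song_rows <- which(sp$freqs_hz >= song_band[1] &
                       sp$freqs_hz <= song_band[2])
  if (!length(song_rows)) stop("no spectrogram bins inside the song band")
  bg_rows <- unlist(lapply(background_freqs, function(f) {
    if (background_halfwidth_hz > 0) {
      which(abs(sp$freqs_hz - f) <= background_halfwidth_hz)
    } else {
      which.min(abs(sp$freqs_hz - f))
    }
  }))
  n_bins <- floor((audio_duration_s(audio)) / bin_s)
  rel_t <- sp$times_s - audio$start_s
  bin_of <- floor(rel_t / bin_s) + 1L
  song_col <- colMeans(sp$power[song_rows, , drop = FALSE])
  bg_col <- colMeans(sp$power[bg_rows, , drop = FALSE])
  idx <- rep(NA_real_, n_bins)
  undefined <- integer(0)
  for (b in seq_len(n_bins)) {
    cols <- which(bin_of == b)
    if (!length(cols)) next
    num <- mean(song_col[cols])
    den <- mean(bg_col[cols])
    if (den == 0) {
      undefined <- c(undefined, b)
    } else {
      idx[b] <- num / den
    }
  }
  if (length(undefined)) {
    warning("zero background power in ", length(undefined),
            " bin(s); index undefined there")
  }
  structure(data.frame(bin_start_s = audio$start_s + (seq_len(n_bins) - 1L) *
                         bin_s,
                       index = idx),
            class = c("song_intensity_series", "data.frame"))
}

#' Mean song intensity over a time window
#'
#' Arithmetic mean of the defined bin indices whose bin start lies in
#' `[window[1], window[2])`.
#'
#' @param series a `song_intensity_series`.
#' @param window numeric `c(start_s, end_s)`.
#' @return mean index (errors if the window covers no complete bin).
#' @export
mean_song_intensity <- function(series, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  inside <- series$bin_start_s >= window[1] & series$bin_start_s < window[2]
  if (!any(inside)) stop("window covers no complete song-intensity bin")
  mean(series$index[inside], na.rm = TRUE)
}
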