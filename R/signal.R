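#' Named spectrogram parameter presets
#'
#' Three presets are used throughout: `detection` (2048-sample Hann window,
#' 50% overlap — the analysis and detector preset), `display` (2048, Hann,
#' 90% overlap — for dense visualization), and `songfig` (3072, Hann, 50%).
#' All analysis functions use `detection` unless configured otherwise.
#'
#' @param name one of `"detection"`, `"display"`, `"songfig"`.
#' @return list with `n_fft`, `window`, `overlap_frac`.
#' @export
spectrogram_preset <- function(name = c("detection", "display", "songfig")) {
  switch(match.arg(name),
         detection = list(n_fft = 2048L, window = "hann", overlap_frac = 0.5),
         display   = list(n_fft = 2048L, window = "hann", overlap_frac = 0.9),
         songfig   = list(n_fft = 3072L, window = "hann", overlap_frac = 0.5))
}

#' Compute a one-sided power spectrogram
#'
#' Magnitude-squared short-time Fourier transform with the one-sided bins
#' doubled (except DC and Nyquist), so that the total power of a column
#' equals `n_fft` times the windowed frame's time-domain energy (discrete
#' Parseval). Frame count is `floor((N - n_fft)/hop) + 1` with
#' `hop = n_fft * (1 - overlap_frac)`.
#'
#' @param audio an `audio_segment` at least `n_fft` samples long.
#' @param n_fft transform length in samples.
#' @param window window name; only `"hann"` is supported.
#' @param overlap_frac fractional overlap between consecutive frames.
#' @return object of class `spectrogram`: `power` (n_freq x n_time, linear),
#'   `freqs_hz`, `times_s` (frame centers, in the audio segment's time
#'   coordinates), and `params`.
#' @export
compute_spectrogram <- function(audio, n_fft = 2048L, window = "hann",
                                overlap_frac = 0.5) {
  stopifnot(inherits(audio, "audio_segment"))
  if (window != "hann") stop("only the Hann window is supported")
  n <- length(audio$samples)
  if (n < n_fft) stop("audio shorter than n_fft (", n, " < ", n_fft, ")")
  fs <- audio$sample_rate_hz
  hop <- round(n_fft * (1 - overlap_frac))
  w <- signal::hanning(n_fft)
  sg <- signal::specgram(audio$samples, n = n_fft, Fs = fs,
                         window = w, overlap = n_fft - hop)
  p <- Mod(sg$S)^2
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)  # single-frame input
  n_freq <- nrow(p)
  # one-sided doubling; bins run 0..(n_fft/2 - 1), so the Nyquist bin is
  # not represented (its power is negligible for in-band signals)
  mult <- rep(2, n_freq)
  mult[1] <- 1
  p <- p * mult
  n_time <- ncol(p)
  times <- audio$start_s + ((seq_len(n_time) - 1L) * hop + n_fft / 2) / fs
  structure(
    list(power = p,
         freqs_hz = as.numeric(sg$f),
         times_s = times,
         params = list(n_fft = as.integer(n_fft), window = window,
                       overlap_frac = overlap_frac, sample_rate_hz = fs,
                       hop = hop, window_sumsq = sum(w^2))),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d freq x %d time, %g Hz, n_fft %d, overlap %g>\n",
              nrow(x$power), ncol(x$power), x$params$sample_rate_hz,
              x$params$n_fft, x$params$overlap_frac))
  invisible(x)
}

#' Construct a time/frequency selection box
#'
#' @param t_min_s,t_max_s time bounds in seconds (`t_min_s < t_max_s`).
#' @param f_min_hz,f_max_hz frequency bounds in Hz (`f_min_hz < f_max_hz`).
#' @return a list of class `selection`.
#' @export
selection <- function(t_min_s, t_max_s, f_min_hz, f_max_hz) {
  stopifnot(t_min_s < t_max_s, f_min_hz < f_max_hz)
  structure(list(t_min_s = t_min_s, t_max_s = t_max_s,
                 f_min_hz = f_min_hz, f_max_hz = f_max_hz),
            class = "selection")
}

# Indices of spectrogram cells inside a selection (closed bounds on centers).
selection_cells <- function(sp, sel) {
  cols <- which(sp$times_s >= sel$t_min_s & sp$times_s <= sel$t_max_s)
  rows <- which(sp$freqs_hz >= sel$f_min_hz & sp$freqs_hz <= sel$f_max_hz)
  list(rows = rows, cols = cols)
}

#' Total linear spectrogram power inside a selection
#'
#' @param sp a `spectrogram`.
#' @param sel a `selection`.
#' @return list with `total` (summed linear power) and `n_frames`.
#' @export
selection_power <- function(sp, sel) {
  cells <- selection_cells(sp, sel)
  if (!length(cells$rows) || !length(cells$cols)) {
    stop("selection does not intersect the spectrogram extent")
  }
  list(total = sum(sp$power[cells$rows, cells$cols, drop = FALSE]),
       n_frames = length(cells$cols))
}

#' Relative energy of a selection in dBFS
#'
#' Sums linear spectrogram power over the selection and expresses it in dB
#' relative to the energy a full-scale DC signal would contribute over the
#' same selection duration (all frames, full band). With this reference a
#' full-scale sine occupying the whole selection measures -3.01 dBFS, any
#' unclipped signal measures <= 0 dBFS, and scaling the waveform by a gain
#' `g` shifts the value by exactly `20*log10(g)` — only differences in
#' level are meaningful, which is all the analysis uses.
#'
#' @param sp a `spectrogram`.
#' @param sel a `selection` intersecting its extent.
#' @return energy in dBFS; `-Inf` (with a warning) for zero energy.
#' @export
selection_energy_dbfs <- function(sp, sel) {
  pw <- selection_power(sp, sel)
  # full-scale DC over the same frames: per frame n_fft * sum(w^2)
  e_ref <- pw$n_frames * sp$params$n_fft * sp$params$window_sumsq
  if (pw$total == 0) {
    warning("zero energy in selection; returning -Inf dBFS")
    return(-Inf)
  }
  10 * log10(pw$total / e_ref)
}

#' Locate an earthquake signal and measure its received level
#'
#' Searches a padded window around the catalog-expected time for the
#' earthquake rumble: the audio is cut into 1-s frames, each frame's
#' 5-100 Hz band energy is computed, and frames exceeding a robust
#' threshold (median + `k_mad` * MAD over the search window) are flagged.
#' The maximal contiguous run of flagged frames is taken as the event; its
#' onset, dBFS energy and duration are returned.
#'
#' @param audio an `audio_segment` covering the search window.
#' @param expected_time_s expected arrival time, in the audio segment's time
#'   coordinates.
#' @param search_pad_s half-width of the search window in seconds.
#' @param band numeric `c(f_low, f_high)` in Hz for the detection band.
#' @param k_mad robust threshold multiplier.
#' @param frame_s detection frame length in seconds.
#' @return list with `found` (logical), `received_time_s`, `rl_dbfs`,
#'   `duration_s` (all `NA` when not found).
#' @export
quake_received_metrics <- function(audio, expected_time_s,
                                   search_pad_s = 120, band = c(5, 100),
                                   k_mad = 5, frame_s = 1) {
  stopifnot(inherits(audio, "audio_segment"))
  t0 <- audio$start_s
  t1 <- t0 + audio_duration_s(audio)
  if (expected_time_s < t0 || expected_time_s > t1) {
    stop("expected_time_s outside the audio extent")
  }
  seg <- audio_slice(audio, max(t0, expected_time_s - search_pad_s),
                     min(t1, expected_time_s + search_pad_s))
  fs <- seg$sample_rate_hz
  nf <- round(frame_s * fs)
  n_frames <- floor(length(seg$samples) / nf)
  if (n_frames < 3L) stop("search window too short")
  m <- matrix(seg$samples[seq_len(n_frames * nf)], nrow = nf)
  spec <- Mod(stats::mvfft(m))^2
  freqs <- (seq_len(nf) - 1L) / nf * fs
  rows <- which(freqs >= band[1] & freqs <= band[2])
  e <- colSums(spec[rows, , drop = FALSE])
  thr <- stats::median(e) + k_mad * stats::mad(e)
  above <- e > thr
  if (!any(above)) {
    return(list(found = FALSE, received_time_s = NA_real_,
                rl_dbfs = NA_real_, duration_s = NA_real_))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  onset <- seg$start_s + (i0 - 1L) * frame_s
  dur <- (i1 - i0 + 1L) * frame_s
  # measure RL over the run; pad the slice to at least one transform frame
  preset <- spectrogram_preset("detection")
  need_s <- preset$n_fft / fs
  run_end <- min(t1, max(onset + dur, onset + need_s))
  run_audio <- audio_slice(audio, onset, run_end)
  sp <- compute_spectrogram(run_audio, preset$n_fft, preset$window,
                            preset$overlap_frac)
  sel <- selection(onset - 1e-9, run_end + 1e-9, band[1], band[2])
  rl <- selection_energy_dbfs(sp, sel)
  list(found = TRUE, received_time_s = onset, rl_dbfs = rl,
       duration_s = dur)
}
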