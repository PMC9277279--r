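#' Build spectrogram correlation templates from exemplar calls
#'
#' Each exemplar waveform is converted to a `detection`-preset power
#' spectrogram, cropped to the D-call band, and normalized to zero mean and
#' unit norm (flattened), so that sliding correlation against a recording's
#' spectrogram is a Pearson correlation, invariant to the exemplar's
#' amplitude.
#'
#' @param exemplars list of `audio_segment` objects, each at least one
#'   spectrogram frame long.
#' @param band_hz numeric `c(f_low, f_high)` crop band in Hz.
#' @param ids optional character ids (default `tpl01`, `tpl02`, ...).
#' @return list of `template` objects (patch, band_hz, duration_s, id).
#' @export
build_templates <- function(exemplars, band_hz = c(15, 110), ids = NULL) {
  stopifnot(length(exemplars) >= 1)
  preset <- spectrogram_preset("detection")
  if (is.null(ids)) ids <- sprintf("tpl%02d", seq_along(exemplars))
  templates <- lapply(seq_along(exemplars), function(i) {
    ex <- exemplars[[i]]
    if (length(ex$samples) < preset$n_fft) {
      stop("exemplar ", ids[i], " shorter than one spectrogram frame (",
           preset$n_fft, " samples)")
    }
    sp <- compute_spectrogram(ex, preset$n_fft, preset$window,
                              preset$overlap_frac)
    rows <- which(sp$freqs_hz >= band_hz[1] & sp$freqs_hz <= band_hz[2])
    patch <- sp$power[rows, , drop = FALSE]
    patch <- patch - mean(patch)
    nrm <- sqrt(sum(patch^2))
    if (nrm == 0) stop("exemplar ", ids[i], " has a constant spectrogram")
    structure(list(patch = patch / nrm, band_hz = band_hz,
                   duration_s = audio_duration_s(ex), id = ids[i]),
              class = "template")
  })
  templates
}

#' The default library of 13 synthetic D-call templates
#'
#' Twelve templates cover the duration x sweep-range grid
#' {1.5, 2, 2.5, 3} s x {100-20, 90-25, 80-30} Hz, plus one curvilinear
#' 100-20 Hz sweep, capturing the variability of downswept D calls. The
#' multi-template maximum-score architecture mirrors detectors used in
#' practice; user-supplied exemplars can replace or extend the library.
#'
#' @param sample_rate_hz sampling rate of the target recordings.
#' @return list of 13 `template` objects.
#' @export
default_dcall_templates <- function(sample_rate_hz = 2000) {
  grid <- expand.grid(duration_s = c(1.5, 2, 2.5, 3),
                      sweep = c("100-20", "90-25", "80-30"),
                      stringsAsFactors = FALSE)
  sweeps <- list("100-20" = c(100, 20), "90-25" = c(90, 25),
                 "80-30" = c(80, 30))
  exemplars <- lapply(seq_len(nrow(grid)), function(i) {
    sw <- sweeps[[grid$sweep[i]]]
    gen_d_call(grid$duration_s[i], sw[1], sw[2], amplitude = 1,
               sample_rate_hz = sample_rate_hz)
  })
  exemplars <- c(exemplars,
                 list(gen_d_call(2, 100, 20, amplitude = 1,
                                 sample_rate_hz = sample_rate_hz,
                                 curvature = 2)))
  build_templates(exemplars)
}

#' Sliding spectrogram correlation of one template
#'
#' At each time lag, the Pearson correlation between the flattened template
#' and the identically-shaped, band-cropped spectrogram patch starting at
#' that lag. Values lie in \[-1, 1\]; a constant (zero-variance) patch gets
#' score 0 at that lag.
#'
#' @param sp a `spectrogram` (must use the `detection` preset parameters the
#'   template was built with).
#' @param template a `template`.
#' @return list with `scores` and `lag_times_s` (the start time, in the
#'   spectrogram's time coordinates, of the patch at each lag).
#' @export
correlation_track <- function(sp, template) {
  rows <- which(sp$freqs_hz >= template$band_hz[1] &
                  sp$freqs_hz <= template$band_hz[2])
  if (length(rows) != nrow(template$patch)) {
    stop("spectrogram band/resolution does not match the template")
  }
  spb <- sp$power[rows, , drop = FALSE]
  nt <- ncol(template$patch)
  n_time <- ncol(spb)
  if (n_time < nt) stop("spectrogram shorter than the template")
  n_lag <- n_time - nt + 1L
  npix <- length(template$patch)
  # numerator: sum over template columns of column dot-products
  a <- crossprod(template$patch, spb)           # nt x n_time
  num <- numeric(n_lag)
  for (j in seq_len(nt)) num <- num + a[j, j:(j + n_lag - 1L)]
  # patch mean/variance from running column sums
  s1 <- colSums(spb); s2 <- colSums(spb^2)
  ps1 <- running_sum(s1, nt); ps2 <- running_sum(s2, nt)
  den <- sqrt(pmax(ps2 - ps1^2 / npix, 0))
  scores <- ifelse(den > 1e-12, num / den, 0)
  scores <- pmin(1, pmax(-1, scores))
  hop_s <- sp$params$hop / sp$params$sample_rate_hz
  lag_times <- sp$times_s[seq_len(n_lag)] -
    sp$params$n_fft / (2 * sp$params$sample_rate_hz)
  list(scores = scores, lag_times_s = lag_times)
}

# Sum of x over sliding windows of length k (length(x) - k + 1 values).
running_sum <- function(x, k) {
  cs <- c(0, cumsum(x))
  cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]
}

#' Detect D calls by multi-template spectrogram correlation
#'
#' Computes a `detection`-preset spectrogram, runs every template's sliding
#' correlation, takes the pointwise maximum across templates, and collapses
#' contiguous supra-threshold regions to local score maxima separated by at
#' least `min_gap_s`. Each detection carries the winning template's time and
#' frequency extent, its correlation score, and its relative received level
#' in dBFS.
#'
#' @param audio an `audio_segment`.
#' @param templates list of `template` objects (default: the 13-template
#'   D-call library).
#' @param threshold detection threshold on the correlation score.
#' @param min_gap_s minimum separation between detection onsets in seconds.
#' @param lag_oversample evaluate the correlation on this many sub-hop
#'   frame-grid offsets (default 2, i.e. half-hop lag resolution), so a
#'   call whose onset falls between frame boundaries is not penalized.
#' @return a data frame of detections: id, start_s, end_s, f_low_hz,
#'   f_high_hz, score, best_template_id, rl_dbfs, source. Zero rows is a
#'   valid result.
#' @export
detect_d_calls <- function(audio, templates = default_dcall_templates(),
                           threshold = 0.80, min_gap_s = 1.0,
                           lag_oversample = 2L) {
  preset <- spectrogram_preset("detection")
  fs <- audio$sample_rate_hz
  hop <- round(preset$n_fft * (1 - preset$overlap_frac))
  cand_t <- numeric(0); cand_score <- numeric(0); cand_tpl <- integer(0)
  sp0 <- NULL
  for (k in seq_len(lag_oversample) - 1L) {
    off <- round(hop * k / lag_oversample)
    seg <- if (off == 0) audio else {
      audio_segment(audio$samples[-seq_len(off)], fs,
                    audio$start_s + off / fs)
    }
    if (length(seg$samples) < preset$n_fft) next
    sp <- compute_spectrogram(seg, preset$n_fft, preset$window,
                              preset$overlap_frac)
    if (k == 0L) sp0 <- sp
    tracks <- lapply(templates, function(tp) correlation_track(sp, tp))
    n_lag <- min(vapply(tracks, function(tr) length(tr$scores), integer(1)))
    score_mat <- vapply(tracks, function(tr) tr$scores[seq_len(n_lag)],
                        numeric(n_lag))
    score_mat <- matrix(score_mat, nrow = n_lag)
    best_score <- apply(score_mat, 1, max)
    best_tpl <- apply(score_mat, 1, which.max)
    keep <- which(best_score >= threshold)
    cand_t <- c(cand_t, tracks[[1]]$lag_times_s[keep])
    cand_score <- c(cand_score, best_score[keep])
    cand_tpl <- c(cand_tpl, best_tpl[keep])
  }
  if (!length(cand_t) || is.null(sp0)) return(empty_detections())
  # collapse to local maxima separated by >= min_gap_s (greedy by score;
  # ties broken by earlier time so the result is deterministic)
  ord <- order(-cand_score, cand_t)
  picked <- integer(0)
  for (i in ord) {
    if (!length(picked) ||
        all(abs(cand_t[picked] - cand_t[i]) >= min_gap_s)) {
      picked <- c(picked, i)
    }
  }
  picked <- picked[order(cand_t[picked])]

  rows <- lapply(picked, function(i) {
    tp <- templates[[cand_tpl[i]]]
    start_s <- cand_t[i]
    end_s <- start_s + tp$duration_s
    sel <- selection(start_s - 1e-9, end_s + 1e-9,
                     tp$band_hz[1], tp$band_hz[2])
    rl <- tryCatch(suppressWarnings(selection_energy_dbfs(sp0, sel)),
                   error = function(e) NA_real_)
    data.frame(id = NA_character_, start_s = start_s, end_s = end_s,
               f_low_hz = tp$band_hz[1], f_high_hz = tp$band_hz[2],
               score = cand_score[i], best_template_id = tp$id,
               rl_dbfs = rl, source = "auto", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$id <- sprintf("det%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(id = character(0), start_s = numeric(0), end_s = numeric(0),
             f_low_hz = numeric(0), f_high_hz = numeric(0),
             score = numeric(0), best_template_id = character(0),
             rl_dbfs = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Merge automatic detections with analyst review decisions
#'
#' Mirrors the manual-review step of detector post-processing: false
#' detections are removed by id, missed calls are added as manual
#' detections, and the result is time-sorted.
#'
#' @param auto detection data frame from [detect_d_calls()].
#' @param removals character ids to remove (must exist in `auto`).
#' @param additions detection data frame of analyst-added calls; their
#'   `source` is set to `"manual"`.
#' @return merged, time-sorted detection data frame.
#' @export
merge_annotations <- function(auto, removals = character(0),
                              additions = NULL) {
  if (length(removals)) {
    missing_ids <- setdiff(removals, auto$id)
    if (length(missing_ids)) {
      stop("removal id(s) not present: ", paste(missing_ids, collapse = ", "))
    }
    auto <- auto[!(auto$id %in% removals), , drop = FALSE]
  }
  if (!is.null(additions) && nrow(additions)) {
    additions$source <- "manual"
    for (col in setdiff(names(auto), names(additions))) {
      additions[[col]] <- NA
    }
    additions <- additions[, names(auto), drop = FALSE]
    for (i in seq_len(nrow(additions))) {
      ov <- pmin(auto$end_s, additions$end_s[i]) -
        pmax(auto$start_s, additions$start_s[i])
      dur <- additions$end_s[i] - additions$start_s[i]
      if (any(ov / dur > 0.5, na.rm = TRUE)) {
        warning("manual addition at ", additions$start_s[i],
                " s overlaps an existing detection by > 50%; kept")
      }
    }
    auto <- rbind(auto, additions)
  }
  out <- auto[order(auto$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate D calls and their mean received level in a time window
#'
#' A detection belongs to the window if its midpoint lies in
#' `[start, end)` (half-open). The mean received level averages the dBFS
#' values directly; with zero calls it is `NA`.
#'
#' @param detections detection data frame.
#' @param window numeric `c(start_s, end_s)`.
#' @return list with `n_calls` and `mean_rl_dbfs`.
#' @export
tabulate_calls <- function(detections, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!nrow(detections)) return(list(n_calls = 0L, mean_rl_dbfs = NA_real_))
  mid <- (detections$start_s + detections$end_s) / 2
  inside <- mid >= window[1] & mid < window[2]
  n <- sum(inside)
  list(n_calls = as.integer(n),
       mean_rl_dbfs = if (n) mean(detections$rl_dbfs[inside], na.rm = TRUE)
                      else NA_real_)
}

#' Write detections as CSV alongside a Raven-style selection table
#'
#' @param detections detection data frame.
#' @param csv_path CSV output path (`NULL` to skip).
#' @param selection_path Raven-style tab-separated output path (`NULL` to
#'   skip).
#' @return `detections`, invisibly.
#' @export
write_detections <- function(detections, csv_path = NULL,
                             selection_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(detections, csv_path, row.names = FALSE)
  }
  if (!is.null(selection_path)) write_selection_table(detections,
                                                      selection_path)
  invisible(detections)
}
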