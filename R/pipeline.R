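#' Run the full before/after calling analysis on a recording
#'
#' Orchestrates the complete analysis on one station's recording: earthquake
#' selection (magnitude/bbox/period filter, 8-h isolation, optional
#' stratified weekly sampling), earthquake received-time and level
#' measurement, D-call detection (or ground-truth tabulation), song
#' intensity, before/after window metrics at all scales, matched null
#' periods, paired t-tests, linear models of the change in calling, and the
#' 15-minute binned series. Calls are extracted once at the largest scale
#' and sub-windowed to the shorter scales, so per-scale metrics are
#' consistent by construction.
#'
#' @param scenario list with `recording` (an `audio_segment`), `catalog`,
#'   `stations` data frames, and either `config$start_time` or station
#'   deployment times (as produced by [gen_scenario()]).
#' @param out_dir optional output directory for results CSVs and a run log.
#' @param scales_h analysis window scales in hours, largest first.
#' @param bbox,period,min_magnitude,isolation_hours catalog selection
#'   parameters; `period` defaults to the recording coverage.
#' @param n_events optional stratified-sample size; `NULL` keeps all
#'   isolated events.
#' @param threshold,templates detector settings; `templates = NULL` uses
#'   the default 13-template library.
#' @param use_truth if `TRUE` and `scenario$truth` exists, tabulate the
#'   ground-truth D-call annotations instead of running the detector
#'   (validation/fast path).
#' @param offset_h backward offset for null-period placement, hours.
#' @param model_scale_h scale used for the linear models (default: 2 h if
#'   present in `scales_h`, else the largest scale).
#' @param binned_span_h half-span of the 15-min binned series, hours.
#' @param default_quake_duration_s event-signal duration assumed when the
#'   rumble is not found in the audio.
#' @param seed master seed for sampling and null placement.
#' @return list of class `quakecall_results` with selected events, null
#'   events, window metrics, paired t-tests, model results, binned series
#'   and the detections used.
#' @export
run_full_analysis <- function(scenario, out_dir = NULL,
                              scales_h = c(4, 3, 2, 1),
                              bbox = c(-43, -38, 172, 176),
                              period = NULL,
                              min_magnitude = 3.0,
                              isolation_hours = 8,
                              n_events = NULL,
                              threshold = 0.80,
                              templates = NULL,
                              use_truth = FALSE,
                              offset_h = 24,
                              model_scale_h = NULL,
                              binned_span_h = 2,
                              default_quake_duration_s = 60,
                              seed = 1L) {
  recording <- scenario$recording
  stopifnot(inherits(recording, "audio_segment"))
  catalog <- scenario$catalog
  stations <- scenario$stations
  start_time <- if (!is.null(scenario$config)) scenario$config$start_time
                else stations$deploy_start[1]
  dur <- audio_duration_s(recording)
  coverage_s <- c(0, dur)
  coverage_t <- start_time + coverage_s
  if (is.null(period)) period <- coverage_t
  if (is.null(model_scale_h)) {
    model_scale_h <- if (2 %in% scales_h) 2 else max(scales_h)
  }
  station <- stations[1, , drop = FALSE]
  fs <- recording$sample_rate_hz
  hop_s <- spectrogram_preset("detection")$n_fft * 0.5 / fs
  log_lines <- c(sprintf("quakecall run: seed=%d, threshold=%.2f", seed,
                         threshold),
                 sprintf("scales_h=%s, model_scale_h=%g, offset_h=%g",
                         paste(scales_h, collapse = "/"), model_scale_h,
                         offset_h))

  ## --- 1. event selection -------------------------------------------------
  sel <- filter_catalog(catalog, bbox, period, min_magnitude)
  sel <- isolate_singular(sel, isolation_hours)
  if (!is.null(n_events) && n_events < nrow(sel)) {
    sel <- stratified_weekly_sample(sel, n_events, period, seed)
  }
  if (!nrow(sel)) stop("no earthquakes survive catalog selection")
  log_lines <- c(log_lines, sprintf("%d earthquake(s) selected", nrow(sel)))

  ## --- 2. per-event audio measurements ------------------------------------
  smax <- max(scales_h)
  if (use_truth && is.null(scenario$truth)) {
    stop("use_truth = TRUE but scenario has no truth table")
  }
  truth_det <- if (use_truth) {
    tr <- scenario$truth[scenario$truth$kind == "dcall", , drop = FALSE]
    data.frame(start_s = tr$start_s, end_s = tr$end_s,
               rl_dbfs = NA_real_, stringsAsFactors = FALSE)
  } else NULL

  analyse_event <- function(event_id, t_e, kind, event_end) {
    win <- build_windows(t_e, scales_h, event_end, coverage = coverage_s)
    ext <- range(win$start_s, win$end_s)
    ext[1] <- max(coverage_s[1], floor(ext[1] / hop_s) * hop_s)
    ext[2] <- min(coverage_s[2], ext[2])
    det <- if (use_truth) truth_det else {
      slices <- list(c(ext[1], t_e), c(event_end, ext[2]))
      dets <- lapply(slices, function(sl) {
        if (sl[2] - sl[1] < 2) return(empty_detections())
        detect_d_calls(audio_slice(recording, sl[1], sl[2]),
                       templates = templates %||% default_dcall_templates(fs),
                       threshold = threshold)
      })
      do.call(rbind, dets)
    }
    song_ext <- c(max(coverage_s[1], floor(ext[1] / 60) * 60),
                  min(coverage_s[2], ceiling(ext[2] / 60) * 60))
    song <- song_intensity_series(audio_slice(recording, song_ext[1],
                                              song_ext[2]))
    metrics <- lapply(seq_len(nrow(win)), function(i) {
      w <- c(win$start_s[i], win$end_s[i])
      tab <- tabulate_calls(det, w)
      sw <- c(floor(w[1] / 60) * 60, ceiling(w[2] / 60) * 60)
      msi <- tryCatch(suppressWarnings(mean_song_intensity(song, sw)),
                      error = function(e) NA_real_)
      data.frame(event_id = event_id, station_id = station$station_id,
                 event_kind = kind, scale_h = win$scale_h[i],
                 side = win$side[i], n_d_calls = tab$n_calls,
                 mean_rl_dbfs = tab$mean_rl_dbfs,
                 mean_song_intensity = msi,
                 truncated = win$truncated[i], stringsAsFactors = FALSE)
    })
    list(metrics = do.call(rbind, metrics), detections = det)
  }

  event_rows <- list(); det_list <- list(); quake_info <- list()
  for (i in seq_len(nrow(sel))) {
    ev <- sel[i, ]
    t_e <- as.numeric(difftime(ev$origin_time, start_time, units = "secs"))
    qm <- tryCatch(
      quake_received_metrics(recording, t_e),
      error = function(e) list(found = FALSE, received_time_s = NA,
                               rl_dbfs = NA, duration_s = NA))
    event_end <- if (isTRUE(qm$found)) {
      qm$received_time_s + qm$duration_s
    } else t_e + default_quake_duration_s
    res <- analyse_event(ev$event_id, t_e, "earthquake", event_end)
    event_rows[[length(event_rows) + 1L]] <- res$metrics
    det_list[[ev$event_id]] <- res$detections
    quake_info[[i]] <- data.frame(
      event_id = ev$event_id, station_id = station$station_id,
      magnitude = ev$magnitude, depth_km = ev$depth_km,
      distance_km = epicentre_distance_km(station, ev),
      rl_dbfs_at_hydrophone = qm$rl_dbfs,
      received_time_s = qm$received_time_s,
      event_time_s = t_e, event_end_s = event_end,
      day_of_year = as.integer(format(ev$origin_time, "%j")),
      stringsAsFactors = FALSE)
  }
  quake_info <- do.call(rbind, quake_info)

  ## --- 3. null periods -----------------------------------------------------
  nulls <- build_null_events(sel, catalog, offset_h, isolation_hours,
                             seed = seed, coverage = coverage_t,
                             scale_h_max = smax)
  nulls <- nulls[!is.na(nulls$null_time), , drop = FALSE]
  for (i in seq_len(nrow(nulls))) {
    t_n <- as.numeric(difftime(nulls$null_time[i], start_time,
                               units = "secs"))
    nid <- paste0("null_", nulls$event_id[i])
    res <- analyse_event(nid, t_n, "null", t_n)
    event_rows[[length(event_rows) + 1L]] <- res$metrics
    det_list[[nid]] <- res$detections
  }
  window_metrics <- do.call(rbind, event_rows)
  rownames(window_metrics) <- NULL

  ## --- 4. paired t-tests ---------------------------------------------------
  t_tests <- list()
  for (s in scales_h) {
    for (metric in c("n_d_calls", "mean_rl_dbfs", "mean_song_intensity")) {
      wm <- window_metrics[window_metrics$event_kind == "earthquake" &
                             window_metrics$scale_h == s, ]
      wide <- merge(
        wm[wm$side == "before", c("event_id", metric)],
        wm[wm$side == "after", c("event_id", metric)],
        by = "event_id", suffixes = c("_before", "_after"))
      wide <- wide[stats::complete.cases(wide), , drop = FALSE]
      row <- data.frame(scale_h = s, metric = metric,
                        n = nrow(wide), t = NA_real_, df = NA_real_,
                        p = NA_real_, mean_diff = NA_real_,
                        stringsAsFactors = FALSE)
      if (nrow(wide) >= 2) {
        tt <- tryCatch(paired_t_test(wide[[paste0(metric, "_before")]],
                                     wide[[paste0(metric, "_after")]]),
                       error = function(e) NULL)
        if (!is.null(tt)) {
          row$t <- tt$t; row$df <- tt$df; row$p <- tt$p
          row$mean_diff <- tt$mean_diff
        }
      }
      t_tests[[length(t_tests) + 1L]] <- row
    }
  }
  t_tests <- do.call(rbind, t_tests)

  ## --- 5. linear models ----------------------------------------------------
  build_records <- function(kind) {
    wm <- window_metrics[window_metrics$event_kind == kind &
                           window_metrics$scale_h == model_scale_h, ]
    before <- wm[wm$side == "before", ]
    after <- wm[wm$side == "after", ]
    m <- merge(before, after, by = c("event_id", "station_id"),
               suffixes = c("_before", "_after"))
    rec <- data.frame(
      event_id = m$event_id, station_id = m$station_id,
      delta_n_dcalls = m$n_d_calls_after - m$n_d_calls_before,
      delta_rl = m$mean_rl_dbfs_after - m$mean_rl_dbfs_before,
      delta_song = m$mean_song_intensity_after -
        m$mean_song_intensity_before,
      prior_n_dcalls = m$n_d_calls_before,
      prior_rl = m$mean_rl_dbfs_before,
      prior_song = m$mean_song_intensity_before,
      stringsAsFactors = FALSE)
    base_id <- sub("^null_", "", rec$event_id)
    info <- quake_info[match(base_id, quake_info$event_id), ]
    rec$day_of_year <- info$day_of_year
    if (kind == "earthquake") {
      rec$magnitude <- info$magnitude
      rec$depth_km <- info$depth_km
      rec$distance_km <- info$distance_km
      rec$rl_dbfs_at_hydrophone <- info$rl_dbfs_at_hydrophone
    }
    rec
  }
  records_eq <- build_records("earthquake")
  records_null <- build_records("null")

  model_spec <- list(
    list(kind = "earthquake", response = "delta_n_dcalls",
         prior = "prior_n_dcalls", set = "full"),
    list(kind = "earthquake", response = "delta_rl",
         prior = "prior_rl", set = "full"),
    list(kind = "earthquake", response = "delta_song",
         prior = "prior_song", set = "full"),
    list(kind = "earthquake", response = "delta_n_dcalls",
         prior = "prior_n_dcalls", set = "context_only"),
    list(kind = "null", response = "delta_n_dcalls",
         prior = "prior_n_dcalls", set = "context_only"),
    list(kind = "earthquake", response = "delta_song",
         prior = "prior_song", set = "context_only"),
    list(kind = "null", response = "delta_song",
         prior = "prior_song", set = "context_only"))
  models <- list(); model_summary <- list()
  for (ms in model_spec) {
    rec <- if (ms$kind == "earthquake") records_eq else records_null
    rec$prior_metric <- rec[[ms$prior]]
    key <- paste(ms$kind, ms$response, ms$set, sep = ".")
    fit <- tryCatch(
      suppressMessages(fit_response_model(rec, ms$response, ms$set)),
      error = function(e) e)
    models[[key]] <- fit
    model_summary[[length(model_summary) + 1L]] <- data.frame(
      kind = ms$kind, response = ms$response, predictor_set = ms$set,
      F_statistic = if (inherits(fit, "error")) NA_real_ else fit$F_statistic,
      R_squared = if (inherits(fit, "error")) NA_real_ else fit$R_squared,
      p = if (inherits(fit, "error")) NA_real_ else fit$overall_p,
      n = if (inherits(fit, "error")) NA_integer_ else fit$n,
      note = if (inherits(fit, "error")) conditionMessage(fit) else "",
      stringsAsFactors = FALSE)
  }
  model_summary <- do.call(rbind, model_summary)

  ## --- 6. binned series ----------------------------------------------------
  per_event <- lapply(seq_len(nrow(quake_info)), function(i) {
    bc <- binned_counts(det_list[[quake_info$event_id[i]]],
                        quake_info$event_time_s[i],
                        span_h = binned_span_h)
    bc$event_id <- quake_info$event_id[i]
    bc
  })
  binned <- binned_series(do.call(rbind, per_event))

  results <- structure(
    list(selected_events = sel, quake_info = quake_info,
         null_events = nulls, window_metrics = window_metrics,
         t_tests = t_tests, models = models,
         model_summary = model_summary, binned = binned,
         detections = det_list,
         params = list(scales_h = scales_h, model_scale_h = model_scale_h,
                       threshold = threshold, offset_h = offset_h,
                       seed = seed, use_truth = use_truth)),
    class = "quakecall_results")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(window_metrics,
                     file.path(out_dir, "window_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(t_tests, file.path(out_dir, "t_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(model_summary, file.path(out_dir, "models.csv"),
                     row.names = FALSE)
    utils::write.csv(binned, file.path(out_dir, "binned_series.csv"),
                     row.names = FALSE)
    write_catalog_csv(sel, file.path(out_dir, "selected_events.csv"))
    cfg_hash <- sum(utf8ToInt(paste(deparse(results$params),
                                    collapse = ""))) %% 1000000L
    writeLines(c(log_lines, sprintf("config checksum: %06d", cfg_hash)),
               file.path(out_dir, "run_log.txt"))
  }
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.quakecall_results <- function(x, ...) {
  cat(sprintf("<quakecall results: %d earthquakes, %d nulls, scales %s h>\n",
              nrow(x$selected_events), nrow(x$null_events),
              paste(x$params$scales_h, collapse = "/")))
  cat("Paired t-tests:\n")
  print(x$t_tests, digits = 3)
  invisible(x)
}
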