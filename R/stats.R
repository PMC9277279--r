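#' Build before/after analysis windows at multiple temporal scales
#'
#' For each scale `s` (hours), the before window is
#' `[event_time - s*3600, event_time)` and the after window is
#' `[event_end_time, event_end_time + s*3600)`, so the earthquake signal
#' itself belongs to neither side.
#'
#' @param event_time event onset in seconds (recording time coordinates).
#' @param scales_h numeric vector of window scales in hours.
#' @param event_end_time end of the event signal (>= `event_time`); for a
#'   zero-duration (null) event the after window starts at `event_time`.
#' @param coverage optional numeric `c(start_s, end_s)` of available
#'   recording; windows extending beyond it are flagged `truncated`.
#' @return data frame: scale_h, side, start_s, end_s, truncated.
#' @export
build_windows <- function(event_time, scales_h = c(4, 3, 2, 1),
                          event_end_time = event_time, coverage = NULL) {
  stopifnot(event_end_time >= event_time, all(scales_h > 0))
  rows <- lapply(scales_h, function(s) {
    data.frame(scale_h = c(s, s), side = c("before", "after"),
               start_s = c(event_time - s * 3600, event_end_time),
               end_s = c(event_time, event_end_time + s * 3600),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$truncated <- FALSE
  if (!is.null(coverage)) {
    out$truncated <- out$start_s < coverage[1] | out$end_s > coverage[2]
  }
  out
}

#' Select null periods matched to analysed earthquakes
#'
#' For each earthquake, a candidate null timestamp is placed `offset_h`
#' hours before its origin; if any catalog event lies within
#' `isolation_hours` of the candidate, or the candidate's analysis windows
#' would fall outside recording coverage, the candidate is shifted earlier
#' in seeded random steps of about one hour until valid. Each earthquake
#' gets exactly one null period, preserving time of year and local whale
#' behaviour while containing no earthquake.
#'
#' @param quakes data frame of analysed earthquakes (`event_id`,
#'   `origin_time`).
#' @param catalog the full earthquake catalog (times to avoid).
#' @param offset_h initial backward offset in hours.
#' @param isolation_hours required clearance from any catalog event.
#' @param seed integer RNG seed for the shift steps.
#' @param coverage optional POSIXct `c(start, end)`; null windows at scale
#'   `scale_h_max` must fit inside it.
#' @param scale_h_max largest analysis scale in hours (window half-width).
#' @param max_steps give up (with a warning and `NA`) after this many
#'   shifts.
#' @return data frame: event_id, null_time (POSIXct; `NA` if no valid slot).
#' @export
build_null_events <- function(quakes, catalog, offset_h = 24,
                              isolation_hours = 8, seed = 1L,
                              coverage = NULL, scale_h_max = 4,
                              max_steps = 200L) {
  cat_t <- as.numeric(catalog$origin_time)
  iso_s <- isolation_hours * 3600
  half_s <- scale_h_max * 3600
  with_seed(seed, {
    null_time <- vapply(seq_len(nrow(quakes)), function(i) {
      cand <- as.numeric(quakes$origin_time[i]) - offset_h * 3600
      ok <- function(x) {
        clear <- !length(cat_t) || all(abs(cat_t - x) >= iso_s)
        inside <- is.null(coverage) ||
          (x - half_s >= as.numeric(coverage[1]) &&
             x + half_s <= as.numeric(coverage[2]))
        clear && inside
      }
      steps <- 0L
      while (!ok(cand) && steps < max_steps) {
        cand <- cand - stats::runif(1, 0.5, 1.5) * 3600
        steps <- steps + 1L
      }
      if (!ok(cand)) NA_real_ else cand
    }, numeric(1))
    if (anyNA(null_time)) {
      warning(sum(is.na(null_time)), " earthquake(s) have no valid null slot")
    }
    data.frame(event_id = quakes$event_id,
               null_time = as.POSIXct(null_time, origin = "1970-01-01",
                                      tz = "UTC"),
               stringsAsFactors = FALSE)
  })
}

#' Paired t-test of before vs after metrics
#'
#' Two-sided paired t-test on the differences `after - before`, with
#' `df = n - 1`. Pairs are aligned by (event, station). The fully degenerate
#' case of identical vectors returns `t = 0, p = 1`; a constant non-zero
#' difference (zero variance, non-zero mean) is a degenerate input and
#' raises an error.
#'
#' @param before,after numeric vectors of equal length (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t_test <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- after - before
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    }
    stop("degenerate input: constant non-zero differences, t undefined")
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = n)
}

#' Linear model of the change in calling around events
#'
#' Ordinary least squares of a change metric (after minus before) on event
#' and context predictors. The `full` set uses depth, magnitude, distance
#' to the epicentre, relative received level at the hydrophone, the metric
#' in the before window, day of year, and hydrophone unit as a factor
#' (reference level: first station id lexicographically). The
#' `context_only` set uses only the prior metric, day of year and the
#' station factor. Rows with missing predictor values are dropped with a
#' message.
#'
#' @param records data frame with the response column plus `prior_metric`,
#'   `day_of_year`, `station_id`, and (for `full`) `magnitude`, `depth_km`,
#'   `distance_km`, `rl_dbfs_at_hydrophone`.
#' @param response name of the response column (e.g. `"delta_n_dcalls"`,
#'   `"delta_rl"`, `"delta_song"`).
#' @param predictor_set `"full"` or `"context_only"`.
#' @return list of class `response_model`: coefficient table, F statistic,
#'   R squared, overall p, n, formula, and the fitted `lm`.
#' @export
fit_response_model <- function(records, response,
                               predictor_set = c("full", "context_only")) {
  predictor_set <- match.arg(predictor_set)
  preds <- if (predictor_set == "full") {
    c("depth_km", "magnitude", "distance_km", "rl_dbfs_at_hydrophone",
      "prior_metric", "day_of_year")
  } else {
    c("prior_metric", "day_of_year")
  }
  needed <- c(response, preds, "station_id")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  terms <- preds
  if (length(unique(records$station_id)) > 1L) {
    records$station_id <- factor(records$station_id,
                                 levels = sort(unique(records$station_id)))
    terms <- c(terms, "station_id")
  } else {
    message("single station in records; station factor omitted")
  }
  df <- records[, c(response, terms), drop = FALSE]
  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    message(sum(!complete), " record(s) dropped for missing values")
    df <- df[complete, , drop = FALSE]
  }
  form <- stats::as.formula(paste(response, "~",
                                  paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(form, df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(df) <= ncol(mm)) {
    stop("too few records (", nrow(df), ") for ", ncol(mm), " parameters")
  }
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  overall_p <- unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                lower.tail = FALSE))
  structure(
    list(coefficients = stats::coef(sm),
         F_statistic = unname(fstat[1]),
         R_squared = sm$r.squared,
         overall_p = overall_p,
         n = nrow(df),
         formula = paste(deparse(form), collapse = " "),
         fit = fit),
    class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat("Linear model:", x$formula, "\n")
  cat(sprintf("n = %d, F = %.3f, R^2 = %.3f, p = %.4g\n",
              x$n, x$F_statistic, x$R_squared, x$overall_p))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Aggregate per-event metric series into a binned time series
#'
#' Mean and standard error across events for each 15-minute offset bin
#' surrounding the events, as used for the fine-scale time-series view of
#' calling around earthquakes.
#'
#' @param per_event long data frame with columns `event_id`,
#'   `bin_offset_min` (bin start offset from the event, minutes) and
#'   `value`.
#' @return data frame of class `binned_series`: bin_offset_min, mean,
#'   standard_error, n_events (bins with no data omitted).
#' @export
binned_series <- function(per_event) {
  stopifnot(all(c("event_id", "bin_offset_min", "value") %in%
                  names(per_event)))
  sp <- split(per_event$value, per_event$bin_offset_min)
  out <- data.frame(
    bin_offset_min = as.numeric(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    standard_error = vapply(sp, function(v) {
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    }, numeric(1)),
    n_events = vapply(sp, length, integer(1)))
  out <- out[order(out$bin_offset_min), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Per-event 15-minute call counts around an event
#'
#' @param detections detection data frame (recording time coordinates).
#' @param event_time event time in seconds.
#' @param span_h half-span in hours on each side of the event.
#' @param bin_min bin width in minutes.
#' @return data frame with `bin_offset_min` (bin start, negative = before)
#'   and `value` (call count; midpoint rule, half-open bins).
#' @export
binned_counts <- function(detections, event_time, span_h = 2, bin_min = 15) {
  offsets <- seq(-span_h * 60, span_h * 60 - bin_min, by = bin_min)
  value <- vapply(offsets, function(o) {
    w <- event_time + c(o, o + bin_min) * 60
    tabulate_calls(detections, w)$n_calls
  }, integer(1))
  data.frame(bin_offset_min = offsets, value = value)
}

#' Simulate per-event before/after call counts through the window machinery
#'
#' Draws Poisson-process D-call times in the before and after windows of
#' `n_events` independent events and tabulates them with the same
#' half-open-window midpoint rule the detector tabulation uses. Used for
#' type-I error and power calibration of the paired design.
#'
#' @param n_events number of events.
#' @param rate_before,rate_after Poisson intensities (calls/hour).
#' @param scale_h window scale in hours.
#' @param seed integer RNG seed.
#' @return data frame: event_id, before, after (counts).
#' @export
simulate_before_after_counts <- function(n_events, rate_before, rate_after,
                                         scale_h = 2, seed = 1L) {
  with_seed(seed, {
    span <- scale_h * 3600
    event_time <- span  # recording-local time of the event
    win <- build_windows(event_time, scales_h = scale_h)
    res <- t(vapply(seq_len(n_events), function(i) {
      draw <- function(rate, t0, t1) {
        k <- stats::rpois(1, rate * (t1 - t0) / 3600)
        stats::runif(k, t0, t1)
      }
      times <- c(draw(rate_before, 0, span), draw(rate_after, span, 2 * span))
      det <- data.frame(start_s = times, end_s = times,
                        rl_dbfs = rep(NA_real_, length(times)))
      b <- tabulate_calls(det, c(win$start_s[win$side == "before"],
                                 win$end_s[win$side == "before"]))$n_calls
      a <- tabulate_calls(det, c(win$start_s[win$side == "after"],
                                 win$end_s[win$side == "after"]))$n_calls
      c(before = b, after = a)
    }, c(before = 0L, after = 0L)))
    data.frame(event_id = sprintf("sim%04d", seq_len(n_events)),
               before = res[, "before"], after = res[, "after"])
  })
}

#' Type-I error / power calibration of the paired before-after test
#'
#' Runs `n_replicates` independent simulated studies of `n_events` events
#' each and reports the fraction in which the paired t-test on D-call
#' counts rejects at level `alpha`. With equal rates this estimates the
#' type-I error; with different rates, the power.
#'
#' @param n_replicates number of simulated studies.
#' @param n_events events per study.
#' @param rate_before,rate_after calls/hour in the before/after windows.
#' @param scale_h window scale in hours.
#' @param alpha test level.
#' @param seed master integer seed (per-replicate seeds derived from it).
#' @return list with `rejection_rate` and the vector of `p_values`.
#' @export
calibrate_paired_test <- function(n_replicates = 50, n_events = 32,
                                  rate_before = 10, rate_after = 10,
                                  scale_h = 2, alpha = 0.05, seed = 1L) {
  p <- vapply(seq_len(n_replicates), function(r) {
    counts <- simulate_before_after_counts(n_events, rate_before,
                                           rate_after, scale_h,
                                           seed = seed * 1000L + r)
    paired_t_test(counts$before, counts$after)$p
  }, numeric(1))
  list(rejection_rate = mean(p < alpha), p_values = p)
}

#' Regression-to-the-mean control simulation
#'
#' With before/after counts i.i.d. per event (no event effect), the
#' regression slope of the change (after - before) on the before count
#' converges to `rho - 1`, where `rho` is the before/after correlation;
#' for independent counts the slope is -1. The simulation draws such counts
#' for events labelled "earthquake" and "null", fits the slope in each
#' group, and tests the group difference with an interaction term --
#' mirroring the control finding that the negative prior-calling
#' relationship is independent of earthquake presence.
#'
#' @param n_events events per group.
#' @param rate Poisson intensity (calls per window).
#' @param seed integer RNG seed.
#' @return list with per-group slopes and standard errors, 95% CIs, and
#'   the p-value of the group-difference interaction.
#' @export
simulate_rtm_control <- function(n_events = 2000, rate = 20, seed = 1L) {
  with_seed(seed, {
    sim_group <- function(label) {
      before <- stats::rpois(n_events, rate)
      after <- stats::rpois(n_events, rate)
      data.frame(label = label, before = before, delta = after - before)
    }
    df <- rbind(sim_group("earthquake"), sim_group("null"))
    one <- function(lbl) {
      f <- stats::lm(delta ~ before, data = df[df$label == lbl, ])
      est <- summary(f)$coefficients["before", ]
      list(slope = unname(est["Estimate"]), se = unname(est["Std. Error"]),
           ci = unname(est["Estimate"] + c(-1.96, 1.96) * est["Std. Error"]))
    }
    eq <- one("earthquake"); nl <- one("null")
    inter <- stats::lm(delta ~ before * label, data = df)
    p_inter <- summary(inter)$coefficients["before:labelnull", "Pr(>|t|)"]
    list(slope_earthquake = eq$slope, se_earthquake = eq$se,
         ci_earthquake = eq$ci,
         slope_null = nl$slope, se_null = nl$se, ci_null = nl$ci,
         interaction_p = p_inter)
  })
}
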