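#' Filter an earthquake catalog by magnitude, bounding box and period
#'
#' Keeps events with magnitude strictly greater than `min_magnitude`, with
#' epicentre inside the closed bounding box, and origin time inside the
#' closed period. Input order is preserved.
#'
#' @param events catalog data frame with `origin_time` (POSIXct),
#'   `magnitude`, `lat`, `lon` columns.
#' @param bbox numeric `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param period POSIXct vector `c(t0, t1)`.
#' @param min_magnitude magnitude cut; events must exceed it strictly.
#' @return the filtered catalog (possibly zero rows).
#' @export
filter_catalog <- function(events, bbox, period, min_magnitude = 3.0) {
  stopifnot(length(bbox) == 4, bbox[1] <= bbox[2], bbox[3] <= bbox[4],
            length(period) == 2, period[1] <= period[2])
  if (nrow(events) == 0L) return(events)
  keep <- events$magnitude > min_magnitude &
    events$lat >= bbox[1] & events$lat <= bbox[2] &
    events$lon >= bbox[3] & events$lon <= bbox[4] &
    events$origin_time >= period[1] & events$origin_time <= period[2]
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only temporally isolated earthquakes
#'
#' Retains events with no other catalog event within `isolation_hours` of
#' their origin time, separating singular earthquakes from swarms or drums.
#' Exclusion is symmetric (both members of a close pair are dropped) and
#' strict: a gap of exactly `isolation_hours` counts as isolated.
#'
#' @param events catalog data frame with an `origin_time` column.
#' @param isolation_hours isolation radius in hours (default 8).
#' @return the isolated subset, original order preserved.
#' @export
isolate_singular <- function(events, isolation_hours = 8) {
  if (nrow(events) < 2L) return(events)
  t <- as.numeric(events$origin_time)
  gap_s <- isolation_hours * 3600
  keep <- vapply(seq_along(t), function(i) {
    all(abs(t[-i] - t[i]) >= gap_s)
  }, logical(1))
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified weekly sample of earthquakes
#'
#' Partitions the analysis period into consecutive 7-day strata anchored at
#' the period start, selects one event uniformly at random from each
#' non-empty stratum, then fills the remaining quota by uniform sampling
#' without replacement from the unselected events. This guarantees at least
#' one selected earthquake in every week that has one, giving temporal
#' coverage of the recording period.
#'
#' @param events catalog data frame with `origin_time`.
#' @param n total number of events to select; must be at least the number
#'   of non-empty weeks and at most `nrow(events)`.
#' @param period POSIXct `c(t0, t1)`; weeks are counted from `t0`.
#' @param seed integer RNG seed (selection is deterministic given it).
#' @return the selected events, sorted by origin time.
#' @export
stratified_weekly_sample <- function(events, n, period, seed = 1L) {
  if (n > nrow(events)) {
    stop("n (", n, ") exceeds the number of available events (",
         nrow(events), ")")
  }
  week <- floor(as.numeric(difftime(events$origin_time, period[1],
                                    units = "days")) / 7)
  nonempty <- sort(unique(week))
  if (n < length(nonempty)) {
    stop("n (", n, ") is smaller than the number of non-empty weeks (",
         length(nonempty), ")")
  }
  with_seed(seed, {
    picked <- integer(0)
    for (w in nonempty) {
      idx <- which(week == w)
      picked <- c(picked, if (length(idx) == 1L) idx else sample(idx, 1L))
    }
    remaining <- setdiff(seq_len(nrow(events)), picked)
    extra <- n - length(picked)
    if (extra > 0L) {
      picked <- c(picked, if (length(remaining) == 1L) remaining
                  else sample(remaining, extra))
    }
    out <- events[sort(picked), , drop = FALSE]
    out <- out[order(out$origin_time), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Great-circle distance from a hydrophone station to an epicentre
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km. This is
#' a deliberately spherical (not ellipsoidal) computation; at the scales of
#' a regional earthquake catalog the difference is below 0.5% and immaterial
#' to any downstream model.
#'
#' @param station a list/one-row data frame with `lat`, `lon` (degrees), or
#'   a numeric `c(lat, lon)`.
#' @param event likewise for the epicentre.
#' @return distance in km (vectorized over rows of `event`).
#' @export
epicentre_distance_km <- function(station, event) {
  coords <- function(p) {
    if (is.numeric(p) && length(p) == 2) list(lat = p[1], lon = p[2])
    else list(lat = p$lat, lon = p$lon)
  }
  a <- coords(station); b <- coords(event)
  if (any(abs(c(a$lat, b$lat)) > 90) || any(abs(c(a$lon, b$lon)) > 180)) {
    stop("invalid coordinates: |lat| <= 90 and |lon| <= 180 required")
  }
  r_earth <- 6371.0088
  to_rad <- pi / 180
  dlat <- (b$lat - a$lat) * to_rad
  dlon <- (b$lon - a$lon) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(a$lat * to_rad) * cos(b$lat * to_rad) * sin(dlon / 2)^2
  2 * r_earth * asin(pmin(1, sqrt(h)))
}

#' Read an earthquake catalog CSV
#'
#' Expected columns: event_id, origin_time (ISO-8601 UTC), magnitude,
#' depth_km, lat, lon.
#'
#' @param path CSV path.
#' @return catalog data frame with POSIXct origin times (UTC).
#' @export
read_catalog_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$origin_time <- as.POSIXct(df$origin_time, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S")
  df
}

#' Write an earthquake catalog CSV with ISO-8601 UTC timestamps
#'
#' @param events catalog data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog_csv <- function(events, path) {
  df <- events
  df$origin_time <- format(df$origin_time, "%Y-%m-%dT%H:%M:%S",
                           tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
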