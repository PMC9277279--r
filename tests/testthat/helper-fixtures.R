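# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# The standard 50-call detector validation fixture plus its detections.
get_detector_fixture <- function() {
  if (is.null(.fixture_cache$detfix)) {
    fix <- standard_detector_fixture(seed = 42L)
    fix$detections <- detect_d_calls(fix$audio)
    .fixture_cache$detfix <- fix
  }
  .fixture_cache$detfix
}

# A toy six-event catalog exercising every selection rule by hand:
# rows 1-2 fail the magnitude cut (3.0 is excluded by the strict inequality),
# row 3 is outside the bounding box, row 4 outside the period, rows 5-6 pass.
toy_catalog <- function() {
  t0 <- as.POSIXct("2016-02-01 00:00:00", tz = "UTC")
  data.frame(
    event_id = sprintf("t%02d", 1:6),
    origin_time = t0 + c(1, 2, 3, 40, 5, 6) * 86400,
    magnitude = c(2.5, 3.0, 3.6, 3.8, 3.5, 4.2),
    depth_km = rep(12, 6),
    lat = c(-40, -40, -50, -40, -40, -41),
    lon = c(174, 174, 174, 174, 174, 173),
    stringsAsFactors = FALSE)
}

toy_bbox <- c(-43, -38, 172, 176)
toy_period <- as.POSIXct(c("2016-02-01", "2016-03-01"), tz = "UTC")

# Event records with two stations and a response that is exactly linear in
# the prior metric, for model identities.
make_records <- function(n, seed = 1L, noise_sd = 0) {
  set.seed(seed)
  data.frame(
    event_id = sprintf("e%03d", seq_len(n)),
    station_id = rep(c("MARU1", "MARU2"), length.out = n),
    magnitude = runif(n, 3, 4.5),
    depth_km = runif(n, 5, 40),
    distance_km = runif(n, 10, 300),
    rl_dbfs_at_hydrophone = runif(n, -40, 0),
    prior_metric = rpois(n, 30),
    day_of_year = sample(30:180, n, replace = TRUE),
    noise = rnorm(n, 0, max(noise_sd, 1e-12)),
    stringsAsFactors = FALSE)
}
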