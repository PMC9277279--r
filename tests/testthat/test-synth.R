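test_that("D-call generator produces a deterministic, tapered downsweep", {
  expect_identical(gen_d_call(2, 100, 20, 0, 2000)$samples,
                   numeric(4000))
  a <- gen_d_call(2, 100, 20, 0.5, 2000)
  b <- gen_d_call(2, 100, 20, 0.5, 2000)
  expect_identical(a$samples, b$samples)
  expect_lte(max(abs(a$samples)), 0.5)
  expect_error(gen_d_call(-1, 100, 20), "duration")
  expect_error(gen_d_call(2, 20, 100), "downsweep")
})

test_that("D-call instantaneous frequency sweeps 100 to 20 Hz", {
  # fine-time spectrogram (n_fft 256 -> 7.8 Hz bins, 0.128 s frames) so the
  # first and last frames sit inside the first/last 10% of the call
  call <- gen_d_call(2, 100, 20, 0.5, 2000)
  sp <- compute_spectrogram(call, n_fft = 256L)
  bin_w <- 2000 / 256
  first_peak <- sp$freqs_hz[which.max(sp$power[, 1])]
  last_peak <- sp$freqs_hz[which.max(sp$power[, ncol(sp$power)])]
  expect_lte(abs(first_peak - 100), bin_w)
  expect_lte(abs(last_peak - 20), bin_w)
})

test_that("song unit concentrates energy in the 17-24 Hz song band", {
  expect_identical(gen_song_unit(0)$samples,
                   gen_song_unit(1)$samples * 0)
  u <- gen_song_unit(0.3, 2000)
  sp <- compute_spectrogram(u)
  frac <- selection_power(sp, selection(0, 13, 17, 24))$total / sum(sp$power)
  expect_gte(frac, 0.5)
  # tonal tail is centered in the 23-24 Hz predominant band
  tail4 <- audio_slice(u, audio_duration_s(u) - 4, audio_duration_s(u))
  spt <- compute_spectrogram(tail4, n_fft = 2048L)
  peak <- spt$freqs_hz[which.max(spt$power[, ncol(spt$power)])]
  expect_gte(peak, 23 - 2000 / 2048)
  expect_lte(peak, 24 + 2000 / 2048)
  # quadratic energy scaling
  e1 <- sum(gen_song_unit(0.2)$samples^2)
  e2 <- sum(gen_song_unit(0.4)$samples^2)
  expect_equal(e2 / e1, 4, tolerance = 1e-6)
})

test_that("quake rumble is seeded, band-limited, and decays", {
  expect_identical(gen_quake_rumble(10, 0, seed = 1)$samples, numeric(20000))
  r1 <- gen_quake_rumble(60, 0.5, seed = 7)
  r2 <- gen_quake_rumble(60, 0.5, seed = 7)
  expect_identical(r1$samples, r2$samples)
  sp <- compute_spectrogram(r1)
  frac_low <- selection_power(sp, selection(0, 60, 0, 100))$total /
    sum(sp$power)
  expect_gte(frac_low, 0.9)
})

test_that("empty scenario is pure noise and scenarios are reproducible", {
  cfg <- scenario_config(duration_s = 120, dcall_rate_before = 0,
                         dcall_rate_after = 0, song_gain_before = 0,
                         song_gain_after = 0, noise_rms = 0.01, seed = 3)
  scen <- gen_scenario(cfg)
  expect_equal(nrow(scen$truth), 0)
  expect_equal(length(scen$recording$samples), 120 * 2000)
  expect_lt(abs(sd(scen$recording$samples) - 0.01), 0.002)

  cfg2 <- scenario_config(duration_s = 600, dcall_rate_before = 30,
                          dcall_rate_after = 30, quake_times = 300,
                          noise_rms = 0.01, seed = 9)
  s1 <- suppressWarnings(gen_scenario(cfg2))
  s2 <- suppressWarnings(gen_scenario(cfg2))
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$catalog, s2$catalog)
  # truth-only fast path yields the same tables
  s3 <- suppressWarnings(gen_scenario(cfg2, render_audio = FALSE))
  expect_null(s3$recording)
  expect_identical(s3$truth, s1$truth)
  # all annotations inside the recording
  expect_true(all(s1$truth$start_s >= 0 & s1$truth$end_s <= 600))
})

test_that("recording energy grows when components are added to noise", {
  base <- scenario_config(duration_s = 120, dcall_rate_before = 0,
                          dcall_rate_after = 0, song_gain_before = 0,
                          song_gain_after = 0, noise_rms = 0.01, seed = 5)
  with_calls <- scenario_config(duration_s = 120, dcall_rate_before = 120,
                                dcall_rate_after = 120, song_gain_before = 1,
                                song_gain_after = 1, noise_rms = 0.01,
                                seed = 5)
  e0 <- sum(gen_scenario(base)$recording$samples^2)
  e1 <- sum(suppressWarnings(gen_scenario(with_calls))$recording$samples^2)
  expect_gt(e1, e0)
})

test_that("scenario D-call counts are Poisson-dispersed across replicates", {
  counts <- vapply(1:500, function(s) {
    cfg <- scenario_config(duration_s = 3600, dcall_rate_before = 12,
                           dcall_rate_after = 12, song_gain_before = 0,
                           song_gain_after = 0, seed = s)
    scen <- suppressWarnings(gen_scenario(cfg, render_audio = FALSE))
    sum(scen$truth$kind == "dcall")
  }, numeric(1))
  ratio <- var(counts) / mean(counts)
  expect_gte(ratio, 0.8)
  expect_lte(ratio, 1.2)
})

test_that("under equal rates the mean after-before difference is near zero", {
  counts <- simulate_before_after_counts(1000, 10, 10, scale_h = 2,
                                         seed = 21)
  d <- counts$after - counts$before
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
})

test_that("extreme amplitudes clip with a warning rather than an error", {
  cfg <- scenario_config(duration_s = 120, dcall_rate_before = 0,
                         dcall_rate_after = 0, song_gain_before = 0,
                         song_gain_after = 0, quake_times = 10,
                         quake_amplitude = 5, noise_rms = 0.01, seed = 2)
  expect_warning(scen <- gen_scenario(cfg), "clipped")
  expect_true(all(abs(scen$recording$samples) <= 1))
})

test_that("gen_catalog produces isolated events and swarms as labelled", {
  bbox <- c(-43, -38, 172, 176)
  period <- as.POSIXct(c("2016-02-01", "2016-06-01"), tz = "UTC")
  one <- gen_catalog(1, 0, bbox, period, seed = 4)
  expect_equal(nrow(one), 1)
  expect_true(one$lat >= bbox[1] && one$lat <= bbox[2])
  expect_true(one$origin_time >= period[1] && one$origin_time <= period[2])

  cat11 <- gen_catalog(5, 2, bbox, period, seed = 8, cluster_size = 3)
  expect_equal(nrow(cat11), 11)
  surv <- isolate_singular(cat11, 8)
  expect_equal(nrow(surv), 5)
  expect_true(all(cat11$magnitude >= 3.0 & cat11$magnitude <= 4.5))
  expect_identical(cat11, gen_catalog(5, 2, bbox, period, seed = 8,
                                      cluster_size = 3))
  # too many events for the period
  short <- as.POSIXct(c("2016-02-01", "2016-02-02"), tz = "UTC")
  expect_error(gen_catalog(10, 0, bbox, short, seed = 1), "infeasible")
})

test_that("selection tables roundtrip through the Raven-style format", {
  truth <- data.frame(start_s = c(1, 5), end_s = c(3, 6.5),
                      f_low_hz = c(20, 25), f_high_hz = c(100, 90))
  path <- withr::local_tempfile(fileext = ".txt")
  write_selection_table(truth, path)
  back <- read_selection_table(path)
  expect_equal(back, truth)
})
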