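test_that("template library has 13 normalized, gain-invariant templates", {
  tpl <- default_dcall_templates()
  expect_length(tpl, 13)
  for (tp in tpl) {
    expect_equal(mean(tp$patch), 0, tolerance = 1e-12)
    expect_equal(sum(tp$patch^2), 1, tolerance = 1e-12)
  }
  # exemplar amplitude does not change the normalized patch
  e1 <- gen_d_call(2, 100, 20, 0.1)
  e10 <- gen_d_call(2, 100, 20, 1.0)
  t1 <- build_templates(list(e1))[[1]]
  t10 <- build_templates(list(e10))[[1]]
  expect_equal(t1$patch, t10$patch, tolerance = 1e-12)
  expect_error(build_templates(list(audio_segment(numeric(100), 2000))),
               "shorter")
})

test_that("correlation peaks at 1 for exact and amplitude-scaled copies", {
  tpl <- default_dcall_templates()
  src <- gen_d_call(2, 100, 20, 1)          # source of tpl02 (2 s, 100-20)
  sp <- compute_spectrogram(src)
  tr <- correlation_track(sp, tpl[[2]])
  expect_equal(max(tr$scores), 1, tolerance = 1e-6)
  # embedded in silence (hop-aligned): peak 1.0 at the true lag
  pad <- audio_segment(c(numeric(8192), src$samples, numeric(8192)), 2000)
  trp <- correlation_track(compute_spectrogram(pad), tpl[[2]])
  peak_lag <- trp$lag_times_s[which.max(trp$scores)]
  expect_equal(max(trp$scores), 1, tolerance = 1e-6)
  expect_equal(peak_lag, 8192 / 2000, tolerance = 1e-9)
  # waveform scaled x0.3: correlation on the power patch is gain-invariant
  scaled <- audio_segment(0.3 * src$samples, 2000)
  trs <- correlation_track(compute_spectrogram(scaled), tpl[[2]])
  expect_equal(max(trs$scores), 1, tolerance = 0.01)
})

test_that("correlation against pure noise stays below the 0.80 threshold", {
  set.seed(41)
  noise <- audio_segment(rnorm(2000 * 600, 0, 0.01), 2000)
  sp <- compute_spectrogram(noise)
  tpl <- default_dcall_templates()
  tr <- correlation_track(sp, tpl[[2]])
  expect_gte(length(tr$scores), 1000)
  expect_lt(max(tr$scores), 0.8)
  expect_true(all(tr$scores <= 1 + 1e-9 & tr$scores >= -1 - 1e-9))
})

test_that("injected calls are detected at their true times, noise is not", {
  fs <- 2000
  set.seed(42)
  x <- rnorm(fs * 120, 0, 0.01)
  starts <- c(10.3, 30.05, 55.7, 80.21, 100.5)
  for (a in starts) {
    cl <- gen_d_call(2, 100, 20, 0.08, fs)$samples
    i0 <- round(a * fs) + 1
    x[i0:(i0 + length(cl) - 1)] <- x[i0:(i0 + length(cl) - 1)] + cl
  }
  aud <- audio_segment(x, fs)
  det <- detect_d_calls(aud)
  expect_equal(nrow(det), 5)
  for (a in starts) expect_true(any(abs(det$start_s - a) <= 0.5))
  expect_true(all(det$score <= 1 + 1e-9))
  expect_true(all(det$rl_dbfs <= 0))
  # determinism: no internal randomness
  expect_identical(det, detect_d_calls(aud))
  # unattainable threshold
  expect_equal(nrow(detect_d_calls(aud, threshold = 1.01)), 0)
  # noise-only audio
  set.seed(43)
  noise <- audio_segment(rnorm(fs * 120, 0, 0.01), fs)
  expect_equal(nrow(detect_d_calls(noise)), 0)
})

test_that("detector meets recall/precision >= 0.90 on the standard fixture", {
  fix <- get_detector_fixture()
  sc <- score_detections(fix$detections, fix$truth)
  expect_gte(sc$recall, 0.90)
  expect_gte(sc$precision, 0.90)
})

test_that("detection count is monotone non-increasing in threshold", {
  fix <- get_detector_fixture()
  counts <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(th) {
    nrow(detect_d_calls(fix$audio, threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("annotation merging follows analyst review semantics", {
  fix <- get_detector_fixture()
  auto <- fix$detections[1:10, ]
  # identity
  expect_identical(merge_annotations(auto), auto)
  # remove 2, add 1 -> 9, time-sorted, manual flagged
  add <- data.frame(start_s = 700.123, end_s = 702.123, f_low_hz = 20,
                    f_high_hz = 100, score = NA_real_)
  merged <- merge_annotations(auto, removals = auto$id[c(3, 7)],
                              additions = add)
  expect_equal(nrow(merged), 9)
  expect_false(is.unsorted(merged$start_s))
  expect_equal(sum(merged$source == "manual"), 1)
  # remove all -> additions only
  only_add <- merge_annotations(auto, removals = auto$id, additions = add)
  expect_equal(nrow(only_add), 1)
  expect_equal(only_add$source, "manual")
  # unknown removal id
  expect_error(merge_annotations(auto, removals = "nope"), "not present")
  # duplicate addition warns but is kept
  dup <- auto[1, c("start_s", "end_s", "f_low_hz", "f_high_hz")]
  expect_warning(kept <- merge_annotations(auto, additions = dup),
                 "overlaps")
  expect_equal(nrow(kept), 11)
})

test_that("call tabulation uses half-open windows on midpoints", {
  expect_equal(tabulate_calls(data.frame(start_s = numeric(0),
                                         end_s = numeric(0),
                                         rl_dbfs = numeric(0)),
                              c(0, 100)),
               list(n_calls = 0L, mean_rl_dbfs = NA_real_))
  det <- data.frame(start_s = c(10, 20, 30), end_s = c(12, 22, 32),
                    rl_dbfs = c(-20, -20, -20))
  expect_equal(tabulate_calls(det, c(0, 100)),
               list(n_calls = 3L, mean_rl_dbfs = -20))
  # midpoints at t-1 and t+1 around a window starting exactly at t
  t <- 50
  det2 <- data.frame(start_s = c(t - 1, t + 1), end_s = c(t - 1, t + 1),
                     rl_dbfs = c(-10, -30))
  expect_equal(tabulate_calls(det2, c(t, t + 100))$n_calls, 1L)
  expect_equal(tabulate_calls(det2, c(t - 100, t))$n_calls, 1L)
})
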