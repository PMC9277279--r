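test_that("before/after windows exclude the event signal at every scale", {
  # event at t = 10000 s lasting 60 s, 1-h scale
  w <- build_windows(10000, scales_h = 1, event_end_time = 10060)
  expect_equal(w$start_s, c(6400, 10060))
  expect_equal(w$end_s, c(10000, 13660))
  # four scales -> four before/after pairs
  w4 <- build_windows(10000, scales_h = c(4, 3, 2, 1),
                      event_end_time = 10060)
  expect_equal(nrow(w4), 8)
  expect_equal(unique(w4$scale_h), c(4, 3, 2, 1))
  # zero-duration event: after begins at the event time
  w0 <- build_windows(5000, scales_h = 1)
  expect_equal(w0$start_s[w0$side == "after"], 5000)
  # truncation flag against coverage
  wt <- build_windows(1000, scales_h = 1, coverage = c(0, 36000))
  expect_true(wt$truncated[wt$side == "before"])
  expect_false(wt$truncated[wt$side == "after"])
})

test_that("null periods are matched one-to-one and avoid all earthquakes", {
  t0 <- as.POSIXct("2016-02-10 00:00:00", tz = "UTC")
  quakes <- data.frame(event_id = "q1", origin_time = t0)
  empty_cat <- quakes[0, ]
  nulls <- build_null_events(quakes, empty_cat, offset_h = 24, seed = 1)
  expect_equal(as.numeric(nulls$null_time), as.numeric(t0) - 24 * 3600)

  bbox <- c(-43, -38, 172, 176)
  period <- as.POSIXct(c("2016-02-01", "2016-06-01"), tz = "UTC")
  catalog <- gen_catalog(8, 2, bbox, period, seed = 61)
  analysed <- isolate_singular(catalog, 8)
  nulls2 <- build_null_events(analysed, catalog, offset_h = 24, seed = 2)
  expect_equal(nrow(nulls2), nrow(analysed))
  for (nt in nulls2$null_time) {
    gaps_h <- abs(as.numeric(difftime(catalog$origin_time, nt,
                                      units = "hours")))
    expect_gte(min(gaps_h), 8)
  }
})

test_that("paired t-test matches hand computation and handles degeneracy", {
  # diffs [2, -1, 2]: mean 1, sd sqrt(3), t = 1 exactly, df = 2
  tt <- paired_t_test(c(10, 12, 8), c(12, 11, 10))
  expect_equal(tt$t, 1.000, tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 2 * pt(-1, df = 2), tolerance = 1e-12)
  # identical vectors: t = 0, p = 1
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant non-zero difference is degenerate
  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)), "degenerate")
})

test_that("response model recovers exact fits and matches normal equations", {
  rec <- make_records(50, seed = 71)
  # exact linear response -> R^2 = 1
  rec$delta <- 3 - 0.8 * rec$prior_metric
  m <- suppressWarnings(
    suppressMessages(fit_response_model(rec, "delta", "context_only")))
  expect_equal(m$R_squared, 1, tolerance = 1e-9)
  # noisy full model: coefficients equal the normal-equations solve
  rec$delta <- 5 - 0.5 * rec$prior_metric + 0.02 * rec$distance_km +
    rnorm(50, 0, 2)
  m2 <- fit_response_model(rec, "delta", "full")
  X <- model.matrix(as.formula(m2$formula),
                    transform(rec, station_id = factor(station_id)))
  beta <- solve(t(X) %*% X, t(X) %*% rec$delta)
  expect_equal(unname(m2$coefficients[, "Estimate"]), as.numeric(beta),
               tolerance = 1e-8)
  # R^2 equals 1 - SSE/SST by brute force
  pred <- as.numeric(X %*% beta)
  r2 <- 1 - sum((rec$delta - pred)^2) / sum((rec$delta - mean(rec$delta))^2)
  expect_equal(m2$R_squared, r2, tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly, naming the collinear term", {
  rec <- make_records(40, seed = 72)
  rec$delta <- rnorm(40)
  rec$distance_km <- 2 * rec$depth_km       # exact collinearity
  expect_error(fit_response_model(rec, "delta", "full"),
               "collinear.*distance_km")
  expect_error(fit_response_model(make_records(5, seed = 1), "delta",
                                  "full"),
               "lack column|too few")
})

test_that("under a null response the overall model p-value is uniform", {
  pvals <- vapply(1:200, function(s) {
    rec <- make_records(200, seed = 1000 + s, noise_sd = 1)
    rec$delta <- rec$noise
    fit_response_model(rec, "delta", "context_only")$overall_p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("binned series aggregates per-event metrics with SE across events", {
  pe <- expand.grid(event_id = sprintf("e%d", 1:5),
                    bin_offset_min = seq(-120, 105, by = 15))
  pe$value <- 7
  bs <- binned_series(pe)
  expect_equal(nrow(bs), 16)             # 2 h each side at 15-min bins
  expect_true(all(bs$mean == 7))
  expect_true(all(bs$standard_error == 0))
  expect_true(all(bs$n_events == 5))
  # single event: SE 0, n_events flagged as 1
  one <- pe[pe$event_id == "e1", ]
  bs1 <- binned_series(one)
  expect_true(all(bs1$n_events == 1))
  expect_true(all(bs1$standard_error == 0))
  # binned_counts produces the 16-bin layout around an event
  det <- data.frame(start_s = c(3500, 7300), end_s = c(3502, 7302),
                    rl_dbfs = c(-20, -25))
  bc <- binned_counts(det, event_time = 7200, span_h = 2)
  expect_equal(nrow(bc), 16)
  expect_equal(sum(bc$value), 2)
})

test_that("iid before/after counts regress to the mean with slope -1", {
  rtm <- simulate_rtm_control(n_events = 2000, rate = 20, seed = 81)
  expect_lte(rtm$ci_earthquake[1], -1)
  expect_gte(rtm$ci_earthquake[2], -1)
  expect_lte(rtm$ci_null[1], -1)
  expect_gte(rtm$ci_null[2], -1)
  # the prior-calling relationship does not differ between labels
  expect_gt(rtm$interaction_p, 0.05)
})

test_that("paired design calibration: level under the null, power under 3x", {
  cal0 <- calibrate_paired_test(20, 32, 10, 10, scale_h = 2, seed = 91)
  expect_lte(cal0$rejection_rate, 0.15)
  cal1 <- calibrate_paired_test(20, 32, 10, 30, scale_h = 2, seed = 91)
  expect_gte(cal1$rejection_rate, 0.9)
})
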