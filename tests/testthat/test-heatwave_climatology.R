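test_that("fit_climatology matches the sorted-interpolation quantile oracle", {
  # constant record: every populated threshold equals the constant
  tp <- make_temp(hours_utc(2 * 8766, "1990-01-01 00:00:00"), 20)
  thr <- fit_climatology(tp, q = 0.85, allow_short = TRUE)
  expect_true(all(thr$threshold_c == 20))
  expect_lte(nrow(thr), 288L)

  # one cell holding 1..100 across years: January 1st, 00:00, 100 years
  ts <- as.POSIXct(sprintf("%d-01-01 00:00:00", 1900:1999), tz = "UTC")
  thr2 <- fit_climatology(make_temp(ts, 1:100), q = 0.85, min_n = 30, allow_short = TRUE)
  expect_equal(thr2$threshold_c, oracle_quantile(1:100, 0.85))
  expect_equal(thr2$threshold_c, 85.15)
})

test_that("a >= 30-yr record populates exactly 24 cells per month", {
  temp <- generate_temperature(synth_config(seed = 5), years = 30)
  thr <- fit_climatology(temp, q = 0.85)
  counts <- table(thr$month)
  expect_equal(length(counts), 12L)
  expect_true(all(counts == 24L))
})

test_that("short records are rejected with the year counts", {
  tp <- make_temp(hours_utc(8766, "2010-01-01 00:00:00"), 15)
  expect_error(fit_climatology(tp), "2 year\\(s\\); 30 required")
  expect_s3_class(fit_climatology(tp, allow_short = TRUE), "climatology_thresholds")
})

test_that("classify_heat uses strict exceedance and excludes unpopulated cells", {
  tp <- make_temp(hours_utc(3 * 8766, "1990-01-01 00:00:00"), 20)
  thr <- fit_climatology(tp, allow_short = TRUE)

  ts <- hours_utc(3, "1993-06-15 00:00:00")
  ds <- make_aligned(ts, rs = 1, tair_c = c(20.1, 20, 19))
  hl <- classify_heat(ds, thr)
  expect_equal(hl$heat, c("HW", "NHW", "NHW"))
  expect_equal(attr(hl, "n_excluded"), 0L)
  expect_equal(heatwave_fraction(hl), 1 / 3)

  # only-June climatology: other months are excluded, not defaulted
  jun <- structure(tibble::as_tibble(thr)[thr$month == 6, ],
                   q = 0.85, class = class(thr))
  ds2 <- make_aligned(hours_utc(2, "1993-07-01 00:00:00"), rs = 1, tair_c = 30)
  expect_warning(hl2 <- classify_heat(ds2, jun), "all threshold cells unpopulated")
  expect_equal(nrow(hl2), 0L)
  expect_equal(attr(hl2, "n_excluded"), 2L)
})

test_that("heatwave_fraction handles degenerate label sets", {
  ts <- hours_utc(4)
  expect_equal(heatwave_fraction(make_heat_labels(ts, rep("NHW", 4))), 0)
  expect_equal(heatwave_fraction(make_heat_labels(ts, c("HW", "HW", "NHW", "NHW"))), 0.5)
  expect_error(heatwave_fraction(make_heat_labels(ts[0], character(0))), "no labelled hours")
})

test_that("thresholds are monotone in q and self-classification recovers 1 - q", {
  temp <- generate_temperature(synth_config(seed = 6, hw_rate = 0), years = 4)
  t50 <- fit_climatology(temp, q = 0.50, allow_short = TRUE)
  t85 <- fit_climatology(temp, q = 0.85, allow_short = TRUE)
  t95 <- fit_climatology(temp, q = 0.95, allow_short = TRUE)
  expect_true(all(t85$threshold_c >= t50$threshold_c))
  expect_true(all(t95$threshold_c >= t85$threshold_c))

  ds <- make_aligned(temp$timestamp, rs = 1, tair_c = temp$tair_c)
  for (q in c(0.5, 0.85)) {
    thr <- fit_climatology(temp, q = q, allow_short = TRUE)
    frac <- heatwave_fraction(classify_heat(ds, thr))
    expect_lt(abs(frac - (1 - q)), 0.03)
  }

  # ordering invariance of classification
  thr <- fit_climatology(temp, allow_short = TRUE)
  perm <- sample(nrow(ds))
  ds_p <- make_aligned(ds$timestamp[perm], rs = 1, tair_c = ds$tair_c[perm])
  hl <- classify_heat(ds, thr)
  hl_p <- classify_heat(ds_p, thr)
  expect_equal(dplyr::arrange(tibble::as_tibble(hl_p), timestamp),
               dplyr::arrange(tibble::as_tibble(hl), timestamp))
})

test_that("climatology tables round-trip through CSV", {
  temp <- generate_temperature(synth_config(seed = 7), years = 3)
  thr <- fit_climatology(temp, allow_short = TRUE)
  path <- tempfile(fileext = ".csv")
  write_climatology(thr, path)
  rt <- read_climatology(path)
  expect_equal(rt$threshold_c, thr$threshold_c)
  expect_equal(rt$month, thr$month)
  expect_equal(rt$hour, thr$hour)
  expect_equal(rt$n, thr$n)
  expect_equal(attr(rt, "q"), 0.85)
})
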