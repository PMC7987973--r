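# In-code fixture builders: small typed series constructed directly, plus
# CSV writers exercising the reader dialects. All stochastic tests set seeds
# explicitly.

hours_utc <- function(n, start = "2016-02-01 00:00:00") {
  as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1)
}

tbl_class <- function(df, cls) {
  structure(tibble::as_tibble(df), class = c(cls, class(tibble::tibble())))
}

make_flux <- function(timestamp, rs, sm = NULL) {
  df <- tibble::tibble(timestamp = timestamp, rs = rs)
  if (!is.null(sm)) df$sm <- sm
  tbl_class(df, "flux_series")
}

make_temp <- function(timestamp, tair_c) {
  tbl_class(tibble::tibble(timestamp = timestamp, tair_c = tair_c), "temperature_series")
}

make_moist <- function(timestamp, sm) {
  tbl_class(tibble::tibble(timestamp = timestamp, sm = sm), "moisture_series")
}

make_aligned <- function(timestamp, rs, tair_c = 20, sm = NA_real_, site = "test") {
  df <- tibble::tibble(timestamp = timestamp, rs = rs,
                       tair_c = rep_len(tair_c, length(timestamp)),
                       sm = rep_len(sm, length(timestamp)))
  structure(df, site = site, class = c("aligned_dataset", class(tibble::tibble())))
}

make_heat_labels <- function(timestamp, heat) {
  structure(tibble::tibble(timestamp = timestamp, heat = heat),
            n_excluded = 0L, q = 0.85,
            class = c("heat_labels", class(tibble::tibble())))
}

make_moist_labels <- function(timestamp, moisture) {
  structure(tibble::tibble(timestamp = timestamp, moisture = moisture),
            class = c("moisture_labels", class(tibble::tibble())))
}

write_fixture_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".csv")
  readr::write_csv(df, path, na = "")
  path
}

# Independent order-statistic quantile oracle: sort + linear interpolation at
# zero-based position (n-1)*q. Kept separate from the package's estimator.
oracle_quantile <- function(x, q) {
  s <- sort(x)
  pos <- (length(s) - 1) * q
  lo <- floor(pos) + 1
  hi <- ceiling(pos) + 1
  s[lo] + (pos - floor(pos)) * (s[hi] - s[lo])
}

# A small fully-labelled synthetic site for identity/property tests:
# 5-yr climatology record, 2-yr study period (fast; allow_short = TRUE).
small_site_pipeline <- function(seed = 11, ...) {
  cfg <- synth_config(seed = seed, clim_years = 5, study_years = 2, ...)
  site <- generate_site(cfg)
  run_site_pipeline(site$flux, site$temp_study, site$temp_station, sm = site$sm,
                    site = paste0("synth", seed), allow_short = TRUE)
}
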