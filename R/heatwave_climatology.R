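#' Fit an hour-of-month percentile climatology from a long-term record
#'
#' For each (month, hour-of-day) cell, all hourly temperatures across the
#' years of the record are pooled and the `q`-quantile is taken with the
#' linear-interpolation order-statistic estimator (position `(n-1)q`,
#' zero-based; `stats::quantile` type 7). Each month therefore contributes
#' up to 24 threshold values and the full table has at most 288 cells.
#' Cells with fewer than `min_n` observations are left unpopulated and
#' reported. Feb 29 hours are pooled into February's cells.
#'
#' An hour whose temperature strictly exceeds its cell threshold is later
#' classified as a heatwave hour (see [classify_heat()]); with `q = 0.85`
#' about 15% of a stationary record exceeds its own climatology.
#'
#' @param temp A `temperature_series` spanning at least `min_years`
#'   calendar years.
#' @param q Percentile level as a fraction (default 0.85).
#' @param min_years Minimum number of distinct calendar years required
#'   (default 30). Override with `allow_short = TRUE` for testing.
#' @param min_n Minimum per-cell sample size for a cell to be populated
#'   (default 30, one observation per required year).
#' @param allow_short If `TRUE`, skip the record-length check.
#' @return A `climatology_thresholds` tibble with columns `month`, `hour`,
#'   `threshold_c`, `n`; attributes `q`, `years`, `min_n` and
#'   `unpopulated` (cells failing the minimum-sample rule).
#' @export
fit_climatology <- function(temp, q = 0.85, min_years = 30, min_n = 30,
                            allow_short = FALSE) {
  stopifnot(inherits(temp, "temperature_series"), q > 0, q < 1)
  lt <- as.POSIXlt(temp$timestamp)
  years <- length(unique(lt$year))
  if (!allow_short && years < min_years) {
    .stopf("temperature record spans %d year(s); %d required", years, min_years)
  }

  cells <- tibble::tibble(
    month = lt$mon + 1L,   # Feb 29 falls in month 2 automatically
    hour = lt$hour,
    tair_c = temp$tair_c
  )
  tab <- dplyr::summarise(
    dplyr::group_by(cells, .data$month, .data$hour),
    threshold_c = .quantile7(.data$tair_c, q),
    n = dplyr::n(),
    .groups = "drop"
  )
  unpop <- tab[tab$n < min_n, c("month", "hour", "n")]
  tab <- tab[tab$n >= min_n, ]
  if (nrow(tab) == 0L) .stopf("no (month, hour) cell reaches the minimum sample size %d", min_n)
  structure(dplyr::arrange(tab, .data$month, .data$hour),
            q = q, years = years, min_n = min_n, unpopulated = unpop,
            class = c("climatology_thresholds", class(tibble::tibble())))
}

#' Label each analysis hour as heatwave or non-heatwave
#'
#' An hour is a heatwave hour (`HW`) iff its air temperature strictly
#' exceeds the climatological threshold of its (month, hour-of-day) cell;
#' a temperature exactly at the threshold is `NHW`. Hours whose cell is
#' unpopulated are excluded (never defaulted) and their count is reported.
#' Classification is per-hour exceedance; `min_run` optionally requires a
#' minimum number of consecutive exceeding hours for sensitivity analyses
#' (default 1, i.e. no duration criterion).
#'
#' @param ds An `aligned_dataset`.
#' @param thr A `climatology_thresholds` table.
#' @param min_run Minimum consecutive exceeding hours for a run to count as
#'   heatwave (default 1).
#' @return A `heat_labels` tibble with columns `timestamp`, `heat`
#'   (`"HW"`/`"NHW"`) and attribute `n_excluded`.
#' @export
classify_heat <- function(ds, thr, min_run = 1L) {
  stopifnot(inherits(ds, "aligned_dataset"), inherits(thr, "climatology_thresholds"))
  lt <- as.POSIXlt(ds$timestamp)
  keyed <- tibble::tibble(timestamp = ds$timestamp, tair_c = ds$tair_c,
                          month = lt$mon + 1L, hour = lt$hour)
  joined <- dplyr::left_join(keyed, tibble::as_tibble(thr), by = c("month", "hour"))
  n_excluded <- sum(is.na(joined$threshold_c))
  joined <- joined[!is.na(joined$threshold_c), ]
  if (nrow(joined) == 0L) .warnf("no hours could be classified: all threshold cells unpopulated")

  hot <- joined$tair_c > joined$threshold_c
  if (min_run > 1L && length(hot)) {
    r <- rle(hot)
    r$values <- r$values & r$lengths >= min_run
    hot <- inverse.rle(r)
  }
  out <- tibble::tibble(timestamp = joined$timestamp,
                        heat = ifelse(hot, "HW", "NHW"))
  structure(out, n_excluded = n_excluded, q = attr(thr, "q"),
            class = c("heat_labels", class(tibble::tibble())))
}

#' Fraction of labelled hours classified as heatwave
#'
#' The duty fraction of heatwave hours, used for annualizing excess flux in
#' the multi-site synthesis.
#'
#' @param labels A `heat_labels` table.
#' @return Fraction of labelled hours that are `HW`, in \[0, 1\].
#' @export
heatwave_fraction <- function(labels) {
  stopifnot(inherits(labels, "heat_labels"))
  if (nrow(labels) == 0L) .stopf("no labelled hours")
  mean(labels$heat == "HW")
}

#' Write / read a climatology threshold table as CSV
#'
#' CSV columns: `month`, `hour`, `threshold_c`, `n`; the percentile level is
#' carried in a `q` column so the table round-trips.
#'
#' @param thr A `climatology_thresholds` table.
#' @param path Output CSV path.
#' @return `write_climatology()` returns `path` invisibly;
#'   `read_climatology()` returns a `climatology_thresholds` table.
#' @export
write_climatology <- function(thr, path) {
  stopifnot(inherits(thr, "climatology_thresholds"))
  df <- tibble::as_tibble(thr)
  df$q <- attr(thr, "q")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_climatology
#' @export
read_climatology <- function(path) {
  df <- readr::read_csv(path, col_types = "iidid", progress = FALSE, show_col_types = FALSE)
  q <- unique(df$q)
  stopifnot(length(q) == 1L)
  structure(df[, c("month", "hour", "threshold_c", "n")],
            q = q, years = NA_integer_, min_n = NA_integer_,
            unpopulated = df[0, c("month", "hour", "n")],
            class = c("climatology_thresholds", class(tibble::tibble())))
}
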