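#' Read a continuous soil CO2 flux record from CSV
#'
#' Reads a COSORE-style flux export: one row per observation with an
#' ISO-8601 timestamp and a flux in umol CO2 m-2 s-1, optionally with a
#' co-located volumetric soil-moisture column. Rows whose timestamp or flux
#' cannot be parsed are dropped and counted in the attached ingest report.
#' Timestamps are interpreted as local standard time with a fixed UTC
#' offset, so no daylight-saving adjustment is ever applied.
#'
#' @param path Path to a CSV file.
#' @param col_map Named list mapping roles to column names. Roles:
#'   `timestamp`, `flux`, and optionally `sm`. Defaults follow the package
#'   CSV dialect (`timestamp`, `flux_umol_m2_s`, `sm_m3_m3`).
#' @param tz Timezone used to interpret timestamps. Keep the default `"UTC"`
#'   for fixed-offset local standard time.
#' @return A `flux_series` tibble with columns `timestamp`, `rs` and, when
#'   present in the file, `sm`. The ingest report (rows read / kept /
#'   dropped) is attached as attribute `"report"`.
#' @export
read_flux_csv <- function(path,
                          col_map = list(timestamp = "timestamp",
                                         flux = "flux_umol_m2_s",
                                         sm = "sm_m3_m3"),
                          tz = "UTC") {
  raw <- .read_raw_csv(path)
  .require_cols(raw, col_map, c("timestamp", "flux"), path)

  ts <- .parse_timestamp(raw[[col_map$timestamp]], tz)
  rs <- suppressWarnings(as.numeric(raw[[col_map$flux]]))
  keep <- !is.na(ts) & is.finite(rs)

  has_sm <- !is.null(col_map$sm) && col_map$sm %in% names(raw)
  sm <- if (has_sm) suppressWarnings(as.numeric(raw[[col_map$sm]])) else NULL

  out <- tibble::tibble(timestamp = ts[keep], rs = rs[keep])
  if (has_sm) out$sm <- sm[keep]
  if (nrow(out) == 0L) .stopf("no parseable rows in '%s'", path)

  dup <- duplicated(out$timestamp)
  if (any(dup)) {
    .stopf("duplicate timestamp in '%s': first duplicate at %s",
           path, format(out$timestamp[which(dup)[1L]], "%Y-%m-%d %H:%M:%S"))
  }
  out <- out[order(out$timestamp), ]

  neg_frac <- mean(out$rs < 0)
  if (neg_frac >= 0.05) {
    .warnf("%.1f%% of flux values are negative (instrument noise should be < 5%%)",
           100 * neg_frac)
  }
  .new_series(out, "flux_series", report = .ingest_report(nrow(raw), nrow(out)))
}

#' Read an hourly air-temperature record from CSV
#'
#' Reads a NOAA-hourly-style station export: timestamp plus air temperature
#' in degrees Celsius. A configurable missing-value sentinel (for example
#' `999.9`) is treated as missing and dropped. Temperatures outside
#' \[-60, 60\] degC are rejected as implausible. If several records imply the
#' same clock hour the first is kept and a warning is raised.
#'
#' @inheritParams read_flux_csv
#' @param col_map Named list with roles `timestamp` and `temp`
#'   (defaults `timestamp`, `tair_c`).
#' @param sentinel Optional numeric missing-value sentinel; matching values
#'   are treated as missing.
#' @return A `temperature_series` tibble with columns `timestamp`, `tair_c`
#'   and an attached ingest report.
#' @export
read_hourly_temperature_csv <- function(path,
                                        col_map = list(timestamp = "timestamp",
                                                       temp = "tair_c"),
                                        sentinel = NULL,
                                        tz = "UTC") {
  raw <- .read_raw_csv(path)
  .require_cols(raw, col_map, c("timestamp", "temp"), path)

  ts <- .parse_timestamp(raw[[col_map$timestamp]], tz)
  tc <- suppressWarnings(as.numeric(raw[[col_map$temp]]))
  if (!is.null(sentinel)) tc[!is.na(tc) & tc == sentinel] <- NA_real_
  keep <- !is.na(ts) & is.finite(tc) & tc >= -60 & tc <= 60

  out <- tibble::tibble(timestamp = .floor_hour(ts[keep]), tair_c = tc[keep])
  if (nrow(out) == 0L) .stopf("no parseable rows in '%s'", path)
  out <- out[order(out$timestamp), ]

  dup <- duplicated(out$timestamp)
  if (any(dup)) {
    .warnf("%d record(s) implied an already-present hour; keeping the first of each",
           sum(dup))
    out <- out[!dup, ]
  }
  .new_series(out, "temperature_series", report = .ingest_report(nrow(raw), nrow(out)))
}

#' Build a moisture series from the soil-moisture column of a flux series
#'
#' Convenience accessor for flux files that carry a co-located volumetric
#' water-content column. Values outside \[0, 1\] m3/m3 are dropped.
#'
#' @param flux A `flux_series` with an `sm` column (see [read_flux_csv()]).
#' @return A `moisture_series` tibble with columns `timestamp`, `sm`.
#' @export
moisture_from_flux <- function(flux) {
  stopifnot(inherits(flux, "flux_series"))
  if (!"sm" %in% names(flux)) .stopf("flux series carries no soil-moisture column")
  out <- tibble::tibble(timestamp = flux$timestamp, sm = flux$sm)
  out <- out[!is.na(out$sm) & out$sm >= 0 & out$sm <= 1, ]
  .new_series(out, "moisture_series")
}

#' Average a sub-hourly flux series to hourly means
#'
#' Each output record is the arithmetic mean of all observations whose
#' timestamp falls in the hour-beginning half-open interval
#' \[H:00, H+1:00). Hours with no observations are absent from the output
#' (gaps propagate; nothing is imputed). The per-hour contributing count is
#' retained in column `n_obs`. The operation is idempotent on input that is
#' already hourly.
#'
#' @param flux A `flux_series`.
#' @return An hourly `flux_series` with columns `timestamp`, `rs`, `n_obs`
#'   and, if present on input, the hourly mean `sm`.
#' @export
resample_to_hourly <- function(flux) {
  stopifnot(inherits(flux, "flux_series"))
  if (nrow(flux) == 0L) {
    out <- tibble::tibble(timestamp = flux$timestamp, rs = numeric(0), n_obs = integer(0))
    return(.new_series(out, "flux_series"))
  }
  grouped <- dplyr::group_by(
    tibble::as_tibble(flux),
    timestamp = .floor_hour(.data$timestamp)
  )
  out <- dplyr::summarise(
    grouped,
    dplyr::across(dplyr::any_of(c("rs", "sm")), ~ mean(.x, na.rm = TRUE)),
    n_obs = dplyr::n(),
    .groups = "drop"
  )
  out$rs[is.nan(out$rs)] <- NA_real_
  if ("sm" %in% names(out)) out$sm[is.nan(out$sm)] <- NA_real_
  out <- dplyr::arrange(out, .data$timestamp)
  out <- dplyr::relocate(out, "timestamp", "rs")
  .new_series(out, "flux_series")
}

#' Align hourly flux, temperature and moisture into one analysis table
#'
#' Performs a strict inner join of the hourly flux and temperature series on
#' the clock hour -- every retained record has both a flux and a temperature
#' value; hours present in only one series are dropped. Soil moisture, when
#' supplied (or carried on the flux series), is attached by a left join and
#' left missing (`NA`, later labelled `unknown`) where unavailable.
#'
#' @param flux An hourly `flux_series` (see [resample_to_hourly()]).
#' @param temp A `temperature_series`.
#' @param sm Optional `moisture_series`. If `NULL` and `flux` carries an
#'   `sm` column, that column is used.
#' @param site Site identifier stored on the result.
#' @return An `aligned_dataset` tibble with columns `timestamp`, `rs`,
#'   `tair_c`, `sm` and attribute `site`.
#' @export
align_series <- function(flux, temp, sm = NULL, site = "site") {
  stopifnot(inherits(flux, "flux_series"), inherits(temp, "temperature_series"))
  ts <- flux$timestamp
  if (any(as.numeric(ts) %% 3600 != 0)) {
    .stopf("flux series is not hourly; call resample_to_hourly() first")
  }

  f <- tibble::tibble(timestamp = ts, rs = flux$rs)
  if (is.null(sm) && "sm" %in% names(flux)) {
    sm <- tibble::tibble(timestamp = ts, sm = flux$sm)
  }
  t <- tibble::tibble(timestamp = temp$timestamp, tair_c = temp$tair_c)

  out <- dplyr::inner_join(f, t, by = "timestamp")
  out <- out[!is.na(out$rs) & !is.na(out$tair_c), ]
  if (nrow(out) == 0L) .stopf("no overlapping hours between flux and temperature")

  if (!is.null(sm)) {
    s <- tibble::tibble(timestamp = .floor_hour(sm$timestamp), sm = sm$sm)
    s <- s[!duplicated(s$timestamp), ]
    out <- dplyr::left_join(out, s, by = "timestamp")
  } else {
    out$sm <- NA_real_
  }
  out <- dplyr::arrange(out, .data$timestamp)
  structure(out, site = site, class = c("aligned_dataset", class(tibble::tibble())))
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset> site '%s': %d hourly records, %d with soil moisture\n",
              attr(x, "site"), nrow(x), sum(!is.na(x$sm))))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# --- internals ---------------------------------------------------------------

.read_raw_csv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  if (nrow(raw) == 0L) .stopf("no parseable rows in '%s'", path)
  raw
}

.require_cols <- function(raw, col_map, roles, path) {
  wanted <- unlist(col_map[roles], use.names = FALSE)
  missing <- setdiff(wanted, names(raw))
  if (length(missing)) {
    .stopf("column(s) %s not found in '%s'", paste0("'", missing, "'", collapse = ", "), path)
  }
}

.parse_timestamp <- function(x, tz) {
  # readr's ISO-8601 parser: yields NA (not an error) on unparseable cells,
  # which is what per-row drop counting needs.
  suppressWarnings(readr::parse_datetime(x, locale = readr::locale(tz = tz)))
}

.floor_hour <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 3600) * 3600,
             origin = "1970-01-01", tz = attr(ts, "tzone") %||% "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ingest_report <- function(read, kept) {
  list(rows_read = read, rows_kept = kept, rows_dropped = read - kept)
}

.new_series <- function(df, cls, report = NULL) {
  structure(df, report = report, class = c(cls, class(tibble::tibble())))
}
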