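#' Hour-of-day (diel) cycle of Rs under heat conditions
#'
#' Groups matched hours by local clock hour (0-23) and heat state, and
#' summarises each cell with the mean, median, 25th/75th percentiles and
#' sample size. Cells with no observations are retained with `n = 0` and
#' `NA` statistics so incomplete cycles are visible rather than silently
#' contiguous.
#'
#' @param ds An `aligned_dataset`.
#' @param heat_labels A `heat_labels` table.
#' @return A `diel_cycle` tibble with columns `hour`, `condition`, `mean`,
#'   `median`, `q25`, `q75`, `n` (48 rows: 24 hours x 2 conditions).
#' @export
compute_diel <- function(ds, heat_labels) {
  stopifnot(inherits(ds, "aligned_dataset"), inherits(heat_labels, "heat_labels"))
  d <- dplyr::inner_join(
    tibble::tibble(timestamp = ds$timestamp, rs = ds$rs),
    tibble::as_tibble(heat_labels), by = "timestamp"
  )
  d$hour <- as.POSIXlt(d$timestamp)$hour
  cyc <- dplyr::summarise(
    dplyr::group_by(d, .data$hour, condition = .data$heat),
    mean = mean(.data$rs),
    median = stats::median(.data$rs),
    q25 = .quantile7(.data$rs, 0.25),
    q75 = .quantile7(.data$rs, 0.75),
    n = dplyr::n(),
    .groups = "drop"
  )
  cyc <- tidyr::complete(cyc, hour = 0:23, condition = c("HW", "NHW"),
                         fill = list(n = 0L))
  cyc <- dplyr::arrange(cyc, .data$condition, .data$hour)
  structure(cyc, class = c("diel_cycle", class(tibble::tibble())))
}

#' Peak window of a diel mean cycle
#'
#' Formalizes "the hours with the highest rates" as the shortest contiguous
#' hour-of-day window containing every hour whose mean Rs is within 5% of
#' the cycle maximum (i.e. mean >= 0.95 x max). For a flat cycle every hour
#' qualifies and the full-day window (0, 23) is returned. The 5% rule is an
#' operational definition for reporting, not a statistical test.
#'
#' @param cycle A `diel_cycle`.
#' @param condition `"HW"` or `"NHW"`.
#' @param tol Fractional closeness to the maximum (default 0.05).
#' @return Integer vector `c(start_hour, end_hour)`.
#' @export
diel_peak_window <- function(cycle, condition, tol = 0.05) {
  stopifnot(inherits(cycle, "diel_cycle"))
  condition <- match.arg(condition, c("HW", "NHW"))
  cc <- cycle[cycle$condition == condition, ]
  if (nrow(cc) < 24L || any(cc$n == 0L)) {
    .stopf("incomplete diel cycle for condition '%s'", condition)
  }
  cc <- cc[order(cc$hour), ]
  peak <- max(cc$mean)
  qualifying <- cc$hour[cc$mean >= (1 - tol) * peak]
  c(start = min(qualifying), end = max(qualifying))
}

#' Plot a diel mean cycle
#'
#' Mean Rs per hour of day for heatwave and non-heatwave hours, with the
#' interquartile band. Requires ggplot2.
#'
#' @param cycle A `diel_cycle`.
#' @return A ggplot object.
#' @export
plot_diel_cycle <- function(cycle) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    .stopf("plot_diel_cycle() requires the ggplot2 package")
  }
  ggplot2::ggplot(tibble::as_tibble(cycle),
                  ggplot2::aes(x = .data$hour, y = .data$mean,
                               colour = .data$condition, fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Local hour of day",
                  y = expression(R[s] ~ (mu * mol ~ CO[2] ~ m^-2 ~ s^-1)),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
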