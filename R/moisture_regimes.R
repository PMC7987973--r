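#' Fit site-specific dry/wet soil-moisture thresholds
#'
#' Soil-moisture regimes are defined by quantiles of the site record:
#' hours below the 30th quantile are dry, hours above the 70th are wet, and
#' the band in between is neutral. Quantiles use the same
#' linear-interpolation estimator as the temperature climatology, so the
#' two regime definitions are numerically consistent.
#'
#' @param sm A `moisture_series`, or a numeric vector of volumetric water
#'   content (m3/m3).
#' @param q_dry,q_wet Quantile levels for the dry and wet thresholds
#'   (defaults 0.30 and 0.70; must satisfy `0 < q_dry < q_wet < 1`).
#' @param min_n Minimum number of non-missing values (default 50, mirroring
#'   the minimum-sample rule of the density analyses).
#' @return A `moisture_thresholds` object: list with `dry`, `wet` (m3/m3),
#'   `n`, `q_dry`, `q_wet`.
#' @export
fit_sm_thresholds <- function(sm, q_dry = 0.30, q_wet = 0.70, min_n = 50) {
  stopifnot(q_dry > 0, q_wet < 1, q_dry < q_wet)
  x <- if (is.data.frame(sm)) sm$sm else sm
  x <- x[!is.na(x)]
  if (length(x) < min_n) {
    .stopf("only %d non-missing soil-moisture values; %d required", length(x), min_n)
  }
  structure(
    list(dry = .quantile7(x, q_dry), wet = .quantile7(x, q_wet),
         n = length(x), q_dry = q_dry, q_wet = q_wet),
    class = "moisture_thresholds"
  )
}

#' @export
print.moisture_thresholds <- function(x, ...) {
  cat(sprintf("<moisture_thresholds> dry < %.4f, wet > %.4f m3/m3 (q = %.2f/%.2f, n = %d)\n",
              x$dry, x$wet, x$q_dry, x$q_wet, x$n))
  invisible(x)
}

#' Label each hour's soil-moisture regime
#'
#' Strict inequalities at both thresholds: `sm < dry` is dry, `sm > wet` is
#' wet, anything in the closed band (including values exactly at a
#' threshold) is neutral, and hours without a moisture observation are
#' `unknown`. Neutral hours are excluded from the dry/wet conditional
#' analyses rather than merged into either regime.
#'
#' @param ds An `aligned_dataset`.
#' @param thr A `moisture_thresholds` object.
#' @return A `moisture_labels` tibble with columns `timestamp`, `moisture`
#'   in `{"dry", "wet", "neutral", "unknown"}`.
#' @export
classify_moisture <- function(ds, thr) {
  stopifnot(inherits(ds, "aligned_dataset"), inherits(thr, "moisture_thresholds"))
  lab <- dplyr::case_when(
    is.na(ds$sm) ~ "unknown",
    ds$sm < thr$dry ~ "dry",
    ds$sm > thr$wet ~ "wet",
    TRUE ~ "neutral"
  )
  structure(tibble::tibble(timestamp = ds$timestamp, moisture = lab),
            class = c("moisture_labels", class(tibble::tibble())))
}
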