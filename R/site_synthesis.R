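#' Assemble one site's condition results into a site record
#'
#' Collects the per-condition exceedance probabilities for one site,
#' keeping only conditions that passed the minimum-sample rule, together
#' with the site-mean Rs, the heatwave hour fraction and (optionally) the
#' mean Rs within heatwave and non-heatwave hours used for annualizing
#' excess flux.
#'
#' @param results A list of `exceedance_result` rows (or a tibble binding
#'   them), covering at least the `HW` and `NHW` conditions.
#' @param heat_fraction Fraction of labelled hours that are heatwave hours
#'   (see [heatwave_fraction()]).
#' @param mean_rs Site-mean Rs (umol CO2 m-2 s-1).
#' @param site Site identifier.
#' @param rs_mean_hw,rs_mean_nhw Optional mean Rs within HW / NHW hours.
#' @return A `site_result`: list with `site`, `pex` (named vector over
#'   populated conditions), `excluded` (conditions flagged insufficient),
#'   `mean_rs`, `heat_fraction`, `rs_mean_hw`, `rs_mean_nhw`.
#' @export
summarize_site <- function(results, heat_fraction, mean_rs, site = "site",
                           rs_mean_hw = NA_real_, rs_mean_nhw = NA_real_) {
  tab <- if (is.data.frame(results)) tibble::as_tibble(results) else dplyr::bind_rows(results)
  stopifnot(all(c("condition", "pex_empirical", "insufficient") %in% names(tab)))
  tab <- tab[tab$condition %in% .CONDITIONS, ]

  ok <- tab[!tab$insufficient, ]
  if (!all(c("HW", "NHW") %in% ok$condition)) {
    .stopf("site '%s': both HW and NHW must pass the minimum-sample rule", site)
  }
  pex <- setNames(ok$pex_empirical, ok$condition)
  pex <- pex[intersect(.CONDITIONS, names(pex))]
  excluded <- setdiff(tab$condition[tab$insufficient], names(pex))

  structure(list(site = site, pex = pex, excluded = excluded,
                 mean_rs = mean_rs, heat_fraction = heat_fraction,
                 rs_mean_hw = rs_mean_hw, rs_mean_nhw = rs_mean_nhw),
            class = "site_result")
}

#' @export
print.site_result <- function(x, ...) {
  cat(sprintf("<site_result> '%s': mean Rs = %.3f, HW fraction = %.3f\n",
              x$site, x$mean_rs, x$heat_fraction))
  cat("  P_ex:", paste(sprintf("%s = %.1f%%", names(x$pex), 100 * x$pex), collapse = ", "), "\n")
  if (length(x$excluded)) cat("  excluded (insufficient n):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-site synthesis of exceedance probabilities
#'
#' Unweighted arithmetic means of the per-condition exceedance
#' probabilities over the sites where each condition is populated, the
#' relative change of the heatwave mean versus the non-heatwave mean
#' (reported as a percentage rounded to the nearest whole percent), both
#' conventions of the wet-versus-dry contrast (ratio of cross-site means
#' and mean of per-site ratios), and the cross-site mean annualized excess
#' flux where the per-site Rs means are available.
#'
#' @param sites A list of `site_result` objects (at least one).
#' @return A `multi_site_summary`: list with `mean_pex` (tibble: condition,
#'   mean_pex, n_sites), `relative_change_pct`, `wet_dry_ratio_of_means`,
#'   `wet_dry_mean_of_ratios`, `excess_flux_g_co2_m2_yr`, `n_sites`.
#' @export
aggregate_sites <- function(sites) {
  if (inherits(sites, "site_result")) sites <- list(sites)
  stopifnot(length(sites) >= 1L, all(vapply(sites, inherits, logical(1), "site_result")))

  per_cond <- lapply(.CONDITIONS, function(cond) {
    vals <- unlist(lapply(sites, function(s) unname(s$pex[cond])))
    vals <- vals[!is.na(vals)]
    tibble::tibble(condition = cond,
                   mean_pex = if (length(vals)) mean(vals) else NA_real_,
                   n_sites = length(vals))
  })
  mean_pex <- dplyr::bind_rows(per_cond)
  m <- setNames(mean_pex$mean_pex, mean_pex$condition)

  rel_change <- round(100 * (m[["HW"]] - m[["NHW"]]) / m[["NHW"]])

  # Wet-vs-dry contrast: the pooling convention is not unique, so report both.
  ratio_of_means <- if (all(is.finite(m[c("wHW", "wNHW", "dHW", "dNHW")]))) {
    mean(m[c("wHW", "wNHW")]) / mean(m[c("dHW", "dNHW")])
  } else NA_real_
  site_ratios <- vapply(sites, function(s) {
    p <- s$pex
    if (all(c("wHW", "wNHW", "dHW", "dNHW") %in% names(p))) {
      mean(p[c("wHW", "wNHW")]) / mean(p[c("dHW", "dNHW")])
    } else NA_real_
  }, numeric(1))
  mean_of_ratios <- if (any(is.finite(site_ratios))) mean(site_ratios, na.rm = TRUE) else NA_real_

  excess <- vapply(sites, function(s) {
    if (is.finite(s$rs_mean_hw) && is.finite(s$rs_mean_nhw)) {
      annualized_excess_flux(s$rs_mean_hw, s$rs_mean_nhw, s$heat_fraction)
    } else NA_real_
  }, numeric(1))
  excess_mean <- if (any(is.finite(excess))) mean(excess, na.rm = TRUE) else NA_real_

  structure(list(mean_pex = mean_pex,
                 relative_change_pct = unname(rel_change),
                 wet_dry_ratio_of_means = unname(ratio_of_means),
                 wet_dry_mean_of_ratios = mean_of_ratios,
                 excess_flux_g_co2_m2_yr = excess_mean,
                 n_sites = length(sites)),
            class = "multi_site_summary")
}

#' @export
print.multi_site_summary <- function(x, ...) {
  cat(sprintf("<multi_site_summary> %d site(s)\n", x$n_sites))
  tab <- x$mean_pex[!is.na(x$mean_pex$mean_pex), ]
  cat("  cross-site mean P_ex:",
      paste(sprintf("%s = %.1f%% (%d sites)", tab$condition, 100 * tab$mean_pex, tab$n_sites),
            collapse = ", "), "\n")
  cat(sprintf("  HW vs NHW relative change: %d%%\n", x$relative_change_pct))
  if (is.finite(x$wet_dry_ratio_of_means)) {
    cat(sprintf("  wet/dry contrast: %.2f (ratio of means), %.2f (mean of ratios)\n",
                x$wet_dry_ratio_of_means, x$wet_dry_mean_of_ratios))
  }
  if (is.finite(x$excess_flux_g_co2_m2_yr)) {
    cat(sprintf("  annualized excess flux: %.1f g CO2 m-2 yr-1\n", x$excess_flux_g_co2_m2_yr))
  }
  invisible(x)
}

#' Annualized excess soil-CO2 flux attributable to heatwave hours
#'
#' Converts the mean Rs difference between heatwave and non-heatwave hours
#' into an annual mass flux, assuming the difference applies over the
#' heatwave duty fraction of a Julian year:
#'
#' `excess = (Rs_HW - Rs_NHW) [umol m-2 s-1] x heat_fraction
#'           x 31,557,600 s yr-1 x 44.01e-6 g umol-1`
#'
#' The formula is an explicit package convention (a duty-cycle
#' annualization) and is printed in every report that uses it.
#'
#' @param rs_hw,rs_nhw Mean Rs within heatwave / non-heatwave hours
#'   (umol CO2 m-2 s-1).
#' @param heat_fraction Heatwave duty fraction in \[0, 1\].
#' @return Excess flux in g CO2 m-2 yr-1 (negative iff `rs_hw < rs_nhw`).
#' @export
annualized_excess_flux <- function(rs_hw, rs_nhw, heat_fraction) {
  stopifnot(is.finite(rs_hw), is.finite(rs_nhw),
            heat_fraction >= 0, heat_fraction <= 1)
  (rs_hw - rs_nhw) * heat_fraction * .JULIAN_YEAR_S * .CO2_G_PER_UMOL
}
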