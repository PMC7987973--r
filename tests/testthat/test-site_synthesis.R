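ex_row <- function(condition, pex, n = 100, insufficient = FALSE) {
  tibble::tibble(condition = condition, n = n, r_star = 1.1,
                 pex_empirical = ifelse(insufficient, NA_real_, pex),
                 pex_kde = NA_real_, insufficient = insufficient)
}

test_that("summarize_site assembles populated conditions and flags exclusions", {
  full <- dplyr::bind_rows(
    ex_row("HW", 0.54), ex_row("NHW", 0.43), ex_row("dHW", 0.54),
    ex_row("dNHW", 0.45), ex_row("wHW", 0.36), ex_row("wNHW", 0.21)
  )
  s <- summarize_site(full, heat_fraction = 0.15, mean_rs = 1.1, site = "a")
  expect_length(s$pex, 6L)
  expect_equal(unname(s$pex["HW"]), 0.54)

  # dry conditions below minimum n are excluded from the record
  part <- dplyr::bind_rows(
    ex_row("HW", 0.5), ex_row("NHW", 0.4),
    ex_row("dHW", NA, n = 20, insufficient = TRUE),
    ex_row("dNHW", NA, n = 30, insufficient = TRUE),
    ex_row("wHW", 0.6), ex_row("wNHW", 0.5)
  )
  s2 <- summarize_site(part, 0.15, 1.0, site = "b")
  expect_setequal(s2$excluded, c("dHW", "dNHW"))
  expect_false("dHW" %in% names(s2$pex))

  # no soil moisture at all: only the heat conditions are populated
  hw_only <- dplyr::bind_rows(ex_row("HW", 0.5), ex_row("NHW", 0.4))
  s3 <- summarize_site(hw_only, 0.15, 1.0, site = "c")
  expect_equal(names(s3$pex), c("HW", "NHW"))

  broken <- dplyr::bind_rows(ex_row("HW", 0.5), ex_row("NHW", NA, insufficient = TRUE))
  expect_error(summarize_site(broken, 0.15, 1.0), "HW and NHW")
})

test_that("aggregate_sites reproduces the worked relative-change example", {
  mk <- function(hw, nhw, site) {
    summarize_site(dplyr::bind_rows(ex_row("HW", hw), ex_row("NHW", nhw)),
                   heat_fraction = 0.15, mean_rs = 1, site = site)
  }
  # cross-site means of 43% (NHW) and 54% (HW): relative change rounds to 26%
  sites <- list(mk(0.50, 0.40, "s1"), mk(0.58, 0.46, "s2"))
  agg <- aggregate_sites(sites)
  m <- setNames(agg$mean_pex$mean_pex, agg$mean_pex$condition)
  expect_equal(unname(m["HW"]), 0.54)
  expect_equal(unname(m["NHW"]), 0.43)
  expect_equal(agg$relative_change_pct, 26)

  expect_equal(aggregate_sites(list(mk(0.5, 0.5, "e")))$relative_change_pct, 0)

  single <- aggregate_sites(list(mk(0.47, 0.35, "sjmr")))
  m1 <- setNames(single$mean_pex$mean_pex, single$mean_pex$condition)
  expect_equal(unname(m1["HW"]), 0.47)
  expect_equal(unname(m1["NHW"]), 0.35)
})

test_that("aggregation invariants: copies, bounds, condition-wise site counts", {
  full <- function(site, shift = 0) {
    summarize_site(dplyr::bind_rows(
      ex_row("HW", 0.54 + shift), ex_row("NHW", 0.43 + shift), ex_row("dHW", 0.54),
      ex_row("dNHW", 0.45), ex_row("wHW", 0.36), ex_row("wNHW", 0.21)
    ), heat_fraction = 0.15, mean_rs = 1.1, site = site,
    rs_mean_hw = 1.3, rs_mean_nhw = 1.05)
  }
  one <- aggregate_sites(list(full("x")))
  five <- aggregate_sites(replicate(5, full("x"), simplify = FALSE))
  expect_equal(five$mean_pex$mean_pex, one$mean_pex$mean_pex)
  expect_equal(five$relative_change_pct, one$relative_change_pct)
  expect_equal(five$excess_flux_g_co2_m2_yr, one$excess_flux_g_co2_m2_yr)

  two <- aggregate_sites(list(full("a"), full("b", shift = 0.04)))
  m <- setNames(two$mean_pex$mean_pex, two$mean_pex$condition)
  expect_gte(m[["HW"]], 0.54)
  expect_lte(m[["HW"]], 0.58)
  expect_true(all(two$mean_pex$n_sites[two$mean_pex$condition %in% c("HW", "NHW")] == 2))

  # both wet/dry contrast conventions are reported and positive
  expect_gt(two$wet_dry_ratio_of_means, 0)
  expect_gt(two$wet_dry_mean_of_ratios, 0)
})

test_that("annualized_excess_flux matches the hand-derived conversion and is linear", {
  expect_equal(annualized_excess_flux(1.0, 1.0, 0.15), 0)

  # hand oracle: 0.1 umol m-2 s-1 x 31,557,600 s x 44.01e-6 g/umol = 138.885 g
  hand <- 0.1 * 31557600 * 44.01e-6
  got <- annualized_excess_flux(1.1, 1.0, 1)
  expect_lt(abs(got - 138.9), 0.1)
  expect_equal(got, hand)

  # linear in both the Rs difference and the duty fraction
  expect_equal(annualized_excess_flux(2.0, 1.0, 0.15), 10 * got * 0.15)
  expect_equal(annualized_excess_flux(1.2, 1.0, 0.5),
               2 * annualized_excess_flux(1.1, 1.0, 0.5))
  expect_lt(annualized_excess_flux(0.9, 1.0, 0.15), 0)
})
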