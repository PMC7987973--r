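test_that("synth_config validates fields by name", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(ar1 = 1), "ar1")
  expect_error(synth_config(q10 = 0), "q10")
  expect_error(synth_config(missing_frac = 1), "missing_frac")
  expect_error(synth_config(sm_floor = 0.4, sm_ceiling = 0.3), "sm_floor")
})

test_that("the generator chain is fully deterministic under a fixed seed", {
  a <- generate_site(synth_config(seed = 21, clim_years = 2, study_years = 1))
  b <- generate_site(synth_config(seed = 21, clim_years = 2, study_years = 1))
  expect_identical(a$temp_station$tair_c, b$temp_station$tair_c)
  expect_identical(a$sm$sm, b$sm$sm)
  expect_identical(a$flux$rs, b$flux$rs)
  c <- generate_site(synth_config(seed = 22, clim_years = 2, study_years = 1))
  expect_false(identical(a$flux$rs, c$flux$rs))
})

test_that("temperature reduces to its deterministic skeleton and matches the analytic mean", {
  flatcfg <- synth_config(seed = 1, seasonal_amp = 0, diurnal_amp = 0,
                          ar_sd = 0, hw_rate = 0)
  tp <- generate_temperature(flatcfg, years = 0.1)
  expect_true(all(tp$tair_c == 17))

  cfg <- synth_config(seed = 31)
  temp <- generate_temperature(cfg, years = 30)
  lt <- as.POSIXlt(temp$timestamp)
  obs <- tapply(temp$tair_c, paste(lt$mon, lt$hour), mean)
  expected <- tapply(expected_temperature(cfg, temp$timestamp),
                     paste(lt$mon, lt$hour), mean)
  expect_lt(max(abs(obs - expected[names(obs)])), 0.5)
})

test_that("moisture decays monotonically, respects bounds, and clips at saturation", {
  dry_cfg <- synth_config(seed = 41, precip_rate = 0, dew_amp = 0)
  tp <- generate_temperature(dry_cfg, years = 0.2)
  sm <- generate_moisture(dry_cfg, tp, init = 0.30)
  expect_true(all(diff(sm$sm) <= 0))
  expect_lt(abs(sm$sm[nrow(sm)] - dry_cfg$sm_floor), 0.005)

  wet_cfg <- synth_config(seed = 42, precip_rate = 4000, sm_jump = 0.2)
  sm2 <- generate_moisture(wet_cfg, generate_temperature(wet_cfg, years = 0.1))
  expect_lte(max(sm2$sm), wet_cfg$sm_ceiling)
  expect_gte(min(sm2$sm), wet_cfg$sm_floor)
})

test_that("long-run moisture mean is reproducible across independent long runs", {
  cfg_a <- synth_config(seed = 43)
  cfg_b <- synth_config(seed = 44)
  ya <- 5e5 / 8766
  ma <- mean(generate_moisture(cfg_a, generate_temperature(cfg_a, years = ya))$sm)
  mb <- mean(generate_moisture(cfg_b, generate_temperature(cfg_b, years = ya))$sm)
  expect_lt(abs(ma - mb), 0.005)
  expect_gt(ma, cfg_a$sm_floor)
  expect_lt(ma, cfg_a$sm_ceiling)
})

test_that("flux implements the Q10 definition exactly in the noise-free limit", {
  base <- synth_config(seed = 51, seasonal_amp = 0, diurnal_amp = 0, ar_sd = 0,
                       hw_rate = 0, obs_noise_sd = 0, missing_frac = 0,
                       q10 = 1, rref = 1.6)
  tp <- generate_temperature(base, years = 0.05)
  expect_true(all(generate_flux(base, tp)$rs == 1.6))

  q10cfg <- synth_config(seed = 51, seasonal_amp = 0, diurnal_amp = 0, ar_sd = 0,
                         hw_rate = 0, obs_noise_sd = 0, missing_frac = 0,
                         q10 = 2, rref = 1.6, mean_temp = 27, tref = 17)
  tp2 <- generate_temperature(q10cfg, years = 0.05)
  expect_equal(unique(generate_flux(q10cfg, tp2)$rs), 2 * 1.6)

  other <- generate_temperature(base, years = 0.04)
  expect_error(generate_flux(base, tp, sm = generate_moisture(base, other)),
               "misaligned")
})

test_that("sub-hourly emission and missingness shape the record as configured", {
  cfg <- synth_config(seed = 52, subhourly = TRUE, missing_frac = 0)
  tp <- generate_temperature(cfg, years = 0.01)
  fl <- generate_flux(cfg, tp)
  expect_equal(nrow(fl), 5L * nrow(tp))
  hr <- resample_to_hourly(fl)
  expect_true(all(hr$n_obs == 5L))

  cfg2 <- synth_config(seed = 53, missing_frac = 0.07)
  tp2 <- generate_temperature(cfg2, years = 1)
  fl2 <- generate_flux(cfg2, tp2)
  expect_lt(abs(1 - nrow(fl2) / nrow(tp2) - 0.07), 0.01)
})

test_that("ground-truth oracle is symmetric when respiration is flat", {
  # Q10 = 1 and a flat moisture response leave Rs = Rref + symmetric noise
  cfg <- synth_config(seed = 61, q10 = 1, sm_g_floor = 1)
  gt <- ground_truth_exceedance(cfg, conditions = c("HW", "NHW"), n_hours = 2e5)
  expect_true(all(abs(gt$p - 0.5) < 3 * gt$se + 0.01))
})

test_that("oracle orders heat conditions consistently across seeds under Q10 > 1", {
  for (s in c(71, 72, 73, 74, 75)) {
    gt <- ground_truth_exceedance(synth_config(seed = s), conditions = c("HW", "NHW"),
                                  n_hours = 2e5)
    p <- setNames(gt$p, gt$condition)
    expect_gt(p[["HW"]], p[["NHW"]])
  }
})

test_that("oracle standard errors scale as 1/sqrt(n)", {
  cfg <- synth_config(seed = 81)
  se1 <- ground_truth_exceedance(cfg, conditions = "HW", n_hours = 1e5)$se
  se2 <- ground_truth_exceedance(cfg, conditions = "HW", n_hours = 2e5)$se
  expect_lt(abs(se1 / se2 - sqrt(2)), 0.2 * sqrt(2))
})

test_that("generated sites round-trip through the CSV readers", {
  site <- generate_site(synth_config(seed = 91, clim_years = 2, study_years = 0.2))
  dir <- withr::local_tempdir()
  write_site_csv(site, dir)
  fx <- read_flux_csv(file.path(dir, "flux.csv"))
  expect_equal(nrow(fx), nrow(site$flux))
  expect_equal(fx$rs, site$flux$rs, tolerance = 1e-12)
  tp <- read_hourly_temperature_csv(file.path(dir, "temperature.csv"))
  expect_equal(tp$tair_c, site$temp_station$tair_c, tolerance = 1e-12)
})
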