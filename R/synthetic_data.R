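#' Configuration for the synthetic weather / moisture / respiration generator
#'
#' Parameterizes a seeded generator of multi-decadal hourly air temperature,
#' pulse-decay soil moisture and Q10-type soil respiration with known
#' statistical structure, so that every pipeline stage can be validated
#' end-to-end (including probability recovery against a large-sample
#' oracle). Defaults emulate a semi-arid Mediterranean-climate site:
#' annual-mean temperature ~17 degC, soil moisture confined to
#' 0.18-0.37 m3/m3 with Rs unresponsive above saturation (~0.33 m3/m3),
#' mean Rs near 1.1 umol CO2 m-2 s-1, and ~7% of flux observations missing.
#'
#' One master `seed` spawns fixed named substreams (temperature noise, heat
#' episodes, precipitation, observation noise, missingness) so each
#' component is independently reproducible.
#'
#' @param seed Master RNG seed (integer).
#' @param clim_years Years of station record used for the climatology
#'   (default 30).
#' @param study_years Length of the flux study period in years (default 1).
#' @param start Start of the station record (ISO date, local standard
#'   time). The study period is its final `study_years`.
#' @param mean_temp Annual-mean air temperature, degC.
#' @param seasonal_amp,diurnal_amp Amplitudes of the seasonal and diurnal
#'   temperature harmonics, degC.
#' @param peak_doy,peak_hour Day-of-year and hour-of-day of the seasonal
#'   and diurnal maxima.
#' @param ar1,ar_sd AR(1) coefficient (in \[0,1)) and innovation sd of the
#'   temperature noise, degC.
#' @param hw_rate,hw_duration,hw_boost Heat-episode arrivals per year
#'   (Poisson), mean episode duration in hours (geometric) and additive
#'   intensity boost, degC.
#' @param precip_rate Precipitation events per year (Poisson arrivals).
#' @param sm_jump Soil-moisture jump per precipitation event, m3/m3.
#' @param sm_tau Exponential drydown time constant, hours.
#' @param sm_floor,sm_ceiling Soil-moisture bounds, m3/m3.
#' @param dew_amp Amplitude of the hourly nocturnal dew input, m3/m3
#'   (peaks at 03:00 local).
#' @param rref Reference respiration at `tref`, umol CO2 m-2 s-1.
#' @param tref Reference temperature, degC.
#' @param q10 Multiplicative Rs increase per 10 degC warming (> 0; 1 makes
#'   respiration temperature-independent).
#' @param t_lag Soil thermal buffering: window (hours) of the trailing
#'   moving average of air temperature that drives respiration.
#' @param sm_sat Moisture saturation point: the multiplicative moisture
#'   response rises linearly from `sm_g_floor` at `sm_floor` to 1 at
#'   `sm_sat` and is flat above (additional moisture has no effect).
#' @param sm_g_floor Moisture response at the dry end, in (0, 1\].
#' @param obs_noise_sd Gaussian observation noise sd, umol CO2 m-2 s-1.
#' @param missing_frac Fraction of flux observations dropped uniformly at
#'   random (default 0.07).
#' @param subhourly If `TRUE`, emit `n_per_hour` sub-hourly observations
#'   per hour instead of one hourly value.
#' @param n_per_hour Sub-hourly observations per hour (default 5).
#' @return A `synth_config` object (validated list).
#' @export
synth_config <- function(seed = 1L,
                         clim_years = 30, study_years = 1,
                         start = "1986-02-01",
                         mean_temp = 17, seasonal_amp = 8, diurnal_amp = 5,
                         peak_doy = 200, peak_hour = 15,
                         ar1 = 0.8, ar_sd = 1.6,
                         hw_rate = 6, hw_duration = 48, hw_boost = 4,
                         precip_rate = 30, sm_jump = 0.06, sm_tau = 240,
                         sm_floor = 0.18, sm_ceiling = 0.37, dew_amp = 2e-4,
                         rref = 1.6, tref = 17, q10 = 2, t_lag = 6,
                         sm_sat = 0.33, sm_g_floor = 0.4,
                         obs_noise_sd = 0.15, missing_frac = 0.07,
                         subhourly = FALSE, n_per_hour = 5) {
  cfg <- as.list(environment())
  .check_field <- function(ok, field, rule) {
    if (!ok) .stopf("invalid synth_config field '%s': %s", field, rule)
  }
  .check_field(is.numeric(seed) && seed == round(seed), "seed", "must be an integer")
  .check_field(ar1 >= 0 && ar1 < 1, "ar1", "must be in [0, 1)")
  .check_field(all(c(ar_sd, hw_rate, hw_boost, precip_rate, sm_jump, dew_amp,
                     obs_noise_sd) >= 0), "rates/sds", "must be >= 0")
  .check_field(hw_duration >= 1, "hw_duration", "must be >= 1 hour")
  .check_field(sm_floor < sm_ceiling, "sm_floor", "must be below sm_ceiling")
  .check_field(q10 > 0, "q10", "must be > 0")
  .check_field(missing_frac >= 0 && missing_frac < 1, "missing_frac", "must be in [0, 1)")
  .check_field(sm_g_floor > 0 && sm_g_floor <= 1, "sm_g_floor", "must be in (0, 1]")
  .check_field(sm_sat > sm_floor, "sm_sat", "must be above sm_floor")
  .check_field(t_lag >= 1, "t_lag", "must be >= 1 hour")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_config> seed %d: %g-yr climatology + %g-yr study from %s\n",
    "  T: mean %g degC, seasonal %g, diurnal %g, AR1 %g (sd %g), %g episodes/yr (+%g degC, %g h)\n",
    "  SM: %g events/yr (+%g), tau %g h, range [%g, %g], sat %g\n",
    "  Rs: Rref %g at %g degC, Q10 %g, lag %g h, noise sd %g, missing %g%%\n"),
    x$seed, x$clim_years, x$study_years, x$start,
    x$mean_temp, x$seasonal_amp, x$diurnal_amp, x$ar1, x$ar_sd,
    x$hw_rate, x$hw_boost, x$hw_duration,
    x$precip_rate, x$sm_jump, x$sm_tau, x$sm_floor, x$sm_ceiling, x$sm_sat,
    x$rref, x$tref, x$q10, x$t_lag, x$obs_noise_sd, 100 * x$missing_frac))
  invisible(x)
}

# Named substreams off the master seed; kept below 2^31 - 1.
.substream <- function(cfg, stream) {
  k <- match(stream, c("temperature", "episodes", "precip", "noise", "missing"))
  as.integer((as.numeric(cfg$seed) * 7919 + k * 104729) %% 2147483647)
}

.hourly_timestamps <- function(start, years, tz = "UTC") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = tz)
  n <- round(years * 365.25 * 24)
  t0 + 3600 * (seq_len(n) - 1)
}

#' Deterministic mean of the synthetic temperature process
#'
#' Closed-form expectation of the generator at given timestamps: the
#' seasonal + diurnal harmonic mean plus the expected heat-episode boost
#' (`hw_rate x hw_duration x hw_boost / 8766` degC, applied uniformly).
#' Used as the analytic oracle for generator-validation tests.
#'
#' @param cfg A `synth_config`.
#' @param timestamps POSIXct vector.
#' @return Expected temperature, degC.
#' @export
expected_temperature <- function(cfg, timestamps) {
  lt <- as.POSIXlt(timestamps)
  doy <- lt$yday + 1
  hour <- lt$hour
  boost <- cfg$hw_rate * cfg$hw_duration * cfg$hw_boost / 8766
  cfg$mean_temp +
    cfg$seasonal_amp * cos(2 * pi * (doy - cfg$peak_doy) / 365.25) +
    cfg$diurnal_amp * cos(2 * pi * (hour - cfg$peak_hour) / 24) +
    boost
}

#' Generate a synthetic hourly air-temperature record
#'
#' Seasonal + diurnal harmonics around the annual mean, AR(1) noise, and
#' additive heat episodes: Poisson arrivals at `hw_rate` per year, geometric
#' durations with mean `hw_duration` hours, constant boost `hw_boost` degC.
#' Fully deterministic under a fixed config seed.
#'
#' @param cfg A `synth_config`.
#' @param years Record length in years (default: climatology plus study
#'   period, i.e. the full station record).
#' @param start Record start (default `cfg$start`).
#' @return A `temperature_series`.
#' @export
generate_temperature <- function(cfg, years = cfg$clim_years + cfg$study_years,
                                 start = cfg$start) {
  stopifnot(inherits(cfg, "synth_config"))
  ts <- .hourly_timestamps(start, years)
  n <- length(ts)

  base <- expected_temperature(cfg, ts) -
    cfg$hw_rate * cfg$hw_duration * cfg$hw_boost / 8766  # harmonics only

  set.seed(.substream(cfg, "temperature"))
  noise <- if (cfg$ar_sd > 0) {
    as.numeric(stats::filter(rnorm(n, 0, cfg$ar_sd), cfg$ar1, method = "recursive"))
  } else rep(0, n)

  boost <- rep(0, n)
  set.seed(.substream(cfg, "episodes"))
  n_ep <- rpois(1, cfg$hw_rate * n / 8766)
  if (n_ep > 0 && cfg$hw_boost > 0) {
    starts <- sample.int(n, n_ep, replace = TRUE)
    durs <- rgeom(n_ep, 1 / cfg$hw_duration) + 1
    for (i in seq_len(n_ep)) {
      idx <- starts[i]:min(n, starts[i] + durs[i] - 1)
      boost[idx] <- boost[idx] + cfg$hw_boost
    }
  }

  .new_series(tibble::tibble(timestamp = ts, tair_c = base + noise + boost),
              "temperature_series")
}

#' Generate synthetic hourly soil moisture
#'
#' Pulse-decay dynamics: volumetric water content jumps by `sm_jump` at
#' Poisson precipitation arrivals, decays exponentially toward `sm_floor`
#' with time constant `sm_tau`, receives an optional nocturnal dew input
#' (half-sine peaking at 03:00 local), and is clipped at `sm_ceiling`
#' (saturation). Values stay within `[sm_floor, sm_ceiling]`.
#'
#' @param cfg A `synth_config`.
#' @param temp A `temperature_series` supplying the timestamps.
#' @param init Initial moisture (default: stationary mean of the linear
#'   pulse-decay process).
#' @return A `moisture_series`.
#' @export
generate_moisture <- function(cfg, temp, init = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(temp, "temperature_series"))
  ts <- temp$timestamp
  n <- length(ts)
  rate_h <- cfg$precip_rate / 8766

  set.seed(.substream(cfg, "precip"))
  jumps <- cfg$sm_jump * rpois(n, rate_h)
  hour <- as.POSIXlt(ts)$hour
  dew <- cfg$dew_amp * pmax(0, cos(2 * pi * (hour - 3) / 24))

  a <- exp(-1 / cfg$sm_tau)
  if (is.null(init)) {
    # stationary mean of the unclipped recursion
    init <- min(cfg$sm_ceiling,
                cfg$sm_floor + cfg$sm_jump * rate_h * cfg$sm_tau +
                  mean(dew) * cfg$sm_tau)
  }
  s <- numeric(n)
  prev <- init
  for (t in seq_len(n)) {
    val <- cfg$sm_floor + (prev - cfg$sm_floor) * a + jumps[t] + dew[t]
    prev <- min(val, cfg$sm_ceiling)
    s[t] <- prev
  }
  .new_series(tibble::tibble(timestamp = ts, sm = s), "moisture_series")
}

#' Multiplicative moisture response of respiration
#'
#' Piecewise-linear scaling: `sm_g_floor` at `sm_floor`, rising linearly to
#' 1 at the saturation point `sm_sat`, flat at 1 above it -- beyond
#' saturation additional moisture does not increase respiration.
#'
#' @param sm Volumetric water content, m3/m3.
#' @param cfg A `synth_config`.
#' @return Scaling factor in `[sm_g_floor, 1]`.
#' @export
moisture_response <- function(sm, cfg) {
  frac <- (sm - cfg$sm_floor) / (cfg$sm_sat - cfg$sm_floor)
  pmin(1, pmax(cfg$sm_g_floor,
               cfg$sm_g_floor + (1 - cfg$sm_g_floor) * frac))
}

#' Generate a synthetic soil-respiration record
#'
#' Q10-type temperature response modulated by moisture:
#' `Rs(t) = Rref x Q10^((T_lag(t) - Tref)/10) x g(SM(t)) + noise`, where
#' `T_lag` is a trailing moving average of air temperature (soil thermal
#' buffering) and `g` is [moisture_response()]. Optionally emits
#' `n_per_hour` sub-hourly observations per hour; a `missing_frac` fraction
#' of observations is dropped uniformly at random.
#'
#' @param cfg A `synth_config`.
#' @param temp A `temperature_series`.
#' @param sm Optional `moisture_series` on the same timestamps; if `NULL`
#'   the moisture response is 1 everywhere.
#' @return A `flux_series` (with the generated `sm` attached as a column
#'   when moisture is supplied).
#' @export
generate_flux <- function(cfg, temp, sm = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(temp, "temperature_series"))
  ts <- temp$timestamp
  n <- length(ts)
  if (!is.null(sm)) {
    if (nrow(sm) != n || !isTRUE(all(sm$timestamp == ts))) {
      .stopf("temperature and moisture inputs are misaligned")
    }
  }

  # trailing moving average; partial means over the warm-up window
  x <- temp$tair_c
  w <- as.integer(cfg$t_lag)
  t_lag <- if (w <= 1L) x else {
    f <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
    warm <- seq_len(min(w - 1L, n))
    f[warm] <- cumsum(x[warm]) / warm
    f
  }

  g <- if (is.null(sm)) rep(1, n) else moisture_response(sm$sm, cfg)
  mu <- cfg$rref * cfg$q10^((t_lag - cfg$tref) / 10) * g

  if (isTRUE(cfg$subhourly)) {
    k <- as.integer(cfg$n_per_hour)
    offsets <- round(seq(0, 3600 * (k - 1) / k, length.out = k))
    obs_ts <- rep(ts, each = k) + rep(offsets, times = n)
    obs_mu <- rep(mu, each = k)
  } else {
    obs_ts <- ts
    obs_mu <- mu
  }

  set.seed(.substream(cfg, "noise"))
  rs <- obs_mu + rnorm(length(obs_mu), 0, cfg$obs_noise_sd)

  keep <- rep(TRUE, length(rs))
  if (cfg$missing_frac > 0) {
    set.seed(.substream(cfg, "missing"))
    keep <- runif(length(rs)) >= cfg$missing_frac
  }

  out <- tibble::tibble(timestamp = obs_ts[keep], rs = rs[keep])
  if (!is.null(sm) && !isTRUE(cfg$subhourly)) out$sm <- sm$sm[keep]
  .new_series(out, "flux_series")
}

#' Generate a complete synthetic site
#'
#' One call producing everything the pipeline ingests: the full station
#' temperature record (climatology + study period), the study-period
#' temperature, soil moisture and flux. The climatology record includes the
#' study period, matching the convention that station climatologies are
#' trained on the full available record.
#'
#' @param cfg A `synth_config`.
#' @return List with `temp_station` (full record), `temp_study`, `sm`,
#'   `flux` (study period) and `config`.
#' @export
generate_site <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  temp_station <- generate_temperature(cfg)
  n_study <- round(cfg$study_years * 365.25 * 24)
  idx <- seq(nrow(temp_station) - n_study + 1, nrow(temp_station))
  temp_study <- .new_series(tibble::as_tibble(temp_station)[idx, ], "temperature_series")
  sm <- generate_moisture(cfg, temp_study)
  flux <- generate_flux(cfg, temp_study, sm)
  list(temp_station = temp_station, temp_study = temp_study,
       sm = sm, flux = flux, config = cfg)
}

#' Large-sample ground-truth exceedance probabilities of the generator
#'
#' Monte-Carlo oracle for probability-recovery tests: regenerates a long
#' record under `cfg` (missingness disabled -- it thins the sample
#' independently of all conditions) and computes, by direct counting with
#' no pipeline machinery, `P(Rs > mean Rs | condition)` for each requested
#' heat x moisture condition, with the heatwave definition (q-quantile of
#' each month x hour cell) and moisture regimes (0.30/0.70 quantiles)
#' evaluated on the long record itself. Standard errors are binomial.
#'
#' @param cfg A `synth_config`.
#' @param conditions Conditions to report (default all six).
#' @param n_hours Record length in hours (default 1e6).
#' @param q Heatwave percentile (default 0.85).
#' @return Tibble with `condition`, `p`, `se`, `n`.
#' @export
ground_truth_exceedance <- function(cfg, conditions = .CONDITIONS,
                                    n_hours = 1e6, q = 0.85) {
  stopifnot(inherits(cfg, "synth_config"))
  cfg0 <- cfg
  cfg0$missing_frac <- 0
  cfg0$subhourly <- FALSE

  years <- n_hours / 8766
  temp <- generate_temperature(cfg0, years = years)
  sm <- generate_moisture(cfg0, temp)
  flux <- generate_flux(cfg0, temp, sm)

  rs <- flux$rs
  r_star <- mean(rs)

  lt <- as.POSIXlt(temp$timestamp)
  cell <- paste(lt$mon, lt$hour)
  thr <- tapply(temp$tair_c, cell, .quantile7, q = q)
  hot <- temp$tair_c > thr[cell]

  qd <- .quantile7(sm$sm, 0.30)
  qw <- .quantile7(sm$sm, 0.70)
  dry <- sm$sm < qd
  wet <- sm$sm > qw

  masks <- list(HW = hot, NHW = !hot,
                dHW = hot & dry, dNHW = !hot & dry,
                wHW = hot & wet, wNHW = !hot & wet)
  rows <- lapply(conditions, function(cond) {
    m <- masks[[cond]]
    nc <- sum(m)
    p <- mean(rs[m] > r_star)
    tibble::tibble(condition = cond, p = p,
                   se = sqrt(p * (1 - p) / nc), n = nc)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "r_star") <- r_star
  out
}

#' Write a synthetic site to CSV in the ingest dialects
#'
#' Emits `flux.csv` (`timestamp`, `flux_umol_m2_s`, `sm_m3_m3`),
#' `temperature.csv` (`timestamp`, `tair_c`) for the full station record,
#' and `ground_truth.json`-style CSV of generator parameters, so the
#' reader functions can round-trip generated data.
#'
#' @param site Result of [generate_site()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_site_csv <- function(site, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flux <- tibble::tibble(
    timestamp = format(site$flux$timestamp, "%Y-%m-%dT%H:%M:%S"),
    flux_umol_m2_s = site$flux$rs
  )
  if (!is.null(site$flux$sm)) flux$sm_m3_m3 <- site$flux$sm
  readr::write_csv(flux, file.path(dir, "flux.csv"))
  readr::write_csv(tibble::tibble(
    timestamp = format(site$temp_station$timestamp, "%Y-%m-%dT%H:%M:%S"),
    tair_c = site$temp_station$tair_c
  ), file.path(dir, "temperature.csv"))
  invisible(dir)
}
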