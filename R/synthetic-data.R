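#' Configuration for the synthetic meteorology generator
#'
#' Defines a daily meteorological climate in the spirit of a continental
#' urban site: a sinusoidal seasonal temperature cycle with a slow warming
#' drift, pressure noise around a standard base, relative humidity
#' anti-coupled to temperature, lognormal wind speed, and intermittent
#' gamma-distributed precipitation.
#'
#' @param n_years Number of whole calendar years to generate (>= 1).
#' @param start_date First day of the record.
#' @param t_mean_annual Annual mean temperature, degrees C.
#' @param t_seasonal_amplitude Half peak-to-trough seasonal swing, degrees C.
#' @param t_noise_sd Day-to-day temperature noise sd, degrees C (may be 0).
#' @param t_warming_slope Linear warming drift, degrees C per year.
#' @param rh_base Mean relative humidity, percent.
#' @param rh_temp_coupling Change in RH per degree of temperature anomaly,
#'   percent per degree C (typically negative).
#' @param p_base Mean sea-level pressure, hPa.
#' @param p_noise_sd Daily pressure noise sd, hPa (may be 0).
#' @param wind_log_mean Mean of log wind speed, log(m/s).
#' @param wind_log_sd Sd of log wind speed (may be 0).
#' @param precip_prob Probability a day is wet, in [0, 1].
#' @param precip_gamma_shape,precip_gamma_scale Gamma parameters for wet-day
#'   precipitation amounts, mm (both > 0).
#' @param seed Integer seed; identical config + seed gives bit-identical output.
#' @return An object of class `met_gen_config`.
#' @export
met_gen_config <- function(n_years = 12L,
                           start_date = "2009-01-01",
                           t_mean_annual = 12,
                           t_seasonal_amplitude = 10,
                           t_noise_sd = 3,
                           t_warming_slope = 0.05,
                           rh_base = 72,
                           rh_temp_coupling = -1.1,
                           p_base = 1013,
                           p_noise_sd = 6,
                           wind_log_mean = log(2.2),
                           wind_log_sd = 0.45,
                           precip_prob = 0.35,
                           precip_gamma_shape = 0.9,
                           precip_gamma_scale = 6,
                           seed = 1L) {
  check_number(n_years, "n_years", lower = 1, integer = TRUE)
  start_date <- check_date(start_date, "start_date")
  check_number(t_mean_annual, "t_mean_annual")
  check_number(t_seasonal_amplitude, "t_seasonal_amplitude", lower = 0)
  check_number(t_noise_sd, "t_noise_sd", lower = 0)
  check_number(t_warming_slope, "t_warming_slope")
  check_number(rh_base, "rh_base", lower = 0, upper = 100)
  check_number(rh_temp_coupling, "rh_temp_coupling")
  check_number(p_base, "p_base", lower = 0)
  check_number(p_noise_sd, "p_noise_sd", lower = 0)
  check_number(wind_log_mean, "wind_log_mean")
  check_number(wind_log_sd, "wind_log_sd", lower = 0)
  check_number(precip_prob, "precip_prob", lower = 0, upper = 1)
  check_number(precip_gamma_shape, "precip_gamma_shape", lower = 1e-12)
  check_number(precip_gamma_scale, "precip_gamma_scale", lower = 1e-12)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(
      n_years = as.integer(n_years), start_date = start_date,
      t_mean_annual = t_mean_annual,
      t_seasonal_amplitude = t_seasonal_amplitude,
      t_noise_sd = t_noise_sd, t_warming_slope = t_warming_slope,
      rh_base = rh_base, rh_temp_coupling = rh_temp_coupling,
      p_base = p_base, p_noise_sd = p_noise_sd,
      wind_log_mean = wind_log_mean, wind_log_sd = wind_log_sd,
      precip_prob = precip_prob,
      precip_gamma_shape = precip_gamma_shape,
      precip_gamma_scale = precip_gamma_scale,
      seed = as.integer(seed)
    ),
    class = "met_gen_config"
  )
}

#' Generate a daily synthetic meteorological record
#'
#' One row per calendar day (leap days included) with the 14 meteorological
#' variables used as model predictors. By construction `*_max >= *_avg >=
#' *_min` and `*_diff = *_max - *_min` for temperature, pressure and relative
#' humidity; RH is clipped to `[0, 100]`; precipitation is 0 on dry days.
#'
#' @param config A [met_gen_config()].
#' @return A data frame with columns `date` and [met_variables()].
#' @export
generate_meteorology <- function(config) {
  if (!inherits(config, "met_gen_config")) {
    stop("'config' must be a met_gen_config object")
  }
  dates <- year_span_dates(config$start_date, config$n_years)
  n <- length(dates)
  set.seed(config$seed)

  doy <- as.POSIXlt(dates)$yday + 1L
  yrs <- as.numeric(dates - dates[1L]) / 365.25
  # seasonal cycle peaking mid-July (day ~196)
  seas <- cos(2 * pi * (doy - 196) / 365.25)

  t_avg <- config$t_mean_annual + config$t_warming_slope * yrs +
    config$t_seasonal_amplitude * seas + rnorm(n, 0, config$t_noise_sd)
  diurnal <- abs(rnorm(n, 8, 2.5))
  t_max <- t_avg + diurnal / 2
  t_min <- t_avg - diurnal / 2

  p_avg <- config$p_base + rnorm(n, 0, config$p_noise_sd)
  p_up <- abs(rnorm(n, 2.5, 1))
  p_dn <- abs(rnorm(n, 2.5, 1))
  p_max <- p_avg + p_up
  p_min <- p_avg - p_dn

  rh0 <- config$rh_base +
    config$rh_temp_coupling * (t_avg - config$t_mean_annual) + rnorm(n, 0, 4)
  rh_up <- abs(rnorm(n, 10, 3))
  rh_dn <- abs(rnorm(n, 10, 3))
  rh_max <- pmin(100, pmax(0, rh0 + rh_up))
  rh_min <- pmax(0, pmin(100, rh0 - rh_dn))
  rh_avg <- pmin(rh_max, pmax(rh_min, pmin(100, pmax(0, rh0))))

  wind_speed <- rlnorm(n, config$wind_log_mean, config$wind_log_sd)
  wet <- runif(n) < config$precip_prob
  amount <- rgamma(n,
    shape = config$precip_gamma_shape,
    scale = config$precip_gamma_scale
  )
  precipitation <- ifelse(wet, amount, 0)

  data.frame(
    date = dates,
    t_max = t_max, t_min = t_min, t_diff = t_max - t_min, t_avg = t_avg,
    p_max = p_max, p_min = p_min, p_diff = p_max - p_min, p_avg = p_avg,
    rh_max = rh_max, rh_min = rh_min, rh_diff = rh_max - rh_min,
    rh_avg = rh_avg,
    wind_speed = wind_speed, precipitation = precipitation
  )
}

#' Configuration for the synthetic PM generator
#'
#' The generative model is multiplicative: a strictly positive additive core
#' per fraction (base level + long-term trend + winter heating seasonality +
#' temperature coupling + weekday structure) is multiplied by a wind
#' dispersion power law, a precipitation washout factor (both normalized to
#' mean one over the record, so configured levels and slopes keep their
#' ug/m3 units), an optional step intervention, optional event-spike
#' multipliers, and lognormal daily noise.
#' The three fractions are physically nested (`pm10 >= pm25 >= pm1` on every
#' day) because they are built as cumulative sums of nonnegative size-band
#' components, and noise is drawn per component.
#'
#' Per-fraction parameters are named vectors over `c("pm1","pm25","pm10")`;
#' scalars are recycled to the three fractions.
#'
#' @param base_level Base concentration per fraction, ug/m3.
#' @param trend_slope Long-term linear trend per fraction, ug/m3 per year
#'   (typically negative).
#' @param heating_amplitude Winter heating-season boost per fraction, ug/m3;
#'   the seasonal weight peaks mid-January.
#' @param temp_coeff Sensitivity to daily temperature anomaly, ug/m3 per
#'   degree C (typically negative: warm days are cleaner).
#' @param wind_exponent Dispersion power-law exponent applied as
#'   `wind_speed^(-wind_exponent)`.
#' @param precip_washout Fractional reduction per mm precipitation, in [0, 1).
#' @param weekday_effect Length-7 additive weekday profile (Monday..Sunday),
#'   ug/m3 at the pm10 level; smaller fractions receive a share proportional
#'   to their base level.
#' @param noise_log_sd Sd of the multiplicative lognormal daily noise (0 for
#'   a noise-free series).
#' @param intervention_window Optional `c(start, end)` dates of a step
#'   intervention (e.g. a lockdown).
#' @param intervention_effect Fractional change inside the window (e.g. -0.3
#'   for a 30% reduction); must be > -1.
#' @param event_spikes Optional list of events, each
#'   `list(start=, end=, multiplier=c(pm1=, pm25=, pm10=))` with multipliers
#'   nondecreasing from pm1 to pm10 (dust transport loads the coarse
#'   fractions hardest).
#' @param missing_prob Probability a day's PM record is absent (applied by
#'   [inject_gaps()] when generating via [generate_daily_dataset()]).
#' @param t_ref Reference temperature for the anomaly; defaults to the mean
#'   `t_avg` of the supplied meteorology.
#' @param seed Integer seed for the noise draws.
#' @return An object of class `pm_gen_config`.
#' @export
pm_gen_config <- function(base_level = c(pm1 = 15, pm25 = 26, pm10 = 35),
                          trend_slope = c(pm1 = -0.5, pm25 = -0.8, pm10 = -1.1),
                          heating_amplitude = c(pm1 = 8, pm25 = 12, pm10 = 14),
                          temp_coeff = c(pm1 = -0.15, pm25 = -0.25, pm10 = -0.30),
                          wind_exponent = 0.5,
                          precip_washout = 0.03,
                          weekday_effect = c(0.6, 0.8, 0.8, 0.8, 0.4, -1.6, -1.8),
                          noise_log_sd = 0.15,
                          intervention_window = NULL,
                          intervention_effect = 0,
                          event_spikes = list(),
                          missing_prob = 0,
                          t_ref = NULL,
                          seed = 1L) {
  as_frac <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, 3L)
    if (length(x) != 3L) {
      stop(sprintf("'%s' must have length 1 or 3 (pm1, pm25, pm10)", name))
    }
    x <- unname(x)
    names(x) <- .pm_vars
    x
  }
  base_level <- as_frac(base_level, "base_level")
  trend_slope <- as_frac(trend_slope, "trend_slope")
  heating_amplitude <- as_frac(heating_amplitude, "heating_amplitude")
  temp_coeff <- as_frac(temp_coeff, "temp_coeff")
  if (any(base_level <= 0)) stop("'base_level' must be strictly positive")
  if (any(diff(base_level) < 0)) {
    stop("'base_level' must be nondecreasing from pm1 to pm10")
  }
  check_number(wind_exponent, "wind_exponent", lower = 0)
  check_number(precip_washout, "precip_washout", lower = 0, upper = 1 - 1e-9)
  if (length(weekday_effect) != 7L || !is.numeric(weekday_effect)) {
    stop("'weekday_effect' must be a numeric vector of length 7 (Mon..Sun)")
  }
  check_number(noise_log_sd, "noise_log_sd", lower = 0)
  if (!is.null(intervention_window)) {
    intervention_window <- as.Date(intervention_window)
    if (length(intervention_window) != 2L || any(is.na(intervention_window)) ||
      intervention_window[1L] > intervention_window[2L]) {
      stop("'intervention_window' must be c(start, end) with start <= end")
    }
  }
  check_number(intervention_effect, "intervention_effect", lower = -1 + 1e-9)
  for (ev in event_spikes) {
    if (!all(c("start", "end", "multiplier") %in% names(ev))) {
      stop("each element of 'event_spikes' needs start, end and multiplier")
    }
    m <- as_frac(ev$multiplier, "event_spikes$multiplier")
    if (any(m < 0) || any(diff(m) < 0)) {
      stop("'event_spikes' multipliers must be nonnegative and nondecreasing from pm1 to pm10")
    }
  }
  check_number(missing_prob, "missing_prob", lower = 0, upper = 1 - 1e-12)
  if (!is.null(t_ref)) check_number(t_ref, "t_ref")
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(
      base_level = base_level, trend_slope = trend_slope,
      heating_amplitude = heating_amplitude, temp_coeff = temp_coeff,
      wind_exponent = wind_exponent, precip_washout = precip_washout,
      weekday_effect = as.numeric(weekday_effect),
      noise_log_sd = noise_log_sd,
      intervention_window = intervention_window,
      intervention_effect = intervention_effect,
      event_spikes = event_spikes,
      missing_prob = missing_prob,
      t_ref = t_ref,
      seed = as.integer(seed)
    ),
    class = "pm_gen_config"
  )
}

## Winter heating weight in [0, 1], peaking mid-January.
heating_weight <- function(doy) {
  (1 + cos(2 * pi * (doy - 15) / 365.25)) / 2
}

#' Generate nested PM fractions over a meteorological record
#'
#' Builds the noise-free baseline described in [pm_gen_config()], applies
#' per-component lognormal noise, and returns the emitted series together
#' with the ground truth needed by recovery tests: the per-day deterministic
#' baseline, the trend+seasonal component (no weather, no weekday), and the
#' realized noise factors such that
#' `emitted == baseline * noise_factor` holds exactly.
#'
#' @param met A meteorological record from [generate_meteorology()] (gapless).
#' @param config A [pm_gen_config()].
#' @return A list with elements `series` (data frame `date`, `pm1`, `pm25`,
#'   `pm10`) and `ground_truth` (class `pm_ground_truth`: `config`,
#'   `baseline`, `trend_seasonal`, `noise_factor` data frames).
#' @export
generate_pm <- function(met, config) {
  if (!inherits(config, "pm_gen_config")) {
    stop("'config' must be a pm_gen_config object")
  }
  if (!all(c("date", "t_avg", "wind_speed", "precipitation") %in% names(met))) {
    stop("'met' must contain date, t_avg, wind_speed and precipitation")
  }
  dates <- as.Date(met$date)
  n <- length(dates)
  if (n == 0L) stop("'met' is empty")
  if (any(diff(dates) != 1)) stop("'met' must cover a gapless daily span")

  doy <- as.POSIXlt(dates)$yday + 1L
  yrs <- as.numeric(dates - dates[1L]) / 365.25
  w <- heating_weight(doy)
  t_ref <- config$t_ref %||% mean(met$t_avg)
  dT <- met$t_avg - t_ref
  wd <- weekday_index(dates)
  wk <- config$weekday_effect[wd + 1L]

  ## Additive core per fraction, then nonnegative size-band components.
  share <- config$base_level / config$base_level[["pm10"]]
  core <- sapply(.pm_vars, function(f) {
    config$base_level[[f]] + config$trend_slope[[f]] * yrs +
      config$heating_amplitude[[f]] * w + config$temp_coeff[[f]] * dT +
      wk * share[[f]]
  })
  comp <- cbind(
    core[, "pm1"],
    core[, "pm25"] - core[, "pm1"],
    core[, "pm10"] - core[, "pm25"]
  )
  bad <- comp[, 1L] <= 0 | comp[, 2L] < 0 | comp[, 3L] < 0
  if (any(bad)) {
    stop(sprintf(
      "parameters produce a nonpositive PM baseline component; first offending date: %s",
      dates[which(bad)[1L]]
    ))
  }

  ## Shared multiplicative day factor (dispersion, washout, intervention).
  ## Dispersion and washout are normalized to mean one over the record so
  ## they act as relative modifiers: base_level and trend_slope then keep
  ## their ug/m3 units in the emitted series instead of being silently
  ## rescaled by the average weather factor.
  fac_wind <- met$wind_speed^(-config$wind_exponent)
  fac_wash <- (1 - config$precip_washout)^met$precipitation
  fac <- (fac_wind / mean(fac_wind)) * (fac_wash / mean(fac_wash))
  if (!is.null(config$intervention_window)) {
    iv <- dates >= config$intervention_window[1L] &
      dates <= config$intervention_window[2L]
    fac <- fac * ifelse(iv, 1 + config$intervention_effect, 1)
  }

  ## Per-fraction event-spike multipliers.
  mult <- matrix(1, n, 3L, dimnames = list(NULL, .pm_vars))
  for (ev in config$event_spikes) {
    m <- ev$multiplier
    if (length(m) == 1L) m <- rep(m, 3L)
    sel <- dates >= as.Date(ev$start) & dates <= as.Date(ev$end)
    mult[sel, ] <- sweep(mult[sel, , drop = FALSE], 2L, as.numeric(m), `*`)
  }

  set.seed(config$seed)
  if (config$noise_log_sd > 0) {
    eps <- matrix(rlnorm(n * 3L, 0, config$noise_log_sd), n, 3L)
  } else {
    eps <- matrix(1, n, 3L)
  }

  cum_core <- cbind(comp[, 1L], comp[, 1L] + comp[, 2L], rowSums(comp))
  cum_noisy <- cbind(
    comp[, 1L] * eps[, 1L],
    comp[, 1L] * eps[, 1L] + comp[, 2L] * eps[, 2L],
    comp[, 1L] * eps[, 1L] + comp[, 2L] * eps[, 2L] + comp[, 3L] * eps[, 3L]
  )
  noise_factor <- cum_noisy / cum_core
  baseline <- cum_core * fac * mult
  emitted <- baseline * noise_factor
  colnames(baseline) <- colnames(emitted) <- colnames(noise_factor) <- .pm_vars

  trend_seasonal <- sapply(.pm_vars, function(f) {
    config$base_level[[f]] + config$trend_slope[[f]] * yrs +
      config$heating_amplitude[[f]] * w
  })

  series <- data.frame(
    date = dates,
    pm1 = emitted[, "pm1"], pm25 = emitted[, "pm25"], pm10 = emitted[, "pm10"]
  )
  ground_truth <- structure(
    list(
      config = config,
      baseline = data.frame(date = dates, baseline),
      trend_seasonal = data.frame(date = dates, trend_seasonal),
      noise_factor = data.frame(date = dates, noise_factor)
    ),
    class = "pm_ground_truth"
  )
  list(series = series, ground_truth = ground_truth)
}

#' Knock out PM records at random to emulate missing days
#'
#' Each day's PM record (all three fractions jointly) is dropped with
#' probability `missing_prob`; dates are retained with explicit `NA` markers
#' and meteorology is never dropped.
#'
#' @param series A daily data frame containing PM columns.
#' @param missing_prob Probability in `[0, 1)`; 1 is rejected (no data left).
#' @param seed Integer seed.
#' @return The series with `NA`s injected into the PM columns.
#' @export
inject_gaps <- function(series, missing_prob, seed = 1L) {
  check_number(missing_prob, "missing_prob", lower = 0, upper = 1 - 1e-12)
  check_number(seed, "seed", integer = TRUE)
  if (missing_prob == 0) {
    return(series)
  }
  pm_cols <- intersect(.pm_vars, names(series))
  if (length(pm_cols) == 0L) stop("'series' has no PM columns")
  set.seed(seed)
  drop <- runif(nrow(series)) < missing_prob
  series[drop, pm_cols] <- NA_real_
  series
}

#' Generate a complete synthetic daily dataset
#'
#' Convenience wrapper: meteorology, nested PM fractions, and missing-day
#' injection, with stage seeds spawned from the configs' seeds via
#' [substream_seed()].
#'
#' @param met_config A [met_gen_config()].
#' @param pm_config A [pm_gen_config()]; its `missing_prob` drives gap
#'   injection.
#' @return A list with `series` (full daily table: date, PM, meteorology) and
#'   `ground_truth`.
#' @export
generate_daily_dataset <- function(met_config = met_gen_config(),
                                   pm_config = pm_gen_config()) {
  met <- generate_meteorology(met_config)
  pm <- generate_pm(met, pm_config)
  series <- cbind(pm$series, met[setdiff(names(met), "date")])
  if (pm_config$missing_prob > 0) {
    series <- inject_gaps(
      series, pm_config$missing_prob,
      seed = substream_seed(pm_config$seed, "gaps")
    )
  }
  list(series = series, ground_truth = pm$ground_truth)
}
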