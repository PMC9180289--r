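test_that("degenerate temperature config collapses to the annual mean", {
  met <- generate_meteorology(met_gen_config(
    n_years = 1, t_noise_sd = 0, t_seasonal_amplitude = 0,
    t_warming_slope = 0, t_mean_annual = 11.5, seed = 4
  ))
  expect_true(all(met$t_avg == 11.5))
})

test_that("meteorology satisfies its definitional identities", {
  met <- generate_meteorology(met_gen_config(n_years = 3, seed = 2))
  expect_equal(nrow(met), 3 * 365) # 2009-2011 contains no leap year
  expect_equal(met$t_diff, met$t_max - met$t_min)
  expect_equal(met$p_diff, met$p_max - met$p_min)
  expect_equal(met$rh_diff, met$rh_max - met$rh_min)
  expect_true(all(met$t_max >= met$t_avg & met$t_avg >= met$t_min))
  expect_true(all(met$p_max >= met$p_avg & met$p_avg >= met$p_min))
  expect_true(all(met$rh_max >= met$rh_avg & met$rh_avg >= met$rh_min))
  expect_true(all(met$rh_max <= 100 & met$rh_min >= 0))
  expect_true(all(met$precipitation >= 0))
  expect_true(all(met$wind_speed > 0))
})

test_that("leap days are generated on the real calendar", {
  met <- generate_meteorology(met_gen_config(
    n_years = 4, start_date = "2017-01-01", seed = 1
  ))
  expect_equal(nrow(met), 3 * 365 + 366)
  expect_true(as.Date("2020-02-29") %in% met$date)
})

test_that("wet-day fraction matches the configured probability", {
  met <- generate_meteorology(met_gen_config(
    n_years = 10, precip_prob = 0.3, seed = 77
  ))
  wet_frac <- mean(met$precipitation > 0)
  expect_lt(abs(wet_frac - 0.3), 0.02) # 3 * sqrt(p(1-p)/n) ~ 0.023
})

test_that("identical seed and config give bit-identical output", {
  cfg <- met_gen_config(n_years = 2, seed = 123)
  expect_identical(generate_meteorology(cfg), generate_meteorology(cfg))
  met <- generate_meteorology(cfg)
  pm_cfg <- pm_gen_config(seed = 5)
  expect_identical(generate_pm(met, pm_cfg), generate_pm(met, pm_cfg))
})

test_that("invalid generator config is rejected naming the field", {
  expect_error(met_gen_config(n_years = 0), "n_years")
  expect_error(met_gen_config(precip_prob = 1.2), "precip_prob")
  expect_error(met_gen_config(t_noise_sd = -1), "t_noise_sd")
  expect_error(met_gen_config(precip_gamma_scale = 0), "precip_gamma_scale")
  expect_error(pm_gen_config(precip_washout = 1), "precip_washout")
  expect_error(pm_gen_config(weekday_effect = 1:3), "weekday_effect")
  expect_error(pm_gen_config(base_level = c(10, 5, 20)), "base_level")
})

test_that("all-effects-off PM series is constant at base level", {
  met <- generate_meteorology(quiet_met_config())
  pm <- generate_pm(met, flat_pm_config(base_level = c(10, 20, 30)))
  expect_equal(unique(pm$series$pm1), 10)
  expect_equal(unique(pm$series$pm25), 20)
  expect_equal(unique(pm$series$pm10), 30)
})

test_that("a -50% intervention exactly halves in-window values", {
  met <- generate_meteorology(met_gen_config(n_years = 2,
    start_date = "2019-01-01", seed = 3))
  window <- c("2020-04-01", "2020-04-30")
  base <- generate_pm(met, pm_gen_config(noise_log_sd = 0))
  cut <- generate_pm(met, pm_gen_config(
    noise_log_sd = 0,
    intervention_window = window, intervention_effect = -0.5
  ))
  inside <- base$series$date >= as.Date(window[1]) &
    base$series$date <= as.Date(window[2])
  expect_equal(cut$series$pm25[inside], base$series$pm25[inside] / 2)
  expect_equal(cut$series$pm25[!inside], base$series$pm25[!inside])
})

test_that("lognormal noise has zero mean on the log scale", {
  met <- generate_meteorology(met_gen_config(n_years = 12, seed = 8))
  pm <- generate_pm(met, pm_gen_config(noise_log_sd = 0.3, seed = 21))
  lr <- log(pm$series$pm1 / pm$ground_truth$baseline$pm1)
  expect_lt(abs(mean(lr)), 0.02)
  expect_lt(abs(sd(lr) - 0.3), 0.02)
})

test_that("fractions are nested on every day across random configs", {
  for (s in 1:3) {
    met <- generate_meteorology(met_gen_config(n_years = 2, seed = s))
    pm <- generate_pm(met, pm_gen_config(
      noise_log_sd = 0.4, seed = s,
      event_spikes = list(list(
        start = "2009-06-01", end = "2009-06-03",
        multiplier = c(pm1 = 1, pm25 = 3, pm10 = 5)
      ))
    ))
    with(pm$series, {
      expect_true(all(pm10 >= pm25))
      expect_true(all(pm25 >= pm1))
      expect_true(all(pm1 > 0))
    })
  }
})

test_that("emitted series equals baseline times realized noise, exactly", {
  met <- generate_meteorology(met_gen_config(n_years = 2, seed = 14))
  pm <- generate_pm(met, pm_gen_config(noise_log_sd = 0.25, seed = 15))
  for (f in pm_fractions()) {
    expect_identical(
      pm$series[[f]],
      pm$ground_truth$baseline[[f]] * pm$ground_truth$noise_factor[[f]]
    )
  }
})

test_that("parameters driving the baseline negative are rejected with a date", {
  met <- generate_meteorology(quiet_met_config(n_years = 2))
  expect_error(
    generate_pm(met, flat_pm_config(
      base_level = c(5, 10, 15), trend_slope = c(-6, -6, -6)
    )),
    "offending date"
  )
})

test_that("yearly-median slope of the noise-free baseline recovers the trend", {
  met <- generate_meteorology(met_gen_config(n_years = 12, seed = 31))
  pm <- generate_pm(met, pm_gen_config(
    trend_slope = c(pm1 = -0.5, pm25 = -1.0, pm10 = -1.4),
    temp_coeff = c(0, 0, 0), wind_exponent = 0, precip_washout = 0,
    weekday_effect = rep(0, 7), noise_log_sd = 0, seed = 32
  ))
  b <- pm$ground_truth$baseline
  yr <- as.integer(format(b$date, "%Y"))
  med <- tapply(b$pm25, yr, median)
  years <- as.integer(names(med))
  slope <- unname(coef(lm(med ~ years))[2])
  expect_lt(abs(slope - (-1.0)) / 1.0, 0.05)
})

test_that("gap injection drops the expected number of PM days and no met", {
  met <- generate_meteorology(met_gen_config(n_years = 12, seed = 41))
  pm <- generate_pm(met, pm_gen_config(seed = 42))
  series <- cbind(pm$series, met[-1])

  expect_identical(inject_gaps(series, 0), series)
  expect_error(inject_gaps(series, 1), "missing_prob")

  gapped <- inject_gaps(series, 0.05, seed = 43)
  n <- nrow(series)
  n_missing <- sum(is.na(gapped$pm25))
  expect_lt(abs(n_missing - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))
  # all fractions drop together; meteorology untouched
  expect_identical(is.na(gapped$pm1), is.na(gapped$pm10))
  expect_identical(gapped[met_variables()], series[met_variables()])
})
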