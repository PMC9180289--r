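test_that("julian_day counts days from the 1970 epoch", {
  expect_identical(julian_day("1970-01-01"), 0L)
  expect_identical(julian_day("1970-01-02"), 1L)

  # independent oracle: accumulate year lengths by hand up to 2009-01-01
  is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  oracle <- sum(ifelse(is_leap(1970:2008), 366L, 365L))
  expect_identical(oracle, 14245L)
  expect_identical(julian_day("2009-01-01"), 14245L)

  # consecutive dates differ by exactly 1 across a leap boundary
  span <- seq(as.Date("2020-02-27"), as.Date("2020-03-02"), by = "day")
  expect_true(all(diff(julian_day(span)) == 1L))

  expect_error(julian_day("1969-12-31"), "1970")
  expect_error(julian_day("not-a-date"), "invalid")
})

test_that("backfill fills from the next later observation", {
  df <- data.frame(
    date = as.Date("2020-01-01") + 0:2,
    pm25 = c(2.0, NA, 4.0)
  )
  expect_equal(backfill_impute(df)$pm25, c(2, 4, 4))

  df$pm25 <- c(NA, NA, 3.0)
  expect_equal(backfill_impute(df)$pm25, c(3, 3, 3))

  df$pm25 <- c(1, 2, 3)
  expect_identical(backfill_impute(df), df)
})

test_that("backfill is idempotent and rejects trailing gaps", {
  df <- data.frame(
    date = as.Date("2020-01-01") + 0:5,
    pm25 = c(NA, 1, NA, NA, 5, 2),
    pm10 = c(3, NA, 4, 1, NA, 6)
  )
  once <- backfill_impute(df)
  expect_identical(backfill_impute(once), once)

  df$pm10 <- c(3, NA, 4, 1, NA, NA)
  err <- tryCatch(backfill_impute(df), error = conditionMessage)
  expect_match(err, "pm10")
  expect_match(err, "2020-01-05")

  gappy <- data.frame(date = as.Date(c("2020-01-01", "2020-01-03")), x = 1:2)
  expect_error(backfill_impute(gappy), "gapless")
})

test_that("feature table encodes calendar facts and drops missing targets", {
  gen <- generate_daily_dataset(
    met_gen_config(n_years = 2, start_date = "2019-01-01", seed = 6),
    pm_gen_config(seed = 7)
  )
  ft <- build_features(gen$series, "pm25",
    holidays = as.Date(c("2020-01-01", "2020-04-13"))
  )
  expect_equal(nrow(ft), 365 + 366)
  i <- which(ft$date == as.Date("2020-01-04")) # a Saturday
  expect_equal(ft$weekday[i], 5)
  expect_equal(ft$month[i], 1)
  expect_equal(ft$year[i], 2020)
  expect_equal(ft$holiday[i], 0)
  expect_equal(ft$holiday[ft$date == as.Date("2020-01-01")], 1)
  expect_equal(ft$julian_day, julian_day(ft$date))
  expect_false(anyNA(ft))

  # missing targets are dropped with a count
  series <- gen$series
  series$pm25[c(10, 20, 30)] <- NA
  expect_message(
    ft2 <- build_features(series, "pm25"),
    "dropped 3"
  )
  expect_equal(nrow(ft2), nrow(ft) - 3)

  expect_error(build_features(gen$series, "pm3"))
})

test_that("build_features is a pure function of its inputs", {
  gen <- generate_daily_dataset(
    met_gen_config(n_years = 1, seed = 2), pm_gen_config(seed = 3)
  )
  expect_identical(
    build_features(gen$series, "pm10"),
    build_features(gen$series, "pm10")
  )
})

test_that("period splitting reproduces the named 2020 windows", {
  ft <- small_feature_table(n_years = 12, seed = 5)
  # gapless span starting 2009: default periods, no exclusions
  sub <- split_periods(ft, default_periods(), exclusions = list())
  expect_equal(nrow(sub$LDS), 30) # April has 30 days
  expect_equal(nrow(sub$CS), 58) # 3 Jan - 29 Feb in leap 2020
  expect_equal(nrow(sub$MVS), 73) # 3 Jan - 15 Mar
  expect_equal(nrow(sub$NNS), 61) # June + July
  expect_equal(range(sub$LDS$date), as.Date(c("2020-04-01", "2020-04-30")))
  expect_equal(nrow(sub$TDS), sum(format(ft$date, "%Y") < 2020))
})

test_that("exclusion windows remove their dates from every subset", {
  ft <- small_feature_table(n_years = 12, seed = 5)
  excl <- list(exclusion_window("2020-04-10", "2020-04-10", "custom"))
  sub <- split_periods(ft, default_periods(), exclusions = excl)
  for (s in sub) expect_false(as.Date("2020-04-10") %in% s$date)
  expect_equal(nrow(sub$LDS), 29)
  manifest <- attr(sub, "manifest")
  expect_equal(manifest$subsets$LDS$n, 29)
  expect_equal(manifest$subsets$LDS$excluded, "2020-04-10")
})

test_that("period subsets respect partition discipline", {
  ft <- small_feature_table(n_years = 12, seed = 5)
  sub <- split_periods(ft, default_periods())
  for (p in c("MVS", "CS", "LDS", "NNS")) {
    expect_length(intersect(sub$TDS$date, sub[[p]]$date), 0)
  }
  expect_length(intersect(sub$CS$date, sub$LDS$date), 0)
  expect_length(intersect(sub$CS$date, sub$NNS$date), 0)
  expect_length(intersect(sub$LDS$date, sub$NNS$date), 0)
})

test_that("a period selecting zero rows is rejected by name", {
  ft <- small_feature_table(n_years = 2, seed = 5) # 2019-2020
  p <- list(period_def("GHOST", "2021-01-01", "2021-12-31", 2021))
  expect_error(split_periods(ft, p), "GHOST")
})

test_that("ratio diagnostics flag coarse-fraction spikes only", {
  met <- generate_meteorology(met_gen_config(n_years = 1, seed = 4))
  pm <- generate_pm(met, pm_gen_config(
    noise_log_sd = 0.1, seed = 5,
    event_spikes = list(list(
      start = "2009-06-10", end = "2009-06-11",
      multiplier = c(pm1 = 1, pm25 = 2, pm10 = 5)
    ))
  ))
  rd <- ratio_diagnostics(pm$series)
  spike_days <- rd$date %in% as.Date(c("2009-06-10", "2009-06-11"))
  expect_true(all(rd$flagged[spike_days]))
  expect_lt(mean(rd$flagged), 0.02)

  # pm10/pm1 on the spike day is 5x its same-day unspiked value
  unspiked <- generate_pm(met, pm_gen_config(noise_log_sd = 0.1, seed = 5))
  r0 <- unspiked$series$pm10 / unspiked$series$pm1
  expect_equal(rd$ratio_10_1[spike_days], 5 * r0[spike_days])
})

test_that("equal fractions give unit ratios and no flags", {
  df <- data.frame(
    date = as.Date("2020-01-01") + 0:9,
    pm1 = rep(10, 10), pm25 = rep(10, 10), pm10 = rep(10, 10)
  )
  rd <- ratio_diagnostics(df)
  expect_true(all(rd$ratio_10_25 == 1))
  expect_true(all(rd$ratio_10_1 == 1))
  expect_false(any(rd$flagged))
})

test_that("zero denominators give undefined ratios, not errors", {
  df <- data.frame(
    date = as.Date("2020-01-01") + 0:2,
    pm1 = c(0, 5, 5), pm25 = c(5, 5, 5), pm10 = c(10, 10, 10)
  )
  rd <- ratio_diagnostics(df)
  expect_true(is.na(rd$ratio_10_1[1]))
  expect_false(is.na(rd$ratio_10_25[1]))
})

test_that("daily CSV round-trips values, dates and gaps", {
  gen <- generate_daily_dataset(
    met_gen_config(n_years = 1, seed = 8),
    pm_gen_config(missing_prob = 0.1, seed = 9)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_daily_csv(gen$series, path)
  back <- read_daily_csv(path)
  expect_equal(back$date, gen$series$date)
  expect_equal(back$pm25, gen$series$pm25, tolerance = 1e-12)
  expect_identical(is.na(back$pm25), is.na(gen$series$pm25))
})

test_that("croatian holiday calendar covers fixed and movable feasts", {
  h <- croatian_holidays(2020)
  expect_true(as.Date("2020-01-01") %in% h)
  expect_true(as.Date("2020-04-13") %in% h) # Easter Monday 2020
  expect_true(as.Date("2020-05-30") %in% h) # Statehood Day post-reform
  expect_false(as.Date("2020-10-08") %in% h) # dropped in the 2020 reform
  h19 <- croatian_holidays(2019)
  expect_true(as.Date("2019-10-08") %in% h19)
  expect_true(as.Date("2019-04-22") %in% h19) # Easter Monday 2019
})
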