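# Shared fixtures, all generated in code.

# A generator config with every stochastic weather effect switched off:
# temperature is exactly the seasonal curve, wind is constant, no rain.
quiet_met_config <- function(n_years = 2L, start_date = "2019-01-01",
                             seed = 1L, ...) {
  met_gen_config(
    n_years = n_years, start_date = start_date,
    t_noise_sd = 0, p_noise_sd = 0, wind_log_sd = 0, precip_prob = 0,
    seed = seed, ...
  )
}

# A PM config whose only active structure is what the caller turns on.
flat_pm_config <- function(...) {
  args <- modifyList(
    list(
      trend_slope = c(0, 0, 0), heating_amplitude = c(0, 0, 0),
      temp_coeff = c(0, 0, 0), wind_exponent = 0, precip_washout = 0,
      weekday_effect = rep(0, 7), noise_log_sd = 0, seed = 1L
    ),
    list(...)
  )
  do.call(pm_gen_config, args)
}

# Small feature table derived from a short synthetic record.
small_feature_table <- function(n_years = 2L, fraction = "pm25", seed = 9L,
                                noise_log_sd = 0.15) {
  gen <- generate_daily_dataset(
    met_gen_config(n_years = n_years, start_date = "2019-01-01",
      seed = substream_seed(seed, "met")),
    pm_gen_config(noise_log_sd = noise_log_sd,
      seed = substream_seed(seed, "pm"))
  )
  build_features(gen$series, fraction)
}

# Hand-built feature table: one predictor (julian_day), explicit targets.
toy_table <- function(x, y, dates = NULL) {
  dates <- dates %||% (as.Date("2020-01-01") + seq_along(x) - 1L)
  structure(
    data.frame(date = dates, julian_day = x, target = y),
    fraction = "pm25", class = c("feature_table", "data.frame")
  )
}

# Deterministic single-tree forest hyperparameters: with all rows in the
# bag and depth-limited splits, ranger's tree is exactly reproducible by
# hand (midpoint splits, leaf means).
stump_hyperparams <- list(
  num_trees = 1, max_depth = 1, min_node_size = 1, mtry_fraction = 1,
  sample_fraction = 1, replace = FALSE
)

interpolator_hyperparams <- list(
  num_trees = 1, max_depth = 0, min_node_size = 1, mtry_fraction = 1,
  sample_fraction = 1, replace = FALSE
)

`%||%` <- function(a, b) if (is.null(a)) b else a
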