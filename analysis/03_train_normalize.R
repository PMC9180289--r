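#!/usr/bin/env Rscript

# Step 3: tune, train, select and de-weather.
#
# Per fraction: Bayesian optimization of both tree families over
# temporal-block CV on the 2009-2019 training window, validation on the
# Jan-Mar 2020 window (MVS), winner selection by validation RMSE, refit of
# the winning configuration on the full record, and normalization by
# 50 permutation draws with the Julian-day trend variable held fixed.
#
# Desk-scale study sizes (reduced search spaces, 3 CV folds, 8 evaluations,
# 50 draws) keep the whole step in a few minutes; the interfaces scale to
# the full-scale settings (10 folds, larger budgets, 100 draws).

library(metnorm)

seed <- 20090103
dir.create("results/model", recursive = TRUE, showWarnings = FALSE)
fractions <- c("pm25", "pm10")
families <- c("random_forest", "gradient_boosted_trees")

scoreboards <- list()
for (frac in fractions) {
  ft <- read_daily_csv(sprintf("results/prepare/features_%s.csv", frac))
  attr(ft, "fraction") <- frac
  class(ft) <- c("feature_table", "data.frame")
  sub <- split_periods(ft)

  specs <- lapply(families, function(fam) {
    model_spec(fam,
      search_space = reduced_search_space(fam),
      cv_folds = 3, opt_budget = 8,
      seed = substream_seed(seed, paste0("opt:", fam, ":", frac))
    )
  })
  trained <- train_fraction(sub$TDS, sub$MVS, specs)
  scoreboards[[frac]] <- cbind(fraction = frac, trained$scoreboard)
  message(sprintf(
    "%s: winner %s (validation RMSE %.2f, R2 %.2f)",
    frac, trained$winner$family,
    min(trained$scoreboard$rmse),
    trained$scoreboard$r2[which.min(trained$scoreboard$rmse)]
  ))

  full_spec <- model_spec(trained$winner$family,
    search_space = reduced_search_space(trained$winner$family),
    cv_folds = 3, opt_budget = 8,
    seed = substream_seed(seed, paste0("refit:", frac))
  )
  full_model <- fit_model(full_spec, trained$winner$hyperparams, ft)
  norm <- normalize_series(
    full_model, ft,
    normalization_config(
      n_samples = 50,
      seed = substream_seed(seed, paste0("norm:", frac))
    )
  )
  write_daily_csv(norm, sprintf("results/model/normalized_%s.csv", frac))
}
write.csv(do.call(rbind, scoreboards), "results/model/scoreboard.csv",
  row.names = FALSE
)
message("normalized series and scoreboard written under results/model/")
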