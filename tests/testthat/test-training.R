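test_that("temporal-block CV matches hand-run fold arithmetic", {
  # 4 rows, 2 folds; a depth-1 single tree with the whole sample in the bag
  # splits the two training points at their midpoint and predicts leaf means.
  tab <- toy_table(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  spec <- model_spec("random_forest", cv_folds = 2, seed = 1)
  score <- cv_objective(spec, stump_hyperparams, tab)
  # fold 1 held out: model on {3,4} predicts 3 for x<3.5 -> errors (2,1)
  # fold 2 held out: model on {1,2} predicts 2 for x>1.5 -> errors (1,2)
  expect_equal(score, sqrt(mean(c(4, 1))))
})

test_that("a constant target scores zero under both families", {
  ft <- small_feature_table(n_years = 1)
  ft$target <- 7.5
  for (fam in c("random_forest", "gradient_boosted_trees")) {
    spec <- model_spec(fam, cv_folds = 3, seed = 2)
    hp <- if (fam == "random_forest") {
      list(num_trees = 20)
    } else {
      list(num_trees = 20, learning_rate = 0.3)
    }
    expect_lt(cv_objective(spec, hp, ft), 1e-6)
  }
})

test_that("CV scoring is deterministic and degeneracy yields +Inf", {
  ft <- small_feature_table(n_years = 1)
  spec <- model_spec("random_forest", cv_folds = 3, seed = 11)
  hp <- list(num_trees = 10, max_depth = 4)
  expect_identical(cv_objective(spec, hp, ft), cv_objective(spec, hp, ft))

  broken <- ft
  broken$target[5] <- NA
  expect_identical(cv_objective(spec, hp, broken), Inf)
  expect_error(cv_objective(spec, hp, ft[1:2, ]), "fewer rows")
})

test_that("a single-row training set predicts its own target everywhere", {
  tab <- toy_table(x = 5, y = 42)
  spec <- model_spec("random_forest", seed = 1)
  m <- fit_model(spec, list(num_trees = 5), tab)
  expect_equal(
    predict(m, toy_table(x = c(-100, 0, 100), y = c(0, 0, 0))),
    c(42, 42, 42)
  )
})

test_that("a deep forest interpolates noise-free synthetic data", {
  gen <- generate_daily_dataset(
    met_gen_config(n_years = 2, start_date = "2019-01-01", seed = 12),
    pm_gen_config(noise_log_sd = 0, seed = 13)
  )
  ft <- build_features(gen$series, "pm25")
  spec <- model_spec("random_forest", seed = 3)
  m <- fit_model(spec, list(
    num_trees = 100, max_depth = 0, min_node_size = 1,
    sample_fraction = 1, replace = FALSE
  ), ft)
  metrics <- evaluate_model(m, ft)
  expect_gte(metrics$r2, 0.99)
})

test_that("refitting with the same seed reproduces predictions exactly", {
  ft <- small_feature_table(n_years = 1)
  for (fam in c("random_forest", "gradient_boosted_trees")) {
    spec <- model_spec(fam, seed = 21)
    hp <- list(num_trees = 30)
    m1 <- fit_model(spec, hp, ft, seed = 99)
    m2 <- fit_model(spec, hp, ft, seed = 99)
    expect_identical(predict(m1, ft), predict(m2, ft))
  }
})

test_that("evaluation metrics follow their closed forms", {
  # exact interpolator trained on y = (1, 2, 6), evaluated against (1, 2, 3)
  spec <- model_spec("random_forest", seed = 1)
  m <- fit_model(spec, interpolator_hyperparams, toy_table(1:3, c(1, 2, 6)))
  truth <- toy_table(1:3, c(1, 2, 3))
  metrics <- evaluate_model(m, truth)
  expect_equal(metrics$rmse, sqrt(3))
  expect_equal(metrics$r2, -3.5)

  # perfect predictions
  perfect <- evaluate_model(m, toy_table(1:3, c(1, 2, 6)))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)

  # constant truth: rmse valid, r2 undefined
  expect_warning(
    const <- evaluate_model(m, toy_table(1:3, c(2, 2, 2))),
    "undefined"
  )
  expect_true(is.na(const$r2))
  expect_equal(const$rmse, sqrt(mean(c(1, 0, 16))))
})

test_that("predicting the mean gives r2 of zero", {
  y <- c(4, 4, 10, 10)
  m <- fit_model(
    model_spec("random_forest", seed = 1),
    list(
      num_trees = 1, max_depth = 1, min_node_size = 4,
      sample_fraction = 1, replace = FALSE
    ),
    toy_table(c(1, 1, 1, 1), y) # no usable split: root predicts mean(y)
  )
  metrics <- evaluate_model(m, toy_table(c(1, 1, 1, 1), y))
  expect_equal(metrics$r2, 0, tolerance = 1e-12)
})

test_that("winner selection orders by RMSE with a fixed tie-break", {
  mk <- function(fam, rmse) {
    list(
      model = structure(list(family = fam), class = "pm_model"),
      metrics = list(rmse = rmse, r2 = 0.5)
    )
  }
  one <- select_winner(list(mk("random_forest", 10.47)))
  expect_equal(one$family, "random_forest")

  w <- select_winner(list(
    mk("gradient_boosted_trees", 11.2), mk("random_forest", 10.47)
  ))
  expect_equal(w$family, "random_forest")
  expect_equal(nrow(attr(w, "scoreboard")), 2)

  tie <- select_winner(list(
    mk("gradient_boosted_trees", 9.9), mk("random_forest", 9.9)
  ))
  expect_equal(tie$family, "random_forest")

  expect_error(select_winner(list()), "no candidate")
})

test_that("a single-point search space is evaluated exactly once", {
  tab <- small_feature_table(n_years = 1)
  point <- function(v) list(type = "int", lower = v, upper = v)
  spec <- model_spec("random_forest",
    search_space = list(
      num_trees = point(10), max_depth = point(3),
      min_node_size = point(5)
    ),
    cv_folds = 2, opt_budget = 7, seed = 3
  )
  opt <- bayes_optimize(spec, tab)
  expect_equal(nrow(opt$trace), 1)
  expect_equal(opt$hyperparams$num_trees, 10)
  expect_equal(opt$hyperparams$max_depth, 3)
})

test_that("the optimization trace has exactly the budgeted length", {
  tab <- small_feature_table(n_years = 1)[1:120, ]
  spec <- model_spec("random_forest",
    search_space = list(
      num_trees = list(type = "int", lower = 5, upper = 50),
      max_depth = list(type = "int", lower = 1, upper = 10)
    ),
    cv_folds = 2, opt_budget = 6, seed = 4
  )
  opt <- bayes_optimize(spec, tab)
  expect_equal(nrow(opt$trace), 6)
  expect_equal(opt$score, min(opt$trace$score))
  # reproducible under the same seed
  expect_identical(bayes_optimize(spec, tab)$hyperparams, opt$hyperparams)
})

test_that("surrogate optimization is no worse than random search", {
  # toy landscape: forest size from 1 tree (noisy) to ~200 trees (smooth)
  tab <- small_feature_table(n_years = 1)[1:90, ]
  space <- list(
    num_trees = list(type = "int", lower = 1, upper = 200),
    max_depth = list(type = "int", lower = 1, upper = 25)
  )
  budget <- 8
  wins <- 0
  for (rep in 1:20) {
    spec <- model_spec("random_forest",
      search_space = space,
      cv_folds = 2, opt_budget = budget, seed = 100 + rep
    )
    bo_best <- bayes_optimize(spec, tab)$score
    set.seed(5000 + rep)
    rs_best <- min(vapply(seq_len(budget), function(i) {
      u <- runif(length(space))
      cv_objective(spec, metnorm:::decode_point(u, space), tab)
    }, numeric(1)))
    if (bo_best <= rs_best) wins <- wins + 1
  }
  expect_gte(wins, 10)
})

test_that("optimization rejects a space yielding no finite score", {
  tab <- small_feature_table(n_years = 1)[1:30, ]
  tab$target[1] <- NA # every fit attempt fails -> +Inf
  spec <- model_spec("random_forest",
    search_space = list(num_trees = list(type = "int", lower = 5, upper = 10)),
    cv_folds = 2, opt_budget = 3, seed = 5
  )
  expect_error(bayes_optimize(spec, tab), "no finite score")
})

test_that("training rows never overlap the validation window", {
  ft <- small_feature_table(n_years = 2)
  sub <- split_periods(
    ft, default_periods(train_years = 2019, analysis_year = 2020),
    exclusions = list()
  )
  expect_true(max(sub$TDS$date) < min(sub$MVS$date))
})
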