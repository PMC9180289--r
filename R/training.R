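#' Hyperparameter search-space defaults
#'
#' Generous standard ranges per model family. Each entry is
#' `list(type, lower, upper)` with `type` one of `"int"`, `"num"`,
#' `"lognum"` (optimized on a log scale). Random forest: number of trees,
#' maximum depth (0 = unlimited), minimum node size and the fraction of
#' features tried per split. Gradient-boosted trees (leaf-wise): learning
#' rate, leaves, boosting rounds, minimum child samples and feature/bagging
#' fractions.
#'
#' @param family `"random_forest"` or `"gradient_boosted_trees"`.
#' @return Named list of parameter definitions.
#' @export
default_search_space <- function(family = c(
                                   "random_forest",
                                   "gradient_boosted_trees"
                                 )) {
  family <- match.arg(family)
  p <- function(type, lower, upper) list(type = type, lower = lower, upper = upper)
  switch(family,
    random_forest = list(
      num_trees = p("int", 100, 1000),
      max_depth = p("int", 0, 30), # 0 = unlimited
      min_node_size = p("int", 1, 20),
      mtry_fraction = p("num", 0.3, 1.0)
    ),
    gradient_boosted_trees = list(
      learning_rate = p("lognum", 1e-3, 0.3),
      num_leaves = p("int", 7, 255),
      num_trees = p("int", 100, 2000),
      min_child_samples = p("int", 5, 50),
      feature_fraction = p("num", 0.5, 1.0),
      bagging_fraction = p("num", 0.5, 1.0)
    )
  )
}

#' Specify a model family, search space and optimization budget
#'
#' @param family `"random_forest"` or `"gradient_boosted_trees"`.
#' @param search_space Named list of `list(type, lower, upper)` parameter
#'   definitions; defaults to [default_search_space()].
#' @param cv_folds Number of cross-validation folds (>= 2); folds are
#'   contiguous temporal blocks, not shuffled rows, because daily pollution
#'   is autocorrelated.
#' @param opt_budget Number of objective evaluations for the Bayesian
#'   optimizer (>= 1).
#' @param seed Integer seed governing fold fitting and the optimizer.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "gradient_boosted_trees"),
                       search_space = NULL, cv_folds = 10L, opt_budget = 50L,
                       seed = 1L) {
  family <- match.arg(family)
  search_space <- search_space %||% default_search_space(family)
  check_number(cv_folds, "cv_folds", lower = 2, integer = TRUE)
  check_number(opt_budget, "opt_budget", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  for (nm in names(search_space)) {
    def <- search_space[[nm]]
    if (!all(c("type", "lower", "upper") %in% names(def)) ||
      !def$type %in% c("int", "num", "lognum") || def$lower > def$upper) {
      stop(sprintf("malformed search-space entry '%s'", nm))
    }
    if (def$type == "lognum" && def$lower <= 0) {
      stop(sprintf("log-scale parameter '%s' needs a positive lower bound", nm))
    }
  }
  structure(
    list(
      family = family, search_space = search_space,
      cv_folds = as.integer(cv_folds), opt_budget = as.integer(opt_budget),
      seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

feature_columns <- function(table) {
  intersect(.feature_vars, names(table))
}

#' Fit one regression model
#'
#' Dispatches on the spec's family: `ranger` for the random forest,
#' `xgboost` with leaf-wise (`lossguide`) growth for the gradient-boosted
#' trees. Single-threaded and seeded, so refitting with the same inputs
#' reproduces identical predictions.
#'
#' @param spec A [model_spec()].
#' @param hyperparams Named list of hyperparameter values drawn from the
#'   spec's search space (missing entries take the family's library
#'   defaults).
#' @param train A [build_features()] table with no missing values.
#' @param seed Fit seed; defaults to a substream of the spec seed.
#' @return An object of class `pm_model` with a [predict()] method.
#' @export
fit_model <- function(spec, hyperparams, train, seed = NULL) {
  if (nrow(train) == 0L) stop("empty training table")
  feats <- feature_columns(train)
  if (length(feats) == 0L) stop("training table has no predictor columns")
  if (!"target" %in% names(train)) stop("training table has no target column")
  X <- train[feats]
  y <- train$target
  if (anyNA(X) || anyNA(y)) stop("training table contains missing values")
  seed <- seed %||% substream_seed(spec$seed, "fit")
  hp <- hyperparams

  fit <- switch(spec$family,
    random_forest = {
      p <- length(feats)
      mtry <- max(1L, min(p, as.integer(round((hp$mtry_fraction %||% 1) * p))))
      max_depth <- as.integer(hp$max_depth %||% 0L)
      ranger::ranger(
        x = X, y = y,
        num.trees = as.integer(hp$num_trees %||% 500L),
        mtry = mtry,
        min.node.size = as.integer(hp$min_node_size %||% 5L),
        max.depth = max_depth,
        replace = hp$replace %||% TRUE,
        sample.fraction = hp$sample_fraction %||% 1,
        seed = seed, num.threads = 1L
      )
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
      params <- list(
        objective = "reg:squarederror",
        eta = hp$learning_rate %||% 0.1,
        max_depth = 0L,
        max_leaves = as.integer(hp$num_leaves %||% 31L),
        grow_policy = "lossguide",
        tree_method = "hist",
        min_child_weight = hp$min_child_samples %||% 5,
        subsample = hp$bagging_fraction %||% 1,
        colsample_bytree = hp$feature_fraction %||% 1,
        nthread = 1L,
        seed = seed
      )
      xgboost::xgb.train(
        params = params, data = dtrain,
        nrounds = as.integer(hp$num_trees %||% 300L), verbose = 0
      )
    }
  )
  structure(
    list(
      family = spec$family,
      hyperparams = hp,
      fit = fit,
      features = feats,
      fraction = attr(train, "fraction"),
      trained_dates = range(as.Date(train$date)),
      seed = seed
    ),
    class = "pm_model"
  )
}

#' Predict from a fitted PM model
#'
#' @param object A `pm_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (ug/m3).
#' @export
predict.pm_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0L) {
    stop(
      "newdata lacks model feature columns: ",
      paste(missing_cols, collapse = ", ")
    )
  }
  X <- newdata[object$features]
  if (object$family == "random_forest") {
    predict(object$fit, data = X, num.threads = 1L)$predictions
  } else {
    predict(object$fit, xgboost::xgb.DMatrix(as.matrix(X)))
  }
}

#' Mean held-out RMSE over temporal-block cross-validation
#'
#' Rows are ordered by the Julian-day trend variable and cut into
#' `cv_folds` contiguous blocks; each block is held out once. Degenerate
#' hyperparameters that fail to fit or produce non-finite error are reported
#' to the optimizer as `+Inf`, never as an exception.
#'
#' @param spec A [model_spec()].
#' @param hyperparams Named list of hyperparameter values.
#' @param table Feature table with at least `cv_folds` rows.
#' @return Mean held-out RMSE (ug/m3), possibly `Inf`.
#' @export
cv_objective <- function(spec, hyperparams, table) {
  n <- nrow(table)
  k <- spec$cv_folds
  if (n < k) stop("table has fewer rows than cv_folds")
  ord <- order(table$julian_day %||% seq_len(n))
  table <- table[ord, , drop = FALSE]
  fold <- ceiling(seq_len(n) * k / n)
  rmses <- numeric(k)
  for (f in seq_len(k)) {
    res <- tryCatch(
      {
        m <- fit_model(spec, hyperparams, table[fold != f, , drop = FALSE],
          seed = substream_seed(spec$seed, "cv", f)
        )
        pred <- predict(m, table[fold == f, , drop = FALSE])
        sqrt(mean((pred - table$target[fold == f])^2))
      },
      error = function(e) Inf
    )
    rmses[f] <- res
  }
  score <- mean(rmses)
  if (!is.finite(score)) Inf else score
}

#' Validation metrics for a fitted model
#'
#' RMSE and the coefficient of determination `R^2 = 1 - SS_res / SS_tot`
#' about the table's target mean. On a constant target `R^2` is undefined
#' and reported as `NA` with a warning; RMSE is still valid.
#'
#' @param model A `pm_model`.
#' @param table Feature table with a `target` column.
#' @return List with `rmse`, `r2` and `n`.
#' @export
evaluate_model <- function(model, table) {
  pred <- predict(model, table)
  y <- table$target
  rmse <- sqrt(mean((pred - y)^2))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant validation target: R^2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((pred - y)^2) / ss_tot
  }
  list(rmse = rmse, r2 = r2, n = length(y))
}

#' Select the winning model by validation RMSE
#'
#' @param candidates List of `list(model=, metrics=)` entries (as produced by
#'   [train_fraction()]); at least one.
#' @return The winning `pm_model`, with the full scoreboard (family, rmse,
#'   r2) attached as `attr(, "scoreboard")`. Exact RMSE ties prefer the
#'   random forest (fixed, logged tie-break).
#' @export
select_winner <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidate models to select from")
  scoreboard <- data.frame(
    family = vapply(candidates, function(c) c$model$family, character(1)),
    rmse = vapply(candidates, function(c) c$metrics$rmse, numeric(1)),
    r2 = vapply(candidates, function(c) c$metrics$r2, numeric(1))
  )
  best_rmse <- min(scoreboard$rmse)
  idx <- which(scoreboard$rmse == best_rmse)
  if (length(idx) > 1L) {
    rf <- idx[scoreboard$family[idx] == "random_forest"]
    idx <- if (length(rf) > 0L) rf[1L] else idx[1L]
  }
  winner <- candidates[[idx]]$model
  attr(winner, "scoreboard") <- scoreboard
  winner
}

#' Optimize, fit and validate both model families for one fraction
#'
#' Runs Bayesian optimization per family on the training subset, refits each
#' family's best configuration on the full training subset, evaluates on the
#' validation subset and selects the winner by validation RMSE.
#'
#' @param train,validation Feature tables (e.g. the TDS and MVS subsets).
#' @param specs List of [model_spec()]s, one per family.
#' @return List with `winner` (a `pm_model`), `candidates`, `scoreboard` and
#'   per-family optimization `traces`.
#' @export
train_fraction <- function(train, validation, specs) {
  candidates <- list()
  traces <- list()
  for (spec in specs) {
    opt <- bayes_optimize(spec, train)
    model <- fit_model(spec, opt$hyperparams, train)
    metrics <- evaluate_model(model, validation)
    candidates[[spec$family]] <- list(
      model = model, metrics = metrics,
      hyperparams = opt$hyperparams, cv_score = opt$score
    )
    traces[[spec$family]] <- opt$trace
  }
  winner <- select_winner(unname(candidates))
  list(
    winner = winner,
    candidates = candidates,
    scoreboard = attr(winner, "scoreboard"),
    traces = traces
  )
}
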