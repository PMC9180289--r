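#' Configuration for meteorological normalization
#'
#' @param n_samples Number of resampling draws to average (default 100).
#' @param fixed_variables Feature names exempt from resampling; by default
#'   only the Julian-day trend variable, so the normalized series retains
#'   long-term change while weather and short-period calendar structure are
#'   averaged out.
#' @param seed Master seed; each draw's permutation seed is spawned from it.
#' @param mode `"columns"` (default): each non-fixed column is permuted
#'   independently over its own observed values. `"rows"`: one shared row
#'   permutation is applied to all non-fixed columns jointly (sensitivity
#'   switch; preserves the meteorological covariance and therefore averages
#'   less weather out).
#' @param exhaustive If `TRUE`, instead of `n_samples` random draws the
#'   normalizer averages over *every* combination of per-column permutations
#'   (the exact expectation the random draws estimate). Only feasible for
#'   tiny tables; the combination count is capped at 50000.
#' @return An object of class `normalization_config`.
#' @export
normalization_config <- function(n_samples = 100L,
                                 fixed_variables = "julian_day",
                                 seed = 1L,
                                 mode = c("columns", "rows"),
                                 exhaustive = FALSE) {
  check_number(n_samples, "n_samples", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  mode <- match.arg(mode)
  structure(
    list(
      n_samples = as.integer(n_samples),
      fixed_variables = as.character(fixed_variables),
      seed = as.integer(seed), mode = mode,
      exhaustive = isTRUE(exhaustive)
    ),
    class = "normalization_config"
  )
}

## All permutations of 1..n as a list (n small).
all_permutations <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Permute predictors within their own columns
#'
#' Implements "sampling without replacement" of the predictors: every
#' non-fixed predictor column is independently permuted over its rows, so
#' each column's observed multiset is preserved exactly while cross-column
#' (and day-to-column) association is destroyed. Fixed columns, the date and
#' the target are untouched.
#'
#' @param table A feature table.
#' @param fixed Character vector of columns exempt from permutation (must
#'   exist in the table).
#' @param seed Integer seed.
#' @param mode See [normalization_config()].
#' @return The table with permuted predictor columns.
#' @export
resample_predictors <- function(table, fixed = "julian_day", seed = 1L,
                                mode = c("columns", "rows")) {
  mode <- match.arg(mode)
  if (nrow(table) == 0L) stop("'table' is empty")
  absent <- setdiff(fixed, names(table))
  if (length(absent) > 0L) {
    stop("fixed variables not present in table: ", paste(absent, collapse = ", "))
  }
  cols <- setdiff(feature_columns(table), fixed)
  if (length(cols) == 0L) {
    return(table)
  }
  n <- nrow(table)
  set.seed(seed)
  if (mode == "columns") {
    for (col in cols) {
      table[[col]] <- table[[col]][sample.int(n)]
    }
  } else {
    perm <- sample.int(n)
    table[cols] <- table[perm, cols, drop = FALSE]
  }
  table
}

#' De-weather a series by resample-and-predict averaging
#'
#' For each of `n_samples` seeded draws, the predictors are resampled with
#' [resample_predictors()] (the trend variable stays fixed) and the model
#' predicts every day; the per-day mean over draws is the normalized
#' ("de-weathered") series and the per-day standard deviation the draw
#' spread. The whole procedure is reproducible from `(model, table,
#' config)`.
#'
#' @param model A fitted `pm_model`.
#' @param table Feature table covering the days to normalize.
#' @param config A [normalization_config()].
#' @return A `normalized_series` data frame: `date`, `normalized`,
#'   `draw_sd`, `n_samples`.
#' @export
normalize_series <- function(model, table, config = normalization_config()) {
  if (!inherits(config, "normalization_config")) {
    stop("'config' must be a normalization_config object")
  }
  missing_cols <- setdiff(model$features, names(table))
  if (length(missing_cols) > 0L) {
    stop(
      "table lacks model feature columns: ",
      paste(missing_cols, collapse = ", ")
    )
  }
  n <- nrow(table)
  total <- numeric(n)
  total_sq <- numeric(n)
  if (config$exhaustive) {
    cols <- setdiff(feature_columns(table), config$fixed_variables)
    perms <- all_permutations(n)
    n_combo <- if (config$mode == "rows") {
      length(perms)
    } else {
      length(perms)^length(cols)
    }
    if (n_combo > 50000) {
      stop("exhaustive normalization infeasible: ", n_combo, " combinations")
    }
    combo_idx <- if (config$mode == "rows") {
      matrix(seq_along(perms), ncol = 1L)
    } else {
      as.matrix(expand.grid(rep(list(seq_along(perms)), length(cols))))
    }
    for (r in seq_len(nrow(combo_idx))) {
      draw <- table
      if (config$mode == "rows") {
        draw[cols] <- draw[perms[[combo_idx[r, 1L]]], cols, drop = FALSE]
      } else {
        for (j in seq_along(cols)) {
          draw[[cols[j]]] <- table[[cols[j]]][perms[[combo_idx[r, j]]]]
        }
      }
      pred <- predict(model, draw)
      total <- total + pred
      total_sq <- total_sq + pred^2
    }
    k <- nrow(combo_idx)
  } else {
    k <- config$n_samples
    for (i in seq_len(k)) {
      draw <- resample_predictors(
        table,
        fixed = config$fixed_variables,
        seed = substream_seed(config$seed, "draw", i),
        mode = config$mode
      )
      pred <- predict(model, draw)
      total <- total + pred
      total_sq <- total_sq + pred^2
    }
  }
  avg <- total / k
  draw_sd <- if (k > 1L) {
    sqrt(pmax(0, (total_sq - k * avg^2) / (k - 1L)))
  } else {
    rep(0, n)
  }
  structure(
    data.frame(
      date = as.Date(table$date),
      normalized = avg,
      draw_sd = draw_sd,
      n_samples = k
    ),
    fraction = attr(table, "fraction"),
    config = config,
    class = c("normalized_series", "data.frame")
  )
}
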