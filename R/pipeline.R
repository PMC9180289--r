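#' Validate and default a pipeline run configuration
#'
#' Accepts a JSON file path, a JSON string, or a list. Exactly one of
#' `data$input` (daily CSV path) or `data$synthetic` (generator overrides)
#' must be present, and `seed` is mandatory. Unknown keys are rejected;
#' every violation found is reported at once.
#'
#' Recognized keys (with defaults): `seed`; `data` (`input` or `synthetic =
#' list(met = ..., pm = ...)`); `fractions` (`"pm25"`); `families` (both);
#' `model` (`cv_folds` 10, `opt_budget` 50, `spaces` `"default"` or
#' `"reduced"`); `normalization` (`n_samples` 100, `fixed_variables`
#' `"julian_day"`, `mode` `"columns"`); `train_years` (2009-2019);
#' `analysis_year` (2020); `years` (2018-2020); `alpha` (0.05);
#' `exclusions` (the default event windows; supply a list of
#' `{start, end, reason}` to override, or an empty list for none);
#' `refit_full_span` (TRUE: after model selection on TDS/MVS, the winning
#' configuration is refit on the full record before normalization, so the
#' trend variable covers the analysis year).
#'
#' @param raw Path, JSON string, or list.
#' @return A validated `run_config` list with all defaults filled.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    txt <- if (file.exists(raw)) paste(readLines(raw, warn = FALSE), collapse = "\n") else raw
    raw <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  if (!is.list(raw)) stop("config must be a list or JSON object")

  problems <- character(0)
  known <- c(
    "seed", "data", "fractions", "families", "model", "normalization",
    "train_years", "analysis_year", "years", "alpha", "exclusions",
    "periods", "refit_full_span"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    problems <- c(problems, paste0(
      "unknown config keys: ", paste(unknown, collapse = ", ")
    ))
  }
  if (is.null(raw$seed)) {
    problems <- c(problems, "'seed' is mandatory")
  } else if (!is.numeric(raw$seed) || length(raw$seed) != 1L ||
    raw$seed != round(raw$seed)) {
    problems <- c(problems, "'seed' must be a single integer")
  }
  data_block <- raw$data %||% list()
  has_input <- !is.null(data_block$input)
  has_synth <- !is.null(data_block$synthetic)
  if (has_input == has_synth) {
    problems <- c(
      problems,
      "exactly one of data$input or data$synthetic must be given"
    )
  }
  fractions <- raw$fractions %||% "pm25"
  if (!all(fractions %in% .pm_vars)) {
    problems <- c(problems, paste0(
      "unknown fractions: ",
      paste(setdiff(fractions, .pm_vars), collapse = ", ")
    ))
  }
  families <- raw$families %||% c("random_forest", "gradient_boosted_trees")
  bad_fam <- setdiff(families, c("random_forest", "gradient_boosted_trees"))
  if (length(bad_fam) > 0L) {
    problems <- c(problems, paste0(
      "unknown families: ", paste(bad_fam, collapse = ", ")
    ))
  }
  model <- modifyList(
    list(cv_folds = 10L, opt_budget = 50L, spaces = "default"),
    raw$model %||% list()
  )
  if (!model$spaces %in% c("default", "reduced")) {
    problems <- c(problems, "model$spaces must be 'default' or 'reduced'")
  }
  if (!is.numeric(model$cv_folds) || model$cv_folds < 2) {
    problems <- c(problems, "model$cv_folds must be >= 2")
  }
  if (!is.numeric(model$opt_budget) || model$opt_budget < 1) {
    problems <- c(problems, "model$opt_budget must be >= 1")
  }
  normalization <- modifyList(
    list(n_samples = 100L, fixed_variables = "julian_day", mode = "columns"),
    raw$normalization %||% list()
  )
  if (!is.numeric(normalization$n_samples) || normalization$n_samples < 1) {
    problems <- c(problems, "normalization$n_samples must be >= 1")
  }
  alpha <- raw$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    problems <- c(problems, "'alpha' must be in [0, 1]")
  }
  if (length(problems) > 0L) {
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "),
      call. = FALSE
    )
  }

  periods <- default_periods(
    train_years = as.integer(raw$train_years %||% 2009:2019),
    analysis_year = as.integer(raw$analysis_year %||% 2020L)
  )
  if (!is.null(raw$periods)) {
    overrides <- if (is.data.frame(raw$periods)) {
      lapply(seq_len(nrow(raw$periods)), function(i) as.list(raw$periods[i, ]))
    } else {
      raw$periods
    }
    for (p in overrides) {
      periods[[p$name]] <- period_def(
        p$name, p$start, p$end,
        p$years %||% as.integer(raw$analysis_year %||% 2020L)
      )
    }
  }
  ## The standard comparison windows are disjoint, but an overlap is not
  ## inherently invalid: accept with a warning.
  for (pair in list(c("CS", "LDS"), c("CS", "NNS"), c("LDS", "NNS"))) {
    a <- periods[[pair[1L]]]
    b <- periods[[pair[2L]]]
    if (is.null(a) || is.null(b)) next
    if (month_day(a$start) <= month_day(b$end) &&
      month_day(b$start) <= month_day(a$end)) {
      warning(sprintf("periods %s and %s overlap", pair[1L], pair[2L]))
    }
  }

  exclusions <- if (is.null(raw$exclusions)) {
    default_exclusions(raw$analysis_year %||% 2020L)
  } else {
    lapply(seq_len(NROW(raw$exclusions)), function(i) {
      e <- if (is.data.frame(raw$exclusions)) {
        as.list(raw$exclusions[i, ])
      } else {
        raw$exclusions[[i]]
      }
      exclusion_window(e$start, e$end, e$reason %||% "custom")
    })
  }

  structure(
    list(
      seed = as.integer(raw$seed),
      data = data_block,
      fractions = fractions,
      families = families,
      model = model,
      normalization = normalization,
      train_years = as.integer(raw$train_years %||% 2009:2019),
      analysis_year = as.integer(raw$analysis_year %||% 2020L),
      years = as.integer(raw$years %||% 2018:2020),
      alpha = alpha,
      exclusions = exclusions,
      periods = periods,
      refit_full_span = isTRUE(raw$refit_full_span %||% TRUE)
    ),
    class = "run_config"
  )
}

build_synthetic_input <- function(config) {
  synth <- config$data$synthetic
  met_args <- synth$met %||% list()
  pm_args <- synth$pm %||% list()
  if (!is.null(pm_args$intervention_window)) {
    pm_args$intervention_window <- as.Date(unlist(pm_args$intervention_window))
  }
  met_args$seed <- met_args$seed %||% substream_seed(config$seed, "met")
  pm_args$seed <- pm_args$seed %||% substream_seed(config$seed, "pm")
  met_cfg <- do.call(met_gen_config, met_args)
  pm_cfg <- do.call(pm_gen_config, pm_args)
  generate_daily_dataset(met_cfg, pm_cfg)
}

## Drop trailing days whose PM record is entirely missing: the backfill rule
## has no later observation to copy from there.
trim_trailing_missing <- function(series) {
  pm_cols <- intersect(.pm_vars, names(series))
  all_na <- apply(is.na(series[pm_cols]), 1L, all)
  keep_until <- max(which(!all_na))
  if (keep_until < nrow(series)) {
    message(sprintf(
      "trimmed %d trailing day(s) with fully missing PM",
      nrow(series) - keep_until
    ))
    series <- series[seq_len(keep_until), , drop = FALSE]
  }
  series
}

#' Run the full de-weathering pipeline
#'
#' Executes simulate/ingest, backfill imputation, feature construction,
#' period splitting, per-family Bayesian optimization and training with
#' winner selection on the validation window, meteorological normalization,
#' and the ANOVA period comparison, writing every intermediate artifact plus
#' a manifest and report into `out_dir`. Re-running with the same config
#' reproduces all numeric outputs bit for bit.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param out_dir Output directory (created if needed).
#' @return The report (invisibly); artifacts under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  ground_truth <- NULL
  series <- stage("data", {
    if (!is.null(config$data$synthetic)) {
      gen <- build_synthetic_input(config)
      ground_truth <- gen$ground_truth
      write_daily_csv(gen$series, file.path(out_dir, "daily.csv"))
      write_daily_csv(
        gen$ground_truth$baseline,
        file.path(out_dir, "ground_truth_baseline.csv")
      )
      gen$series
    } else {
      read_daily_csv(config$data$input)
    }
  })

  series <- stage("impute", {
    backfill_impute(trim_trailing_missing(series))
  })

  periods <- config$periods
  spaces_for <- function(family) {
    if (config$model$spaces == "reduced") {
      reduced_search_space(family)
    } else {
      default_search_space(family)
    }
  }

  report_tests <- list()
  scoreboards <- list()
  normalized <- list()
  for (frac in config$fractions) {
    features <- stage(paste0("features:", frac), {
      build_features(series, frac)
    })
    subsets <- stage(paste0("split:", frac), {
      split_periods(features, periods, config$exclusions)
    })
    trained <- stage(paste0("train:", frac), {
      specs <- lapply(config$families, function(fam) {
        model_spec(fam,
          search_space = spaces_for(fam),
          cv_folds = config$model$cv_folds,
          opt_budget = config$model$opt_budget,
          seed = substream_seed(config$seed, paste0("opt:", fam, ":", frac))
        )
      })
      train_fraction(subsets$TDS, subsets$MVS, specs)
    })
    scoreboards[[frac]] <- trained$scoreboard
    norm_model <- stage(paste0("refit:", frac), {
      if (config$refit_full_span) {
        spec <- model_spec(trained$winner$family,
          search_space = spaces_for(trained$winner$family),
          cv_folds = config$model$cv_folds,
          opt_budget = config$model$opt_budget,
          seed = substream_seed(config$seed, paste0("refit:", frac))
        )
        fit_model(spec, trained$winner$hyperparams, features)
      } else {
        trained$winner
      }
    })
    normalized[[frac]] <- stage(paste0("normalize:", frac), {
      normalize_series(
        norm_model, features,
        normalization_config(
          n_samples = config$normalization$n_samples,
          fixed_variables = config$normalization$fixed_variables,
          seed = substream_seed(config$seed, paste0("norm:", frac)),
          mode = config$normalization$mode
        )
      )
      })
    write_daily_csv(
      normalized[[frac]],
      file.path(out_dir, sprintf("normalized_%s.csv", frac))
    )
  }

  report <- stage("compare", {
    lockdown_report(
      normalized,
      periods = periods[c("LDS", "NNS")],
      years = config$years,
      alpha = config$alpha,
      exclusions = config$exclusions
    )
  })

  scoreboard_df <- do.call(rbind, lapply(names(scoreboards), function(frac) {
    cbind(fraction = frac, scoreboards[[frac]])
  }))
  write.csv(scoreboard_df, file.path(out_dir, "scoreboard.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      alpha = report$alpha, years = report$years,
      tests = report$tests
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))

  manifest <- list(
    config = list(
      seed = config$seed,
      fractions = config$fractions,
      families = config$families,
      model = config$model,
      normalization = config$normalization,
      train_years = config$train_years,
      analysis_year = config$analysis_year,
      years = config$years,
      alpha = config$alpha,
      refit_full_span = config$refit_full_span,
      exclusions = lapply(config$exclusions, function(e) {
        list(
          start = as.character(e$start), end = as.character(e$end),
          reason = e$reason
        )
      }),
      synthetic = !is.null(config$data$synthetic)
    ),
    n_days = nrow(series),
    scoreboard = scoreboard_df
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}
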