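#' Days elapsed since 1 January 1970
#'
#' The Julian-day trend variable: an exact count of calendar days from the
#' Unix epoch, with `1970-01-01 -> 0`. This is the one predictor exempt from
#' resampling during normalization, so the normalized series retains
#' long-term change.
#'
#' @param date A date (or vector of dates) on or after 1970-01-01.
#' @return Integer day counts.
#' @export
julian_day <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) as.Date(NA))
  if (length(d) != length(date) || any(is.na(d))) {
    stop("invalid date passed to julian_day()")
  }
  jd <- as.integer(d - as.Date("1970-01-01"))
  if (any(jd < 0L)) {
    stop("julian_day() is defined for dates on or after 1970-01-01")
  }
  jd
}

#' Backfill-impute missing daily values
#'
#' Each missing value is replaced by the next later non-missing value in its
#' column; runs of missing days all take the first later observation. A run
#' of missing values at the end of a column has no later observation and is
#' an error (the rule is undefined there): trim the series or supply data.
#'
#' @param series Daily data frame with a contiguous `date` column; all other
#'   numeric columns are imputed.
#' @param columns Columns to impute; defaults to every non-date column.
#' @return The series with no missing values in the imputed columns.
#' @export
backfill_impute <- function(series, columns = NULL) {
  if (!"date" %in% names(series)) stop("'series' needs a date column")
  dates <- as.Date(series$date)
  if (nrow(series) > 1L && any(diff(dates) != 1)) {
    stop("backfill imputation requires a gapless daily date sequence")
  }
  columns <- columns %||% setdiff(names(series), "date")
  trailing <- character(0)
  for (col in columns) {
    x <- series[[col]]
    if (!anyNA(x)) next
    filled <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)
    if (anyNA(filled)) {
      bad <- dates[is.na(filled)]
      trailing <- c(trailing, sprintf(
        "%s (%s..%s)", col, min(bad), max(bad)
      ))
      next
    }
    series[[col]] <- filled
  }
  if (length(trailing) > 0L) {
    stop(
      "backfill undefined for trailing missing values in: ",
      paste(trailing, collapse = ", ")
    )
  }
  series
}

#' Build the model-ready feature table for one PM fraction
#'
#' Combines the 14 meteorological predictors with 5 temporal predictors
#' (weekday 0=Monday..6=Sunday, Julian day, month, year, holiday flag) and
#' the selected fraction as target. Rows whose target is missing are dropped
#' (count reported via `message()`); meteorological predictors must already
#' be imputed.
#'
#' @param series An imputed daily series (PM + meteorology).
#' @param fraction One of `"pm1"`, `"pm25"`, `"pm10"`.
#' @param holidays Vector of holiday dates; defaults to the bundled Croatian
#'   calendar over the series' span.
#' @return A `feature_table` data frame: `date`, predictors, `target`; the
#'   fraction is recorded in `attr(, "fraction")`.
#' @export
build_features <- function(series, fraction = c("pm25", "pm1", "pm10"),
                           holidays = NULL) {
  fraction <- match.arg(fraction)
  if (!fraction %in% names(series)) {
    stop(sprintf("series has no column '%s'", fraction))
  }
  missing_met <- setdiff(.met_vars, names(series))
  if (length(missing_met) > 0L) {
    stop(
      "series lacks meteorological columns: ",
      paste(missing_met, collapse = ", ")
    )
  }
  if (anyNA(series[.met_vars])) {
    stop("meteorological predictors contain missing values; impute first")
  }
  dates <- as.Date(series$date)
  holidays <- as.Date(holidays %||% croatian_holidays(unique(as.integer(format(dates, "%Y")))))

  tab <- data.frame(
    date = dates,
    series[.met_vars],
    weekday = weekday_index(dates),
    julian_day = julian_day(dates),
    month = as.integer(format(dates, "%m")),
    year = as.integer(format(dates, "%Y")),
    holiday = as.integer(dates %in% holidays),
    target = series[[fraction]]
  )
  dropped <- sum(is.na(tab$target))
  if (dropped > 0L) {
    message(sprintf(
      "build_features: dropped %d row(s) with missing %s target", dropped,
      fraction
    ))
    tab <- tab[!is.na(tab$target), , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no rows left after dropping missing targets")
  rownames(tab) <- NULL
  structure(tab,
    fraction = fraction,
    class = c("feature_table", "data.frame")
  )
}

#' Define an analysis period
#'
#' A named inclusive month-day window applied to a set of years; e.g. the
#' lockdown set LDS is 1–30 April of 2020. Windows may not cross the turn of
#' the year.
#'
#' @param name Period name (TDS, MVS, CS, LDS, NNS, OFFICIAL_LOCKDOWN, or a
#'   custom label).
#' @param start,end Dates whose month and day delimit the window (inclusive);
#'   `start`'s month-day must not come after `end`'s.
#' @param years Integer years the window applies to.
#' @return An object of class `period_def`.
#' @export
period_def <- function(name, start, end, years) {
  start <- check_date(start, "start")
  end <- check_date(end, "end")
  if (month_day(start) > month_day(end)) {
    stop("'start' month-day must not come after 'end' month-day")
  }
  structure(
    list(name = name, start = start, end = end, years = as.integer(years)),
    class = "period_def"
  )
}

#' Define an exclusion window for out-of-ordinary events
#'
#' @param start,end Inclusive calendar dates.
#' @param reason Free-text label (earthquake, dust, construction, custom).
#' @return An object of class `exclusion_window`.
#' @export
exclusion_window <- function(start, end, reason = "custom") {
  start <- check_date(start, "start")
  end <- check_date(end, "end")
  if (start > end) stop("'start' must be <= 'end'")
  structure(
    list(start = start, end = end, reason = reason),
    class = "exclusion_window"
  )
}

#' Default analysis periods
#'
#' The study's named windows: training set TDS (whole training years), model
#' validation set MVS (3 January–15 March), comparison set CS (3 January–29
#' February), lockdown set LDS (1–30 April), new-normal set NNS (1 June–31
#' July), and the official lockdown span (13 March–11 May), the latter five
#' in the analysis year.
#'
#' @param train_years Years forming the training set (default 2009–2019).
#' @param analysis_year Year under investigation (default 2020).
#' @return A named list of [period_def()]s.
#' @export
default_periods <- function(train_years = 2009:2019, analysis_year = 2020L) {
  y <- analysis_year
  d <- function(md) sprintf("%d-%s", y, md)
  list(
    TDS = period_def("TDS", d("01-01"), d("12-31"), train_years),
    MVS = period_def("MVS", d("01-03"), d("03-15"), y),
    CS = period_def("CS", d("01-03"), d("02-29"), y),
    LDS = period_def("LDS", d("04-01"), d("04-30"), y),
    NNS = period_def("NNS", d("06-01"), d("07-31"), y),
    OFFICIAL_LOCKDOWN = period_def(
      "OFFICIAL_LOCKDOWN", d("03-13"), d("05-11"), y
    )
  )
}

#' Default out-of-ordinary event exclusions
#'
#' The 2020 windows excluded from analysis: the Zagreb earthquake (22 March),
#' desert-dust transport (26–30 March), and construction activity near the
#' site (early March; August–September). All are overridable; the dust
#' window's exact extent is reported ambiguously (24–30 vs 26–30 March) and
#' the narrower reading is the default.
#'
#' @param analysis_year Year the defaults refer to (default 2020).
#' @return A list of [exclusion_window()]s.
#' @export
default_exclusions <- function(analysis_year = 2020L) {
  y <- analysis_year
  d <- function(md) sprintf("%d-%s", y, md)
  list(
    exclusion_window(d("03-22"), d("03-22"), "earthquake"),
    exclusion_window(d("03-26"), d("03-30"), "dust"),
    exclusion_window(d("03-01"), d("03-15"), "construction"),
    exclusion_window(d("08-01"), d("09-30"), "construction")
  )
}

exclusion_dates <- function(exclusions) {
  if (length(exclusions) == 0L) {
    return(as.Date(character(0)))
  }
  do.call(c, lapply(exclusions, function(e) seq(e$start, e$end, by = "day")))
}

#' Split a feature table into named period subsets
#'
#' Each subset contains exactly the rows inside its period's month-day bounds
#' and years, minus any rows falling in an exclusion window. Subsets are row
#' views, never re-imputed. The attached `"manifest"` attribute records
#' per-subset row counts and excluded dates.
#'
#' @param table A [build_features()] table (any data frame with a `date`).
#' @param periods Named list of [period_def()]s; default [default_periods()].
#' @param exclusions List of [exclusion_window()]s; default
#'   [default_exclusions()].
#' @return Named list of data frames, one per period, with a `manifest`
#'   attribute.
#' @export
split_periods <- function(table, periods = default_periods(),
                          exclusions = default_exclusions()) {
  if (length(periods) == 0L) stop("'periods' must be non-empty")
  dates <- as.Date(table$date)
  md <- month_day(dates)
  yr <- as.integer(format(dates, "%Y"))
  excl <- exclusion_dates(exclusions)

  out <- list()
  manifest <- list(subsets = list(), excluded_dates = as.character(sort(unique(excl))))
  for (p in periods) {
    sel <- md >= month_day(p$start) & md <= month_day(p$end) & yr %in% p$years
    sel_excl <- sel & dates %in% excl
    sel <- sel & !dates %in% excl
    if (!any(sel)) {
      stop(sprintf("period '%s' selects zero rows", p$name))
    }
    sub <- table[sel, , drop = FALSE]
    rownames(sub) <- NULL
    out[[p$name]] <- sub
    manifest$subsets[[p$name]] <- list(
      n = sum(sel),
      excluded = as.character(dates[sel_excl])
    )
  }
  attr(out, "manifest") <- manifest
  out
}

#' Screen PM ratios for out-of-ordinary events
#'
#' Computes per-day `pm10/pm25` and `pm10/pm1` ratios and flags days where a
#' ratio exceeds `median + k * MAD` of that ratio as candidate
#' out-of-ordinary events (desert-dust transport inflates the coarse
#' fraction). Flags are advisory — they are never auto-applied as
#' exclusions. Zero or missing denominators give an undefined (`NA`) ratio.
#'
#' @param series Daily series with PM columns.
#' @param k Robust threshold multiplier (default 5).
#' @return Data frame `date`, `ratio_10_25`, `ratio_10_1`, per-ratio flags
#'   and a combined `flagged` column; thresholds in `attr(, "thresholds")`.
#' @export
ratio_diagnostics <- function(series, k = 5) {
  if (!all(.pm_vars %in% names(series))) {
    stop("'series' must contain pm1, pm25 and pm10 columns")
  }
  safe_ratio <- function(num, den) {
    r <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
    r
  }
  r25 <- safe_ratio(series$pm10, series$pm25)
  r1 <- safe_ratio(series$pm10, series$pm1)
  thr <- function(r) {
    ok <- is.finite(r)
    if (!any(ok)) {
      return(NA_real_)
    }
    median(r[ok]) + k * mad(r[ok])
  }
  t25 <- thr(r25)
  t1 <- thr(r1)
  flag25 <- !is.na(r25) & !is.na(t25) & r25 > t25
  flag1 <- !is.na(r1) & !is.na(t1) & r1 > t1
  structure(
    data.frame(
      date = as.Date(series$date),
      ratio_10_25 = r25, ratio_10_1 = r1,
      flag_10_25 = flag25, flag_10_1 = flag1,
      flagged = flag25 | flag1
    ),
    thresholds = c(ratio_10_25 = t25, ratio_10_1 = t1)
  )
}

#' Read a daily series CSV
#'
#' ISO-8601 dates, period decimal separator, empty cells for missing values.
#'
#' @param path File path.
#' @return A daily series data frame with a `Date`-classed `date` column.
#' @export
read_daily_csv <- function(path) {
  x <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (!"date" %in% names(x)) stop("daily CSV must have a 'date' column")
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable dates in daily CSV")
  if (anyDuplicated(x$date)) stop("duplicate dates in daily CSV")
  if (is.unsorted(x$date)) stop("dates in daily CSV must be increasing")
  x
}

#' Write a daily series CSV
#'
#' @param series Daily series data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(series, path) {
  out <- series
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
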