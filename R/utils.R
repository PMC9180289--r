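`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a master seed
#'
#' Every random decision in the pipeline is reached from one master seed
#' through named substreams, so that changing the work done in one stage does
#' not shift the random numbers drawn by another. The mapping is a fixed
#' integer hash of `(master, key, index)` into the range of R's 32-bit seeds.
#'
#' @param master Integer master seed.
#' @param key Character stream label, e.g. `"met"`, `"draw"`.
#' @param index Optional integer within-stream index (e.g. draw number).
#' @return An integer usable with [set.seed()].
#' @export
substream_seed <- function(master, key, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% m
  x <- abs(as.numeric(master)) %% m
  x <- (x * 48271) %% m
  x <- (x + h * 69621) %% m
  x <- (x + (abs(as.numeric(index)) %% m) * 16807) %% m
  as.integer(x)
}

## Scalar validators used by the config constructors; errors name the field.
check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
      call. = FALSE
    )
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be a whole number, got %s", name, x), call. = FALSE)
  }
  invisible(x)
}

check_date <- function(x, name) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) {
    stop(sprintf("'%s' must be a single valid date", name), call. = FALSE)
  }
  d
}

## Weekday as 0 = Monday ... 6 = Sunday (ordinal feature for the tree models).
weekday_index <- function(dates) {
  as.integer(format(as.Date(dates), "%u")) - 1L
}

## Month-day key for period windows that repeat across years.
month_day <- function(dates) {
  d <- as.Date(dates)
  as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d"))
}

## Calendar span of n whole years starting at start_date (leap days included).
year_span_dates <- function(start_date, n_years) {
  start <- as.Date(start_date)
  end <- seq(start, by = paste(n_years, "years"), length.out = 2L)[2L] - 1L
  seq(start, end, by = "day")
}
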