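## Gregorian Easter Sunday (anonymous computus, Meeus/Jones/Butcher).
easter_sunday <- function(year) {
  a <- year %% 19
  b <- year %/% 100
  c <- year %% 100
  d <- b %/% 4
  e <- b %% 4
  f <- (b + 8) %/% 25
  g <- (b - f + 1) %/% 3
  h <- (19 * a + b - d - g + 15) %% 30
  i <- c %/% 4
  k <- c %% 4
  l <- (32 + 2 * e + 2 * i - h - k) %% 7
  m <- (a + 11 * h + 22 * l) %/% 451
  month <- (h + l - 7 * m + 114) %/% 31
  day <- ((h + l - 7 * m + 114) %% 31) + 1
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

#' Croatian public holidays
#'
#' Holiday dates for the requested years: fixed national and religious
#' holidays plus the movable Easter Monday and Corpus Christi, including the
#' 2020 calendar reform (Statehood Day moved from 25 June to 30 May,
#' Independence Day on 8 October replaced by Remembrance Day on 18 November).
#' Used as the default `holiday` feature flag; the synthetic generator tests
#' supply their own list so nothing downstream depends on this calendar.
#'
#' @param years Integer vector of years.
#' @return Sorted vector of `Date`s.
#' @export
croatian_holidays <- function(years) {
  years <- sort(unique(as.integer(years)))
  out <- as.Date(character(0))
  for (y in years) {
    fixed <- c(
      "01-01", # New Year
      "01-06", # Epiphany
      "05-01", # Labour Day
      "06-22", # Anti-Fascist Struggle Day
      "08-05", # Victory and Homeland Thanksgiving Day
      "08-15", # Assumption
      "11-01", # All Saints
      "12-25", "12-26" # Christmas
    )
    if (y >= 2020L) {
      fixed <- c(fixed, "05-30", "11-18") # Statehood Day; Remembrance Day
    } else {
      fixed <- c(fixed, "06-25", "10-08") # Statehood Day; Independence Day
    }
    easter <- easter_sunday(y)
    out <- c(
      out,
      as.Date(sprintf("%d-%s", y, fixed)),
      easter + 1L, # Easter Monday
      easter + 60L # Corpus Christi
    )
  }
  sort(out)
}
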