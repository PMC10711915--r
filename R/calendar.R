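#' Study calendar of analysis weeks
#'
#' Builds the weekly grid used throughout the evaluation: consecutive 7-day
#' blocks from a start date, with the indices of the week containing the levy
#' announcement (16 March 2016) and the week containing its implementation
#' (6 April 2018), plus Christmas-period and Easter-week indicators.
#'
#' The defaults reproduce the study window: 107 complete weeks before the
#' announcement (weeks start on Wednesdays, the announcement date itself
#' opening week 108), implementation falling in week 215, and 266 weeks in
#' total so the final week starts in late March 2019 -- roughly one year
#' after implementation.
#'
#' @param start_date Date of the first day of week 1.
#' @param n_weeks Total number of weeks in the grid.
#' @param announcement_date,implementation_date Dates of the two
#'   interruptions; each must fall inside the grid and the announcement must
#'   precede the implementation.
#'
#' @return An object of class `levy_calendar`: a list with `weeks` (a tibble
#'   with `week`, `week_start_date`, `christmas`, `easter`), `n_weeks`,
#'   `announcement_week` and `implementation_week` (1-based indices of the
#'   weeks containing each date).
#' @examples
#' cal <- study_calendar()
#' cal$announcement_week   # 108
#' cal$implementation_week # 215
#' @export
study_calendar <- function(start_date = as.Date("2014-02-26"),
                           n_weeks = 266L,
                           announcement_date = as.Date("2016-03-16"),
                           implementation_date = as.Date("2018-04-06")) {
  start_date <- as.Date(start_date)
  n_weeks <- as.integer(n_weeks)
  stopifnot(n_weeks >= 2L)
  announcement_date <- as.Date(announcement_date)
  implementation_date <- as.Date(implementation_date)

  week_of <- function(d) as.integer(floor(as.numeric(d - start_date) / 7)) + 1L
  ann_week <- week_of(announcement_date)
  imp_week <- week_of(implementation_date)
  if (!(ann_week >= 1L && ann_week < imp_week && imp_week <= n_weeks)) {
    abort(glue::glue(
      "announcement week ({ann_week}) must precede implementation week ",
      "({imp_week}) and both must lie within the {n_weeks}-week grid"
    ))
  }

  starts <- start_date + 7L * (seq_len(n_weeks) - 1L)
  months <- as.integer(format(starts, "%m"))
  years <- unique(as.integer(format(c(starts, starts + 6L), "%Y")))
  easters <- as.Date(vapply(years, easter_sunday, character(1)))
  easter_flag <- vapply(
    starts,
    function(s) any(easters >= s & easters <= s + 6L),
    logical(1)
  )

  structure(
    list(
      weeks = tibble(
        week = seq_len(n_weeks),
        week_start_date = starts,
        christmas = months %in% c(12L, 1L),
        easter = easter_flag
      ),
      n_weeks = n_weeks,
      start_date = start_date,
      announcement_date = announcement_date,
      implementation_date = implementation_date,
      announcement_week = ann_week,
      implementation_week = imp_week
    ),
    class = "levy_calendar"
  )
}

#' @export
print.levy_calendar <- function(x, ...) {
  cat(
    "<levy_calendar> ", x$n_weeks, " weeks from ", format(x$start_date),
    "; announcement week ", x$announcement_week,
    ", implementation week ", x$implementation_week, "\n",
    sep = ""
  )
  invisible(x)
}

# Gregorian Easter Sunday (anonymous Gauss algorithm); returns "YYYY-MM-DD".
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
  sprintf("%04d-%02d-%02d", year, month, day)
}
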