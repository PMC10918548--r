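#' Monthly grid over a study window
#'
#' Builds the 1-based month index grid used throughout the pipeline.  The
#' default grid is January 2016 -- December 2020 (60 months), with the
#' month of a fill defined as the calendar month containing its start
#' date.
#'
#' @param start First month, as `"YYYY-MM"` or a date in that month.
#' @param n_months Number of consecutive months.
#' @return Data frame with columns `month_index`, `year`, `month`.
#' @export
#' @examples
#' head(month_grid())
month_grid <- function(start = "2016-01", n_months = 60) {
  if (inherits(start, "Date")) {
    y <- as.integer(format(start, "%Y"))
    m <- as.integer(format(start, "%m"))
  } else {
    parts <- as.integer(strsplit(as.character(start), "-", fixed = TRUE)[[1]])
    y <- parts[1]
    m <- parts[2]
  }
  if (is.na(y) || is.na(m) || m < 1 || m > 12) stop("invalid grid start: ", start)
  idx <- seq_len(n_months) - 1L
  data.frame(
    month_index = idx + 1L,
    year = y + (m - 1L + idx) %/% 12L,
    month = (m - 1L + idx) %% 12L + 1L
  )
}

#' Month index of calendar dates on a grid
#'
#' @param dates Dates (or strings coercible to dates).
#' @param grid A [month_grid()] data frame.
#' @return Integer month indices (`NA` for dates off the grid).
#' @export
month_index_of <- function(dates, grid) {
  dates <- as.Date(dates)
  key <- as.integer(format(dates, "%Y")) * 12L + as.integer(format(dates, "%m"))
  grid_key <- grid$year * 12L + grid$month
  grid$month_index[match(key, grid_key)]
}

month_start <- function(year, month) as.Date(sprintf("%d-%02d-01", year, month))

month_end <- function(year, month) {
  nxt_y <- year + (month == 12L)
  nxt_m <- month %% 12L + 1L
  month_start(nxt_y, nxt_m) - 1L
}
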