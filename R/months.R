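#' Month-granular time indexing
#'
#' All event timing in a claims extract is month-granular. A month index
#' encodes calendar year and month as the integer `year * 12 + (month - 1)`,
#' so that subtraction gives whole-month differences and comparison is
#' ordinary integer comparison.
#'
#' @param year,month integer vectors; `month` in 1..12.
#' @return integer month index vector.
#' @examples
#' month_index(2020, 5) - month_index(2020, 4)  # 1
#' format_month_index(month_index(2014, 4))     # "2014-04"
#' @export
month_index <- function(year, month) {
  year <- as.integer(year)
  month <- as.integer(month)
  if (anyNA(year) || anyNA(month)) stop("year/month must be non-missing integers")
  if (any(month < 1L | month > 12L)) stop("month must be in 1..12")
  year * 12L + (month - 1L)
}

#' @rdname month_index
#' @param mi integer month index.
#' @export
month_index_year <- function(mi) as.integer(mi) %/% 12L

#' @rdname month_index
#' @export
month_index_month <- function(mi) as.integer(mi) %% 12L + 1L

#' @rdname month_index
#' @export
format_month_index <- function(mi) {
  sprintf("%04d-%02d", month_index_year(mi), month_index_month(mi))
}

#' @rdname month_index
#' @param x character vector of `"YYYY-MM"` strings.
#' @export
parse_month <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{1,2})$", x))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("cannot parse month string(s): ", paste(x[bad], collapse = ", "))
  month_index(vapply(m, function(p) as.integer(p[2]), 1L),
              vapply(m, function(p) as.integer(p[3]), 1L))
}

#' Completed age in years at an event month
#'
#' Age is computed from month-granular dates as completed years,
#' `floor((event - mother_birth) / 12)`; a woman born 1990-04 is 29 at an
#' event in 2020-03 and 30 at one in 2020-04. Used for the 15-49 maternal
#' age eligibility filter of the gold standard.
#'
#' @param mother_birth month index of the mother's own birth.
#' @param event month index of the event (e.g. a child's birth).
#' @return integer vector of completed years.
#' @export
compute_age_years <- function(mother_birth, event) {
  if (any(event < mother_birth)) {
    stop("invalid linkage: event month precedes the mother's own birth month")
  }
  as.integer((event - mother_birth) %/% 12L)
}

## default observation window, half-open [start, end) at month granularity:
## extract submissions run 2014-04 through 2023-01 inclusive
default_window <- function() {
  c(month_index(2014L, 4L), month_index(2023L, 2L))
}
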