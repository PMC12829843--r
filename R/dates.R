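#' Parse verbatim collection-date strings to midpoint dates
#'
#' Type-series metadata report collection dates at mixed precision: an exact
#' day ("12 March 2010", "2010-03-12"), a day range within or across months
#' ("5-7 December 2008", "28 February - 3 March 2008"), a month ("February
#' 2007"), or a bare year ("1925"). Every string implies a closed interval of
#' calendar days; the resolved date is the midpoint of that interval, taking
#' the floor of the arithmetic mean of the first and last day so that an
#' even-length interval resolves to the earlier of the two central days
#' (e.g. "February 2007" resolves to 2007-02-14).
#'
#' Ambiguous all-numeric forms such as "03/04/2010" are rejected rather than
#' guessed. Calendar arithmetic is proleptic Gregorian; leap days are honored.
#'
#' @param raw Character vector of verbatim date strings.
#' @return A tibble with one row per input and columns `raw_text`,
#'   `resolved` (`Date`, the interval midpoint), `precision` (one of
#'   `"day"`, `"day_range"`, `"month"`, `"year"`) and `span_days`
#'   (interval length minus one; 0 for an exact day).
#' @examples
#' parse_date_text(c("5-7 December 2008", "February 2007", "1925"))
#' @export
parse_date_text <- function(raw) {
  out <- parse_date_quietly(raw)
  if (any(!out$ok)) {
    bad <- out$raw_text[!out$ok]
    stop(date_parse_error(bad))
  }
  out$ok <- NULL
  out
}

#' @rdname parse_date_text
#' @description `parse_date_quietly()` is the non-throwing variant used by the
#'   reader: unparseable strings get `ok = FALSE` instead of an error so the
#'   caller can route them to the exclusion log.
#' @export
parse_date_quietly <- function(raw) {
  stopifnot(is.character(raw))
  res <- purrr::map(raw, parse_one_date)
  tibble::tibble(
    raw_text = raw,
    resolved = as.Date(purrr::map_dbl(res, "resolved")),
    precision = purrr::map_chr(res, "precision"),
    span_days = purrr::map_int(res, "span_days"),
    ok = purrr::map_lgl(res, "ok")
  )
}

date_parse_error <- function(bad) {
  structure(
    class = c("taxalag_parse_error", "error", "condition"),
    list(
      message = sprintf(
        "unparseable date string(s): %s",
        paste(sprintf("\"%s\"", utils::head(bad, 5L)), collapse = ", ")
      ),
      call = NULL,
      raw_text = bad
    )
  )
}

.months <- c(
  "january", "february", "march", "april", "may", "june",
  "july", "august", "september", "october", "november", "december"
)

month_index <- function(name) {
  m <- match(tolower(name), .months)
  if (is.na(m)) m <- match(tolower(substr(name, 1L, 3L)), substr(.months, 1L, 3L))
  m
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  as.integer(seq(first, by = "1 month", length.out = 2L)[2L] - first)
}

make_date <- function(year, month, day) {
  if (is.na(month) || month < 1L || month > 12L) return(as.Date(NA))
  if (is.na(day) || day < 1L || day > days_in_month(year, month)) return(as.Date(NA))
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

# Midpoint of a closed day interval: floor of the mean day index.
interval_midpoint <- function(first, last) {
  first + floor(as.numeric(last - first) / 2)
}

failed_parse <- function() {
  list(resolved = NA_real_, precision = NA_character_, span_days = NA_integer_, ok = FALSE)
}

interval_result <- function(first, last, precision) {
  if (is.na(first) || is.na(last) || last < first) return(failed_parse())
  list(
    resolved = as.numeric(interval_midpoint(first, last)),
    precision = precision,
    span_days = as.integer(last - first),
    ok = TRUE
  )
}

# dash variants accepted between range endpoints: hyphen, en dash, em dash
.dash <- "[-\u2013\u2014]"

parse_one_date <- function(txt) {
  if (is.na(txt)) return(failed_parse())
  s <- trimws(gsub("\\s+", " ", txt))
  if (!nzchar(s)) return(failed_parse())
  mon_re <- "([A-Za-z]+)"

  # ISO 8601 exact day
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", s)) {
    d <- as.Date(s, format = "%Y-%m-%d")
    if (is.na(d)) return(failed_parse())
    return(interval_result(d, d, "day"))
  }
  # "12 March 2010"
  m <- regmatches(s, regexec(paste0("^(\\d{1,2}) ", mon_re, " (\\d{4})$"), s))[[1]]
  if (length(m)) {
    d <- make_date(as.integer(m[4]), month_index(m[3]), as.integer(m[2]))
    if (is.na(d)) return(failed_parse())
    return(interval_result(d, d, "day"))
  }
  # "5-7 December 2008" (day range within one month)
  m <- regmatches(s, regexec(
    paste0("^(\\d{1,2}) ?", .dash, " ?(\\d{1,2}) ", mon_re, " (\\d{4})$"), s))[[1]]
  if (length(m)) {
    yr <- as.integer(m[5]); mo <- month_index(m[4])
    first <- make_date(yr, mo, as.integer(m[2]))
    last <- make_date(yr, mo, as.integer(m[3]))
    return(interval_result(first, last, "day_range"))
  }
  # "28 February - 3 March 2008" (range across months, same year)
  m <- regmatches(s, regexec(
    paste0("^(\\d{1,2}) ", mon_re, " ?", .dash, " ?(\\d{1,2}) ", mon_re, " (\\d{4})$"), s))[[1]]
  if (length(m)) {
    yr <- as.integer(m[6])
    first <- make_date(yr, month_index(m[3]), as.integer(m[2]))
    last <- make_date(yr, month_index(m[5]), as.integer(m[4]))
    return(interval_result(first, last, "day_range"))
  }
  # "28 December 2007 - 3 January 2008" (fully qualified endpoints)
  m <- regmatches(s, regexec(
    paste0("^(\\d{1,2}) ", mon_re, " (\\d{4}) ?", .dash, " ?(\\d{1,2}) ", mon_re, " (\\d{4})$"), s))[[1]]
  if (length(m)) {
    first <- make_date(as.integer(m[4]), month_index(m[3]), as.integer(m[2]))
    last <- make_date(as.integer(m[7]), month_index(m[6]), as.integer(m[5]))
    return(interval_result(first, last, "day_range"))
  }
  # "February 2007"
  m <- regmatches(s, regexec(paste0("^", mon_re, " (\\d{4})$"), s))[[1]]
  if (length(m)) {
    yr <- as.integer(m[3]); mo <- month_index(m[2])
    if (is.na(mo)) return(failed_parse())
    first <- make_date(yr, mo, 1L)
    last <- make_date(yr, mo, days_in_month(yr, mo))
    return(interval_result(first, last, "month"))
  }
  # "1925"
  if (grepl("^\\d{4}$", s)) {
    yr <- as.integer(s)
    return(interval_result(make_date(yr, 1L, 1L), make_date(yr, 12L, 31L), "year"))
  }
  failed_parse()
}

#' Canonical serialization of a resolved collection date
#'
#' Writes a `CollectionDate` back to a string in the same dialect it was read
#' from, so that parsing the serialization reproduces the resolved date,
#' precision and span exactly (used by the round-trip tests and the record
#' writer). Day precision serializes as ISO; coarser precisions re-emit the
#' original verbatim text, which already is canonical for its dialect.
#'
#' @param dates A tibble as returned by [parse_date_text()].
#' @return Character vector of date strings.
#' @export
format_date_text <- function(dates) {
  ifelse(dates$precision == "day" & dates$span_days == 0L,
    format(dates$resolved, "%Y-%m-%d"),
    dates$raw_text
  )
}
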