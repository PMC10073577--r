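# Year-month arithmetic at the granularity the claims database exposes.
# A year-month is the string "YYYY-MM"; internally an integer month index
# (year * 12 + month - 1) so spans and gaps are plain integer arithmetic.

ym_index <- function(ym) {
  stopifnot(is.character(ym))
  ok <- is.na(ym) | grepl("^\\d{4}-(0[1-9]|1[0-2])$", ym)
  if (!all(ok)) {
    rlang::abort(sprintf(
      "malformed year-month value(s): %s",
      paste(unique(ym[!ok]), collapse = ", ")
    ))
  }
  yr <- as.integer(substr(ym, 1, 4))
  mo <- as.integer(substr(ym, 6, 7))
  yr * 12L + mo - 1L
}

index_ym <- function(idx) {
  yr <- idx %/% 12L
  mo <- idx %% 12L + 1L
  sprintf("%04d-%02d", yr, mo)
}

date_ym <- function(d) format(d, "%Y-%m")

ym_day <- function(ym, day) {
  if (!length(ym)) return(as.Date(character()))
  as.Date(paste0(ym, "-", day), format = "%Y-%m-%d")
}

#' First day of a year-month
#' @noRd
ym_first_day <- function(ym) ym_day(ym, "01")

#' Last day of a year-month
#' @noRd
ym_last_day <- function(ym) {
  if (!length(ym)) return(as.Date(character()))
  nxt <- index_ym(ym_index(ym) + 1L)
  ym_first_day(nxt) - 1L
}

#' The 15th of a year-month (the database's mid-month fallback day)
#' @noRd
ym_mid_day <- function(ym) ym_day(ym, "15")

ym_shift <- function(ym, months) index_ym(ym_index(ym) + as.integer(months))

# Strict ISO-8601 date parsing: readr and as.Date() silently coerce some
# impossible dates; validate the calendar explicitly and report offenders.
parse_iso_date <- function(x, what = "date") {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  blank <- is.na(x) | x == ""
  todo <- which(!blank)
  if (length(todo)) {
    good <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x[todo])
    parsed <- as.Date(rep(NA_character_, length(todo)), format = "%Y-%m-%d")
    parsed[good] <- as.Date(x[todo][good], format = "%Y-%m-%d")
    # round-trip check catches impossible months/days (e.g. 2015-13-01)
    bad <- good & (is.na(parsed) | format(parsed, "%Y-%m-%d") != x[todo])
    bad <- bad | !good
    if (any(bad)) {
      rows <- todo[bad]
      rlang::abort(sprintf(
        "unparseable %s at row(s) %s: %s",
        what,
        paste(head(rows, 5L), collapse = ", "),
        paste(head(unique(x[rows]), 5L), collapse = ", ")
      ))
    }
    out[todo] <- parsed
  }
  out
}
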