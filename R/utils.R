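#' Normalize free-text terms for matching
#'
#' FAERS drug names and reaction terms are inconsistent free text. All
#' matching in the package is done on upper-cased, whitespace-collapsed
#' strings so that `"alendronate  sodium "` and `"ALENDRONATE SODIUM"`
#' compare equal.
#'
#' @param x character vector.
#' @return character vector of the same length, upper-cased with runs of
#'   whitespace collapsed to single spaces and ends trimmed. `NA` stays `NA`.
#' @export
#' @examples
#' norm_term(c(" alendronate  sodium ", "Oesophagitis"))
norm_term <- function(x) {
  out <- toupper(trimws(gsub("[[:space:]]+", " ", as.character(x))))
  out[!nzchar(out)] <- NA_character_
  out
}

#' Parse FAERS YYYYMMDD dates with explicit precision
#'
#' FAERS date fields may be full dates (`YYYYMMDD`), partial (`YYYYMM` or
#' `YYYY`) or empty. Partial dates are kept, not discarded: each value gets an
#' explicit precision level so downstream stages (deduplication, time-to-onset
#' extraction) can decide usability themselves.
#'
#' @param x character vector of raw date fields.
#' @return data.frame with columns `raw` (input), `precision` (one of
#'   `"day"`, `"month"`, `"year"`, `"missing"`), `key` (zero-padded 8-digit
#'   string used for ordering; missing sorts lowest as `"00000000"`),
#'   `year` (integer or NA) and `date` (`Date`, NA unless day precision).
#' @export
#' @examples
#' parse_faers_date(c("20200131", "201705", "2017", "", "garbage"))
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  digits <- grepl("^[0-9]+$", x)
  n <- nchar(x)
  precision <- rep("missing", length(x))
  precision[digits & n == 8] <- "day"
  precision[digits & n == 6] <- "month"
  precision[digits & n == 4] <- "year"
  # anything else (odd lengths, non-digits) is treated as missing, never coerced
  key <- rep("00000000", length(x))
  key[precision == "day"] <- x[precision == "day"]
  key[precision == "month"] <- paste0(x[precision == "month"], "00")
  key[precision == "year"] <- paste0(x[precision == "year"], "0000")
  year <- rep(NA_integer_, length(x))
  ok <- precision != "missing"
  year[ok] <- as.integer(substr(x[ok], 1L, 4L))
  date <- rep(as.Date(NA), length(x))
  day <- precision == "day"
  if (any(day)) {
    d <- as.Date(x[day], format = "%Y%m%d")
    date[day] <- d
    # impossible calendar dates (e.g. 20200230) degrade to month precision
    bad <- is.na(d)
    if (any(bad)) {
      idx <- which(day)[bad]
      precision[idx] <- "month"
      key[idx] <- paste0(substr(x[idx], 1L, 6L), "00")
    }
  }
  data.frame(raw = x, precision = precision, key = key, year = year,
             date = date, stringsAsFactors = FALSE)
}

#' Convert FAERS age values to years
#'
#' @param age numeric vector (or character coercible to numeric).
#' @param unit character vector of FAERS age unit codes:
#'   `YR` (years), `DEC` (decades), `MON` (months), `WK` (weeks), `DY` (days).
#'   Unknown or missing units yield `NA`.
#' @return numeric vector of ages in years.
#' @export
#' @examples
#' age_in_years(c(65, 7, 18, 26, 730), c("YR", "DEC", "MON", "WK", "DY"))
age_in_years <- function(age, unit) {
  a <- suppressWarnings(as.numeric(age))
  u <- toupper(trimws(as.character(unit)))
  fac <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18, DY = 1 / 365.25)
  f <- fac[u]
  out <- a * as.numeric(f)
  out[is.na(f) | is.na(a)] <- NA_real_
  out
}

# internal: quiet message-based stage log used across the pipeline
log_stage <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}
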