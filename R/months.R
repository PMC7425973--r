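#' Calendar-month utilities
#'
#' Claims panels use calendar months with first-of-month semantics. Internally
#' a month is an integer index, `year * 12 + (month - 1)`, so that ordinary
#' integer arithmetic gives month offsets; externally months are `"YYYY-MM"`
#' strings.
#'
#' @param x For [ym()], a character vector of `"YYYY-MM"` months; for
#'   [ym_format()], an integer month index vector.
#' @return [ym()] returns an integer vector of month indices; [ym_format()]
#'   the corresponding `"YYYY-MM"` strings.
#' @examples
#' ym("2010-04")
#' ym_format(ym("2010-04") + 11) # "2011-03"
#' @export
ym <- function(x) {
  if (is.numeric(x)) {
    return(as.integer(x))
  }
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", x)
  if (!all(ok | is.na(x))) {
    stop("malformed month(s), expected YYYY-MM: ",
         paste(utils::head(x[!ok & !is.na(x)], 5L), collapse = ", "),
         call. = FALSE)
  }
  year <- as.integer(substr(x, 1L, 4L))
  mon  <- as.integer(substr(x, 6L, 7L))
  as.integer(year * 12L + (mon - 1L))
}

#' @rdname ym
#' @export
ym_format <- function(x) {
  x <- as.integer(x)
  sprintf("%04d-%02d", x %/% 12L, x %% 12L + 1L)
}

#' Completed years of age at a given month
#'
#' @param birth_month,at_month Integer month indices (see [ym()]).
#' @return Integer vector of completed years.
#' @export
age_years <- function(birth_month, at_month) {
  as.integer((as.integer(at_month) - as.integer(birth_month)) %/% 12L)
}

#' 5-year age bands used as matching strata
#'
#' Bands run `20-24`, `25-29`, ..., `90-94`, with `95+` open-ended. Ages
#' under 20 return `NA` (such patients are ineligible as cases and are never
#' used as matching strata).
#'
#' @param age Integer vector of completed years.
#' @return Character vector of band labels (`NA` below 20).
#' @export
age_band <- function(age) {
  age <- as.integer(age)
  idx <- pmin((age - 20L) %/% 5L, 15L)
  lab <- ifelse(idx >= 15L, "95+",
                sprintf("%d-%d", 20L + 5L * idx, 24L + 5L * idx))
  lab[age < 20L | is.na(age)] <- NA_character_
  lab
}
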