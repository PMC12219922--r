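#' Fiscal-year helpers
#'
#' The source registries operate on fiscal years: fiscal year \code{t} runs
#' from 1 April of calendar year \code{t} to 31 March of calendar year
#' \code{t + 1}. The default study window, fiscal 2001/02 to 2020/21,
#' therefore spans 2001-04-01 to 2021-03-31.
#'
#' @param date A \code{Date} vector.
#' @return \code{fiscal_year()}: integer vector of fiscal-year start years.
#' @examples
#' fiscal_year(as.Date(c("2001-04-01", "2002-03-31")))  # both 2001
#' @export
fiscal_year <- function(date) {
  lt <- as.POSIXlt(date)
  yr <- lt$year + 1900L
  ifelse(lt$mon + 1L < 4L, yr - 1L, yr)
}

#' @rdname fiscal_year
#' @param year Integer fiscal-year start year(s).
#' @export
fiscal_year_start <- function(year) as.Date(paste0(year, "-04-01"))

#' @rdname fiscal_year
#' @export
fiscal_year_end <- function(year) as.Date(paste0(year + 1L, "-03-31")) # nolint

#' Default study window
#'
#' @return A Date vector of length 2: 2001-04-01 to 2021-03-31 (fiscal
#'   2001/02 through 2020/21).
#' @export
default_study_window <- function() {
  c(fiscal_year_start(2001L), fiscal_year_end(2020L))
}

# Age convention: a person's age at an event is the age attained in the
# fiscal year of the event, i.e. fiscal_year(date) - birth calendar year.
# Used consistently by the generator, case qualification and stratification.
age_at <- function(birth_year, date) {
  fiscal_year(date) - as.integer(birth_year)
}
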