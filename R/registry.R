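#' Disease registry
#'
#' Loads the packaged registry of the 25 chronic conditions used in the
#' multimorbidity analyses: 18 conditions sourced from a provincial chronic
#' disease registry and 7 cancer subtypes from a cancer registry. Each
#' definition carries a sex restriction (breast cancer is female-only,
#' prostate cancer male-only) and a case-definition age cut-off: the minimum
#' age, in years, at which an incident case is counted. Cancers have no
#' cut-off (recorded as \code{NA}, which behaves as "no minimum age").
#'
#' @param path Optional path to a registry CSV with columns
#'   \code{disease}, \code{source}, \code{sex_restriction}, \code{age_cutoff}.
#'   Defaults to the packaged fixture.
#' @return A data frame with one row per disease definition and columns
#'   \code{disease} (character), \code{source}
#'   (\code{"chronic-disease-registry"} or \code{"cancer-registry"}),
#'   \code{sex_restriction} (\code{"none"}, \code{"female-only"} or
#'   \code{"male-only"}) and \code{age_cutoff} (integer years or \code{NA}).
#' @examples
#' reg <- disease_registry()
#' nrow(reg)           # 25
#' table(reg$source)
#' @export
disease_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "disease_registry.csv", package = "morbnet")
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  reg$age_cutoff <- suppressWarnings(as.integer(reg$age_cutoff))
  validate_registry(reg)
  reg
}

#' Validate a disease registry table
#'
#' @param registry A registry data frame as returned by [disease_registry()].
#' @return The registry, invisibly, or an error describing the violation.
#' @export
validate_registry <- function(registry) {
  required <- c("disease", "source", "sex_restriction", "age_cutoff")
  missing <- setdiff(required, names(registry))
  if (length(missing) > 0) {
    stop("registry is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(registry$disease)) {
    stop("registry disease names must be unique")
  }
  bad_sex <- setdiff(registry$sex_restriction, c("none", "female-only", "male-only"))
  if (length(bad_sex) > 0) {
    stop("unknown sex_restriction values: ", paste(bad_sex, collapse = ", "))
  }
  bad_src <- setdiff(registry$source, c("chronic-disease-registry", "cancer-registry"))
  if (length(bad_src) > 0) {
    stop("unknown source values: ", paste(bad_src, collapse = ", "))
  }
  cuts <- registry$age_cutoff[!is.na(registry$age_cutoff)]
  if (any(cuts < 0)) stop("age_cutoff must be non-negative")
  invisible(registry)
}

#' Diseases eligible for one sex
#'
#' Drops the diseases whose sex restriction excludes \code{sex}; with the
#' packaged 25-disease registry this leaves the 24 diseases analysed within
#' each sex-stratified network.
#'
#' @param registry A registry data frame.
#' @param sex \code{"female"} or \code{"male"}.
#' @return Character vector of disease names, alphabetically ordered.
#' @export
sex_disease_list <- function(registry, sex) {
  sex <- match.arg(sex, c("female", "male"))
  excluded <- if (sex == "female") "male-only" else "female-only"
  sort(registry$disease[registry$sex_restriction != excluded])
}

# Effective minimum age for case counting; NA cut-offs (cancers) bind at 0.
effective_cutoff <- function(age_cutoff) {
  ifelse(is.na(age_cutoff), 0L, as.integer(age_cutoff))
}
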