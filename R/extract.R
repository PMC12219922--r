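#' Construct a cohort extract
#'
#' A cohort extract is the person-level input of the pipeline: one row per
#' registration interval in \code{persons} and one row per incident disease
#' case in \code{cases}, together with the study window. This mirrors the
#' delimited extract format produced by administrative data providers (and by
#' [generate_cohort()]).
#'
#' @param persons Data frame with columns \code{person_id}, \code{sex}
#'   (\code{"female"}/\code{"male"}), \code{birth_date} (Date),
#'   \code{reg_start}, \code{reg_end} (Dates; one row per registration
#'   interval) and optionally \code{death_date}.
#' @param cases Data frame with columns \code{person_id}, \code{disease},
#'   \code{incident_date} (Date). One row per person-disease: the incident
#'   date is the first date the person met the disease's case definition.
#' @param study_window Date vector of length 2; defaults to fiscal
#'   2001/02-2020/21.
#' @return An object of class \code{cohort_extract}.
#' @export
cohort_extract <- function(persons, cases, study_window = default_study_window()) {
  persons <- as.data.frame(persons)
  cases <- as.data.frame(cases)
  need_p <- c("person_id", "sex", "birth_date", "reg_start", "reg_end")
  miss <- setdiff(need_p, names(persons))
  if (length(miss) > 0) stop("persons table missing columns: ", paste(miss, collapse = ", "))
  need_c <- c("person_id", "disease", "incident_date")
  miss <- setdiff(need_c, names(cases))
  if (length(miss) > 0) stop("cases table missing columns: ", paste(miss, collapse = ", "))
  if (!"death_date" %in% names(persons)) persons$death_date <- as.Date(NA)
  for (col in c("birth_date", "reg_start", "reg_end", "death_date")) {
    persons[[col]] <- as.Date(persons[[col]])
  }
  cases$incident_date <- as.Date(cases$incident_date)
  study_window <- as.Date(study_window)
  if (length(study_window) != 2 || study_window[2] <= study_window[1]) {
    stop("study_window must be two dates with end after start")
  }

  bad <- which(is.na(persons$reg_start) | is.na(persons$reg_end) |
                 persons$reg_end < persons$reg_start)
  if (length(bad) > 0) {
    stop("malformed registration intervals in persons rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  # intervals must be chronologically ordered and non-overlapping per person
  ord <- order(persons$person_id, persons$reg_start)
  p <- persons[ord, ]
  samep <- duplicated(p$person_id)
  overlap <- samep & c(FALSE, p$reg_start[-1] <= p$reg_end[-nrow(p)])[seq_len(nrow(p))]
  if (nrow(p) > 1) {
    overlap <- samep
    overlap[samep] <- p$reg_start[samep] <= p$reg_end[which(samep) - 1L]
    if (any(overlap)) {
      stop("overlapping registration intervals for person(s): ",
           paste(unique(p$person_id[overlap]), collapse = ", "))
    }
  }

  orphan <- setdiff(cases$person_id, persons$person_id)
  if (length(orphan) > 0) {
    stop("cases reference unknown person_id(s): ",
         paste(utils::head(orphan, 10), collapse = ", "))
  }
  if (anyDuplicated(cases[, c("person_id", "disease")])) {
    stop("duplicate (person_id, disease) rows in cases")
  }

  structure(
    list(persons = persons, cases = cases, study_window = study_window),
    class = "cohort_extract"
  )
}

#' @export
print.cohort_extract <- function(x, ...) {
  cat("<cohort_extract>\n")
  cat("  persons:", length(unique(x$persons$person_id)),
      " (", nrow(x$persons), "registration intervals )\n")
  cat("  incident cases:", nrow(x$cases), "\n")
  cat("  study window:", format(x$study_window[1]), "to",
      format(x$study_window[2]), "\n")
  invisible(x)
}

#' Write / read a cohort extract
#'
#' The on-disk format is a pair of comma-delimited, UTF-8 files with
#' ISO-8601 dates: \code{persons.csv} (one row per registration interval)
#' and \code{cases.csv}, plus \code{window.csv} holding the study window.
#'
#' @param extract A \code{cohort_extract}.
#' @param dir Directory to write to (created if needed) or read from.
#' @return \code{write_cohort_extract()} returns \code{dir} invisibly;
#'   \code{read_cohort_extract()} returns a \code{cohort_extract}.
#' @export
write_cohort_extract <- function(extract, dir) {
  stopifnot(inherits(extract, "cohort_extract"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(extract$persons, file.path(dir, "persons.csv"), row.names = FALSE)
  utils::write.csv(extract$cases, file.path(dir, "cases.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(window_start = extract$study_window[1],
               window_end = extract$study_window[2]),
    file.path(dir, "window.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_cohort_extract
#' @export
read_cohort_extract <- function(dir) {
  persons <- utils::read.csv(file.path(dir, "persons.csv"), stringsAsFactors = FALSE)
  cases <- utils::read.csv(file.path(dir, "cases.csv"), stringsAsFactors = FALSE)
  win <- utils::read.csv(file.path(dir, "window.csv"), stringsAsFactors = FALSE)
  cohort_extract(persons, cases,
                 study_window = as.Date(c(win$window_start[1], win$window_end[1])))
}
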