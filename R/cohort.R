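AGE_GROUPS <- c("20-44", "45-69", "70+")

#' Enumerate the analysis strata
#'
#' All analyses are stratified by sex and age group (20-44, 45-69, 70+ years),
#' giving six strata.
#'
#' @return Data frame with columns \code{sex} and \code{age_group} (6 rows).
#' @export
analysis_strata <- function() {
  expand.grid(sex = c("female", "male"), age_group = AGE_GROUPS,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

age_group_of <- function(age) {
  cut(age, breaks = c(20, 45, 70, Inf), right = FALSE, labels = AGE_GROUPS)
}

# Merge a person's registration intervals, bridging gaps of at most
# gap_tolerance days. Input vectors are sorted by start.
merge_intervals <- function(starts, ends, gap_tolerance = 0) {
  ms <- starts[1]; me <- ends[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (as.numeric(starts[i] - me) - 1 <= gap_tolerance) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Apply the cohort inclusion criteria
#'
#' Retains persons who (a) are over age 20 by the end of their observation,
#' (b) were continuously registered for at least \code{min_years} years in a
#' single registration interval (after bridging gaps of at most
#' \code{gap_tolerance} days) that overlaps the study window, and (c) have two
#' or more qualifying incident diseases, i.e. multimorbidity. A case
#' qualifies when the disease's sex restriction is satisfied and the person's
#' age at the incident date (fiscal-year convention, see [fiscal_year()]) is
#' at or past the disease's case-definition age cut-off; cases failing the
#' cut-off are dropped. Persons meeting (a) and (b) only form the eligible
#' general population used for prevalence denominators.
#'
#' @param extract A [cohort_extract()].
#' @param registry Disease registry; cases naming diseases outside it are an
#'   error.
#' @param min_years Minimum continuous registration, in years (default 10).
#' @param gap_tolerance Days of registration gap to bridge (default 0).
#' @param left_censor Optional Date: incident cases before it are ignored
#'   (a washout boundary); defaults to the window start.
#' @return An object of class \code{mm_inclusion}: person-level table with
#'   eligibility flags, the qualifying cases of eligible persons, and a
#'   participant-flow report.
#' @export
apply_inclusion <- function(extract, registry = disease_registry(),
                            min_years = 10, gap_tolerance = 0,
                            left_censor = NULL) {
  stopifnot(inherits(extract, "cohort_extract"))
  validate_registry(registry)
  win <- extract$study_window
  if (is.null(left_censor)) left_censor <- win[1]
  left_censor <- as.Date(left_censor)

  unknown <- setdiff(extract$cases$disease, registry$disease)
  if (length(unknown) > 0) {
    stop("cases name diseases absent from the registry: ",
         paste(unknown, collapse = ", "))
  }

  p <- extract$persons[order(extract$persons$person_id,
                             extract$persons$reg_start), ]
  ids <- unique(p$person_id)
  first_row <- match(ids, p$person_id)
  sex <- p$sex[first_row]
  birth_year <- as.integer(format(p$birth_date[first_row], "%Y"))
  death <- p$death_date[first_row]

  min_days <- round(365.25 * min_years)
  reg_ok <- logical(length(ids))
  last_end_day <- rep(NA_real_, length(ids))
  pid_idx <- match(p$person_id, ids)
  n_int <- tabulate(pid_idx, nbins = length(ids))
  rs <- as.numeric(p$reg_start)
  re <- as.numeric(p$reg_end)
  w1 <- as.numeric(win[1]); w2 <- as.numeric(win[2])
  # fast path: persons with a single registration interval
  single <- which(n_int == 1L)
  if (length(single) > 0) {
    row1 <- match(ids[single], p$person_id)
    reg_ok[single] <- (re[row1] - rs[row1] + 1) >= min_days &
      rs[row1] <= w2 & re[row1] >= w1
    last_end_day[single] <- re[row1]
  }
  multi <- which(n_int > 1L)
  if (length(multi) > 0) {
    idx_multi <- which(pid_idx %in% multi)
    rows_of <- split(idx_multi, match(pid_idx[idx_multi], multi))
    for (j in seq_along(multi)) {
      i <- multi[j]
      rows <- rows_of[[j]]
      m <- merge_intervals(rs[rows], re[rows], gap_tolerance)
      reg_ok[i] <- any((m$end - m$start + 1) >= min_days &
                         m$start <= w2 & m$end >= w1)
      last_end_day[i] <- max(m$end)
    }
  }
  last_reg_end <- as.Date(last_end_day, origin = "1970-01-01")

  # end of observation: last registered day inside the window, capped by death
  end_obs <- pmin(last_reg_end, win[2])
  end_obs <- pmin(end_obs, ifelse(is.na(death), end_obs, death))
  end_obs <- as.Date(end_obs, origin = "1970-01-01")
  age_end <- age_at(birth_year, end_obs)
  age_ok <- age_end > 20

  # qualifying cases: within window (post washout), sex restriction and age
  # cut-off satisfied at the incident date
  cs <- extract$cases
  cs <- cs[cs$incident_date >= left_censor & cs$incident_date <= win[2], ]
  ridx <- match(cs$disease, registry$disease)
  pidx <- match(cs$person_id, ids)
  cs_age <- age_at(birth_year[pidx], cs$incident_date)
  restriction <- registry$sex_restriction[ridx]
  sex_ok <- restriction == "none" |
    (restriction == "female-only" & sex[pidx] == "female") |
    (restriction == "male-only" & sex[pidx] == "male")
  qual <- sex_ok & cs_age >= effective_cutoff(registry$age_cutoff[ridx])
  qcases <- cs[qual, c("person_id", "disease", "incident_date")]

  n_qual <- tabulate(match(qcases$person_id, ids), nbins = length(ids))
  eligible <- age_ok & reg_ok
  multimorbid <- eligible & n_qual >= 2

  persons <- data.frame(
    person_id = ids, sex = sex, birth_year = birth_year,
    death_date = death, end_obs = end_obs,
    n_qualifying = n_qual, eligible = eligible, multimorbid = multimorbid,
    stringsAsFactors = FALSE
  )
  qcases <- qcases[qcases$person_id %in% ids[eligible], ]
  rownames(qcases) <- NULL

  flow <- data.frame(
    stage = c("persons_in_extract", "over_age_20", "registered_min_years",
              "eligible_population", "multimorbid_cohort"),
    n = c(length(ids), sum(age_ok), sum(reg_ok), sum(eligible),
          sum(multimorbid))
  )

  structure(
    list(persons = persons, qualifying_cases = qcases, flow = flow,
         study_window = win, registry = registry,
         params = list(min_years = min_years, gap_tolerance = gap_tolerance,
                       left_censor = left_censor)),
    class = "mm_inclusion"
  )
}

#' @export
print.mm_inclusion <- function(x, ...) {
  cat("<mm_inclusion>\n")
  print(x$flow, row.names = FALSE)
  invisible(x)
}

#' Assign each person to a sex and age-group stratum
#'
#' Age is measured at a configurable reference date: the end of observation
#' (default: the earlier of study end, death and last registered day), the
#' date of the second qualifying disease (falling back to end of observation
#' for persons with fewer than two qualifying diseases), or the window
#' midpoint. Each person belongs to exactly one stratum per run; persons whose
#' reference age is under 20 are left unstratified and excluded from
#' denominators and networks.
#'
#' @param inclusion An \code{mm_inclusion} from [apply_inclusion()].
#' @param age_reference One of \code{"end-of-observation"},
#'   \code{"at-second-disease"}, \code{"window-midpoint"}.
#' @return An object of class \code{mm_cohort}: the inclusion object with
#'   \code{reference_age} and \code{age_group} columns added to
#'   \code{persons}.
#' @export
assign_stratum <- function(inclusion,
                           age_reference = c("end-of-observation",
                                             "at-second-disease",
                                             "window-midpoint")) {
  stopifnot(inherits(inclusion, "mm_inclusion"))
  age_reference <- match.arg(age_reference)
  persons <- inclusion$persons
  ref_date <- persons$end_obs
  if (age_reference == "window-midpoint") {
    mid <- inclusion$study_window[1] +
      floor(as.numeric(diff(inclusion$study_window)) / 2)
    ref_date <- rep(mid, nrow(persons))
  } else if (age_reference == "at-second-disease") {
    qc <- inclusion$qualifying_cases[order(inclusion$qualifying_cases$person_id,
                                           inclusion$qualifying_cases$incident_date), ]
    second <- tapply(as.integer(qc$incident_date), qc$person_id,
                     function(d) if (length(d) >= 2) sort(d)[2] else NA_integer_)
    hit <- match(persons$person_id, names(second))
    sec <- as.Date(unname(second[hit]), origin = "1970-01-01")
    ref_date <- as.Date(ifelse(is.na(sec), ref_date, sec), origin = "1970-01-01")
  }
  persons$reference_age <- age_at(persons$birth_year, ref_date)
  persons$age_group <- as.character(age_group_of(persons$reference_age))
  dropped <- persons$eligible & persons$reference_age < 20
  if (any(dropped)) {
    message(sum(dropped), " person(s) dropped: reference age under 20")
    persons$eligible[dropped] <- FALSE
    persons$multimorbid[dropped] <- FALSE
  }
  inclusion$persons <- persons
  inclusion$params$age_reference <- age_reference
  class(inclusion) <- c("mm_cohort", "mm_inclusion")
  inclusion
}

#' Population denominator for a stratum under an age cut-off
#'
#' Counts the persons in a stratum whose reference age is at or above the
#' age cut-off. Denominators adhere to the highest age cut-off of the
#' disease(s) being reported, so the count is antitone in the cut-off. The
#' scope is either the eligible general population (default) or the
#' multimorbid cohort.
#'
#' @param cohort An \code{mm_cohort} from [assign_stratum()].
#' @param sex \code{"female"}, \code{"male"}, or \code{NULL} for both sexes
#'   pooled.
#' @param age_group One of \code{"20-44"}, \code{"45-69"}, \code{"70+"}, or
#'   \code{NULL} for all ages pooled.
#' @param age_cutoff Minimum reference age, in years (use the maximum cut-off
#'   over the diseases in the statistic; \code{NA} means no cut-off).
#' @param scope \code{"general-population"} or \code{"multimorbid-cohort"}.
#' @return Integer count (0 with a warning when the stratum is empty).
#' @export
eligible_denominator <- function(cohort, sex, age_group = NULL, age_cutoff = 0,
                                 scope = c("general-population",
                                           "multimorbid-cohort")) {
  stopifnot(inherits(cohort, "mm_cohort"))
  scope <- match.arg(scope)
  p <- cohort$persons
  keep <- if (scope == "general-population") p$eligible else p$multimorbid
  if (!is.null(sex)) keep <- keep & p$sex == sex
  if (!is.null(age_group)) keep <- keep & !is.na(p$age_group) & p$age_group == age_group
  keep <- keep & p$reference_age >= effective_cutoff(age_cutoff)
  n <- sum(keep, na.rm = TRUE)
  if (n == 0) warning("empty denominator for stratum ",
                      if (is.null(sex)) "all" else sex, "/",
                      if (is.null(age_group)) "all" else age_group)
  n
}
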