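#' Assign persons to a disease cluster under strict temporal membership
#'
#' A person is a member of a cluster when they have an incident case of every
#' disease appearing in the cluster's links and, for every member link
#' i to j, their incident date for i strictly precedes their incident date
#' for j. Same-day ties fail the strict inequality (consistent with the
#' same-day exclusion in pair counting). Diseases beyond the cluster are
#' permitted. Temporal consistency is checked link-wise: every directed link's
#' order must hold, but no total order over the cluster's diseases is
#' imposed.
#'
#' @param cohort An \code{mm_cohort}.
#' @param community One community from [cut_link_communities()] (a list with a
#'   \code{links} data frame), or any data frame with \code{from}/\code{to}
#'   columns.
#' @param sex,age_group Stratum selector (passed as in
#'   [count_directed_pairs()]).
#' @return Character vector of member person ids.
#' @export
assign_members <- function(cohort, community, sex = NULL, age_group = NULL) {
  stopifnot(inherits(cohort, "mm_cohort"))
  links <- if (is.data.frame(community)) community else community$links
  diseases <- sort(unique(c(links$from, links$to)))

  p <- cohort$persons
  keep <- p$multimorbid
  if (!is.null(sex)) keep <- keep & p$sex == sex
  if (!is.null(age_group)) keep <- keep & !is.na(p$age_group) & p$age_group == age_group
  ids <- p$person_id[keep]

  cs <- cohort$qualifying_cases
  cs <- cs[cs$person_id %in% ids & cs$disease %in% diseases, ]
  if (nrow(cs) == 0) return(character(0))

  # wide matrix of incident days: persons x cluster diseases
  pid <- factor(cs$person_id)
  did <- match(cs$disease, diseases)
  day <- matrix(NA_real_, nlevels(pid), length(diseases),
                dimnames = list(levels(pid), diseases))
  day[cbind(as.integer(pid), did)] <- as.numeric(cs$incident_date)

  complete <- rowSums(!is.na(day)) == length(diseases)
  ok <- complete
  for (r in seq_len(nrow(links))) {
    ok <- ok & !is.na(day[, links$from[r]]) & !is.na(day[, links$to[r]]) &
      day[, links$from[r]] < day[, links$to[r]]
  }
  rownames(day)[which(ok)]
}

#' Cluster prevalence with small-cell suppression
#'
#' Prevalence of cluster membership as a percentage of the stratified
#' population subgroup, using the eligible-population denominator at the
#' maximum age cut-off over the cluster's diseases. Clusters with fewer than
#' five members are suppressed: no member count or prevalence is reported for
#' them, limiting re-identification risk.
#'
#' @param cohort An \code{mm_cohort}.
#' @param community A community (see [assign_members()]).
#' @param sex,age_group Stratum selector.
#' @param scope Denominator scope, see [eligible_denominator()].
#' @param suppress_below Minimum reportable member count (default 5).
#' @return One-row data frame: \code{community_id}, \code{name},
#'   \code{n_members}, \code{denominator}, \code{prevalence_pct},
#'   \code{suppressed}. For suppressed clusters \code{n_members} and
#'   \code{prevalence_pct} are \code{NA}.
#' @export
cluster_prevalence <- function(cohort, community, sex = NULL, age_group = NULL,
                               scope = c("general-population",
                                         "multimorbid-cohort"),
                               suppress_below = 5) {
  scope <- match.arg(scope)
  links <- if (is.data.frame(community)) community else community$links
  diseases <- unique(c(links$from, links$to))
  cutoffs <- effective_cutoff(
    cohort$registry$age_cutoff[match(diseases, cohort$registry$disease)]
  )
  denom <- suppressWarnings(
    eligible_denominator(cohort, sex = sex, age_group = age_group,
                         age_cutoff = max(cutoffs), scope = scope)
  )
  members <- assign_members(cohort, community, sex = sex, age_group = age_group)
  n <- length(members)
  suppressed <- n < suppress_below || denom == 0
  data.frame(
    community_id = if (is.data.frame(community)) NA_integer_ else community$community_id,
    name = if (is.data.frame(community)) NA_character_ else community$name,
    n_members = if (suppressed) NA_integer_ else n,
    denominator = denom,
    prevalence_pct = if (suppressed) NA_real_ else 100 * n / denom,
    suppressed = suppressed,
    stringsAsFactors = FALSE
  )
}
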