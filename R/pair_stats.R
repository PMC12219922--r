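#' Count directed disease pairs in a stratum
#'
#' For every ordered disease pair (i, j), counts the persons in the stratum's
#' multimorbid cohort whose incident case of i strictly precedes their
#' incident case of j. Persons whose two incident dates fall on the same day
#' contribute to neither direction of that pair, since temporality cannot be
#' established. Marginals \code{n_ix} (i followed by anything),
#' \code{n_xj} (anything followed by j) and the grand total \code{N} are
#' derived from the pair counts.
#'
#' @param cohort An \code{mm_cohort}.
#' @param sex \code{"female"} or \code{"male"}, or \code{NULL} together with
#'   \code{age_group = NULL} to pool the whole multimorbid cohort (then all
#'   registry diseases form the node set).
#' @param age_group Age-group label or \code{NULL} for all ages.
#' @return An object of class \code{pair_count_table}: the ordered-pair count
#'   matrix \code{n} (rows = first disease), marginals and total.
#' @export
count_directed_pairs <- function(cohort, sex = NULL, age_group = NULL) {
  stopifnot(inherits(cohort, "mm_cohort"))
  p <- cohort$persons
  keep <- p$multimorbid
  if (!is.null(sex)) keep <- keep & p$sex == sex
  if (!is.null(age_group)) keep <- keep & !is.na(p$age_group) & p$age_group == age_group
  ids <- p$person_id[keep]

  diseases <- if (is.null(sex)) {
    sort(cohort$registry$disease)
  } else {
    sex_disease_list(cohort$registry, sex)
  }
  nd <- length(diseases)

  cs <- cohort$qualifying_cases
  cs <- cs[cs$person_id %in% ids, ]
  bad <- setdiff(unique(cs$disease), diseases)
  if (length(bad) > 0) {
    stop("cases outside the stratum's disease list: ", paste(bad, collapse = ", "))
  }

  n <- matrix(0L, nd, nd, dimnames = list(diseases, diseases))
  if (nrow(cs) > 0) {
    m <- merge(cs, cs, by = "person_id")
    m <- m[m$disease.x != m$disease.y & m$incident_date.x < m$incident_date.y, ]
    if (nrow(m) > 0) {
      tab <- table(factor(m$disease.x, levels = diseases),
                   factor(m$disease.y, levels = diseases))
      n <- matrix(as.integer(tab), nd, nd, dimnames = list(diseases, diseases))
    }
  }

  structure(
    list(sex = sex, age_group = age_group, diseases = diseases,
         n = n, n_ix = rowSums(n), n_xj = colSums(n), N = sum(n),
         n_persons = length(ids)),
    class = "pair_count_table"
  )
}

#' Directed pair prevalence
#'
#' The percentage of the eligible population with the ordered disease pair:
#' \code{100 * n_pair_persons / denominator}. The denominator must respect
#' the higher age cut-off of the two diseases (see [eligible_denominator()]).
#'
#' @param n_pair_persons Count of persons with i strictly before j.
#' @param denominator Eligible population count.
#' @return Percentage in [0, 100]; \code{NA} when the denominator is 0.
#' @export
pair_prevalence <- function(n_pair_persons, denominator) {
  if (any(n_pair_persons > denominator & denominator > 0)) {
    stop("pair count exceeds its denominator: data integrity error")
  }
  ifelse(denominator > 0, 100 * n_pair_persons / denominator, NA_real_)
}

#' Directed lift (observed/expected ratio)
#'
#' \code{lift_ij = (n_ij * N) / (n_ix * n_xj)}: the observed count of disease
#' i followed by disease j, relative to its expectation if ordered
#' co-occurrence were random given the margins. Lift above 1 means the ordered
#' pair occurs more often than chance predicts.
#'
#' @param n_ij Ordered pair count (i before j).
#' @param n_ix Count of i followed by any disease.
#' @param n_xj Count of any disease followed by j.
#' @param N Total ordered-pair count across the network.
#' @return Numeric lift; \code{NA} when a margin is zero (link absent).
#' @export
lift <- function(n_ij, n_ix, n_xj, N) {
  ifelse(n_ix > 0 & n_xj > 0 & N > 0,
         (n_ij * N) / (n_ix * n_xj), NA_real_)
}

#' Exact binomial direction test
#'
#' Treats the two directional counts of a disease pair as a Bernoulli trial
#' with null probability 1/2 and returns the one-sided exact tail
#' \code{P(X >= n_ij | n = n_ij + n_ji, p = 1/2)} for the direction i to j.
#' Because the test is one-sided, at most one direction of a pair can be
#' significant at any threshold below 0.5.
#'
#' @param n_ij,n_ji Directional counts (vectors allowed).
#' @return One-sided p-value; \code{NA} when both counts are zero.
#' @export
direction_test <- function(n_ij, n_ji) {
  n <- n_ij + n_ji
  ifelse(n > 0,
         stats::pbinom(n_ij - 1, n, 0.5, lower.tail = FALSE),
         NA_real_)
}

#' Build the per-stratum directed link table
#'
#' One row per ordered disease pair with at least one directed case, carrying
#' the counts, pair prevalence (against the eligible-population denominator at
#' the pair's higher age cut-off), lift and the direction-test p-value.
#'
#' @param pair_table A \code{pair_count_table}.
#' @param cohort The \code{mm_cohort} the table was counted from (used for
#'   denominators).
#' @param scope Denominator scope, see [eligible_denominator()].
#' @return Data frame with columns \code{disease_i, disease_j, n_ij, n_ji,
#'   denominator, prevalence_pct, lift, p_value}.
#' @export
pair_links <- function(pair_table, cohort,
                       scope = c("general-population", "multimorbid-cohort")) {
  stopifnot(inherits(pair_table, "pair_count_table"))
  scope <- match.arg(scope)
  ds <- pair_table$diseases
  cutoffs <- effective_cutoff(
    cohort$registry$age_cutoff[match(ds, cohort$registry$disease)]
  )
  names(cutoffs) <- ds

  idx <- which(pair_table$n + t(pair_table$n) > 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  if (nrow(idx) == 0) {
    return(data.frame(disease_i = character(0), disease_j = character(0),
                      n_ij = integer(0), n_ji = integer(0),
                      denominator = integer(0), prevalence_pct = numeric(0),
                      lift = numeric(0), p_value = numeric(0)))
  }
  di <- ds[idx[, 1]]; dj <- ds[idx[, 2]]
  n_ij <- pair_table$n[idx]
  n_ji <- pair_table$n[idx[, c(2, 1), drop = FALSE]]

  pair_cut <- pmax(cutoffs[di], cutoffs[dj])
  denom_for <- vapply(sort(unique(pair_cut)), function(co) {
    suppressWarnings(
      eligible_denominator(cohort, sex = pair_table$sex,
                           age_group = pair_table$age_group,
                           age_cutoff = co, scope = scope)
    )
  }, integer(1))
  names(denom_for) <- as.character(sort(unique(pair_cut)))
  denom <- denom_for[as.character(pair_cut)]

  out <- data.frame(
    disease_i = di, disease_j = dj, n_ij = n_ij, n_ji = n_ji,
    denominator = as.integer(denom),
    prevalence_pct = pair_prevalence(n_ij, denom),
    lift = lift(n_ij, pair_table$n_ix[di], pair_table$n_xj[dj], pair_table$N),
    p_value = direction_test(n_ij, n_ji),
    stringsAsFactors = FALSE
  )
  # pooled tables (sex = NULL) carry no stratum columns; stratified ones do
  if (!is.null(pair_table$age_group)) {
    out <- cbind(age_group = pair_table$age_group, out, stringsAsFactors = FALSE)
  }
  if (!is.null(pair_table$sex)) {
    out <- cbind(sex = pair_table$sex, out, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Filter directed links by direction-exclusive significance and lift
#'
#' A link i to j is retained when its direction test is significant after
#' Bonferroni correction (\code{p_ij < threshold}), the reverse direction is
#' not (\code{p_ji >= threshold}), and \code{lift_ij > 1}. The threshold is
#' \code{alpha / m_tests}; by default \code{m_tests} is the number of
#' direction tests in \code{links} (rows with a p-value), and a fixed
#' \code{p_threshold} can be supplied instead to reproduce an externally
#' stated cut such as 1.70e-5.
#'
#' @param links Link table from [pair_links()] (rows for both directions of a
#'   pair when both were observed), or several strata's tables row-bound.
#' @param alpha Family-wise error level (default 0.05).
#' @param m_tests Number of tests for the Bonferroni correction; default
#'   \code{sum(!is.na(links$p_value))}.
#' @param p_threshold Optional fixed threshold overriding \code{alpha/m}.
#' @return \code{links} with a logical \code{retained} column; the threshold
#'   and test count are attached as attributes \code{p_threshold} and
#'   \code{m_tests}.
#' @export
filter_links <- function(links, alpha = 0.05, m_tests = NULL,
                         p_threshold = NULL) {
  if (is.null(m_tests)) m_tests <- sum(!is.na(links$p_value))
  if (is.null(p_threshold)) {
    if (m_tests <= 0) stop("m_tests must be positive")
    p_threshold <- alpha / m_tests
  }
  key <- paste(links$disease_i, links$disease_j, sep = "\r")
  if (!is.null(links$sex)) key <- paste(links$sex, links$age_group, key)
  rev_key <- paste(links$disease_j, links$disease_i, sep = "\r")
  if (!is.null(links$sex)) rev_key <- paste(links$sex, links$age_group, rev_key)
  p_rev <- links$p_value[match(rev_key, key)]
  p_rev[is.na(p_rev)] <- 1 # unobserved reverse direction: not significant
  links$retained <- !is.na(links$p_value) & links$p_value < p_threshold &
    p_rev >= p_threshold & !is.na(links$lift) & links$lift > 1
  attr(links, "p_threshold") <- p_threshold
  attr(links, "m_tests") <- m_tests
  links
}
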