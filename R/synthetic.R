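#' Default annual base hazards for the packaged registry
#'
#' Annual probabilities of an incident case for a person who is registered,
#' past the disease's age cut-off and not yet incident. Values are plausible
#' population-level incidence magnitudes for each condition (common chronic
#' conditions around 1-3 per 100 person-years, cancers and rarer neurological
#' conditions well below 1 per 100); they are deliberately simple constants,
#' not calibrated to any particular jurisdiction.
#'
#' @return Named numeric vector over the 25 packaged diseases.
#' @export
default_base_hazards <- function() {
  c(
    "Anxiety and mood disorders" = 0.020,
    "Asthma" = 0.008,
    "Chronic kidney disease" = 0.006,
    "Diabetes mellitus" = 0.008,
    "Epilepsy" = 0.0010,
    "Heart failure" = 0.004,
    "Osteoarthritis" = 0.012,
    "Rheumatoid arthritis" = 0.0012,
    "Schizophrenia and delusional disorders" = 0.0015,
    "Gout" = 0.004,
    "Hypertension" = 0.025,
    "Ischemic heart disease" = 0.008,
    "Multiple sclerosis" = 0.0003,
    "Stroke" = 0.004,
    "COPD" = 0.006,
    "Alzheimers and other dementias" = 0.008,
    "Parkinsons disease" = 0.0015,
    "Osteoporosis" = 0.008,
    "Breast cancer" = 0.0015,
    "Colorectal cancer" = 0.0008,
    "Hematological cancer" = 0.0005,
    "Lung cancer" = 0.0008,
    "Melanoma" = 0.0005,
    "Other solid organ cancer" = 0.0015,
    "Prostate cancer" = 0.0015
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The generator draws longitudinal cohorts under a discrete annual hazard
#' model: in each fiscal year of each registration interval, every disease
#' the person is eligible for (sex restriction satisfied, age at or past the
#' cut-off, not yet incident) occurs with probability
#' \code{base_hazard * product of planted multipliers} over planted source
#' diseases that became incident in an \emph{earlier} fiscal year. Multipliers
#' therefore act only after the source disease's incident date, which induces
#' directional (temporally asymmetric) associations that the downstream
#' direction test should detect.
#'
#' @param n_persons Number of persons to simulate.
#' @param study_window Date vector of length 2 (default fiscal 2001/02-2020/21).
#' @param base_hazards Named vector of annual incidence probabilities; names
#'   must be registry diseases. Defaults to [default_base_hazards()].
#' @param planted_effects \code{NULL} or a data frame with columns
#'   \code{source}, \code{target}, \code{multiplier} (multiplier >= 0).
#' @param sex_ratio Fraction female, in [0, 1].
#' @param birth_year_range Integer range of birth years (uniform).
#' @param dropout_rate Annual probability that a registration interval ends;
#'   after a dropout, persons may re-register after a gap of one or more
#'   fiscal years (so extracts contain registration gaps).
#' @param same_day_tie_prob Probability that an incident date is set equal to
#'   another incident date of the same person, emulating the same-day ties
#'   seen in administrative records (about 1.5 percent of pair records).
#' @param death_rate Annual death probability; deaths truncate registration.
#' @param rng_seed Integer seed; the same config and seed give byte-identical
#'   extracts.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_persons,
                             study_window = default_study_window(),
                             base_hazards = default_base_hazards(),
                             planted_effects = NULL,
                             sex_ratio = 0.5,
                             birth_year_range = c(1920L, 1990L),
                             dropout_rate = 0.01,
                             same_day_tie_prob = 0.015,
                             death_rate = 0.005,
                             rng_seed = 1L) {
  study_window <- as.Date(study_window)
  if (length(study_window) != 2 || study_window[2] <= study_window[1]) {
    stop("empty or invalid study window")
  }
  probs <- c(unlist(base_hazards), sex_ratio, dropout_rate,
             same_day_tie_prob, death_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (is.null(names(base_hazards)) || any(names(base_hazards) == "")) {
    stop("base_hazards must be a named vector of diseases")
  }
  if (!is.null(planted_effects)) {
    planted_effects <- as.data.frame(planted_effects)
    need <- c("source", "target", "multiplier")
    if (!all(need %in% names(planted_effects))) {
      stop("planted_effects needs columns source, target, multiplier")
    }
    if (any(planted_effects$multiplier < 0)) stop("multipliers must be >= 0")
    if (any(planted_effects$source == planted_effects$target)) {
      stop("planted effect source and target must differ")
    }
  }
  if (n_persons < 1) stop("n_persons must be positive")
  structure(
    list(
      n_persons = as.integer(n_persons),
      study_window = study_window,
      base_hazards = unlist(base_hazards),
      planted_effects = planted_effects,
      sex_ratio = sex_ratio,
      birth_year_range = as.integer(birth_year_range),
      dropout_rate = dropout_rate,
      same_day_tie_prob = same_day_tie_prob,
      death_rate = death_rate,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates persons (sex, birth year, registration intervals with gaps,
#' optional death date) and incident disease cases under the annual hazard
#' model described in [synthetic_config()]. Incident dates are drawn uniformly
#' within the intersection of the event's fiscal year, the covering
#' registration interval and the study window, so every case date lies inside
#' a registration interval and the window, respects its disease's sex
#' restriction and age cut-off, and occurs at most once per person.
#'
#' @param config A \code{synthetic_config}.
#' @param registry Disease registry data frame; every disease named in
#'   \code{base_hazards} or \code{planted_effects} must appear in it.
#' @return A [cohort_extract()].
#' @examples
#' cfg <- synthetic_config(n_persons = 200, rng_seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort
#' @export
generate_cohort <- function(config, registry = disease_registry()) {
  stopifnot(inherits(config, "synthetic_config"))
  diseases <- names(config$base_hazards)
  unknown <- setdiff(diseases, registry$disease)
  if (length(unknown) > 0) {
    stop("base_hazards names not in registry: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(config$planted_effects)) {
    unknown <- setdiff(
      c(config$planted_effects$source, config$planted_effects$target),
      diseases
    )
    if (length(unknown) > 0) {
      stop("planted_effects diseases not in base_hazards/registry: ",
           paste(unknown, collapse = ", "))
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$rng_seed)

  n <- config$n_persons
  reg <- registry[match(diseases, registry$disease), ]
  cutoff <- effective_cutoff(reg$age_cutoff)
  restriction <- reg$sex_restriction
  nd <- length(diseases)

  y0 <- fiscal_year(config$study_window[1])
  y1 <- fiscal_year(config$study_window[2])
  win_start <- as.integer(config$study_window[1])
  win_end <- as.integer(config$study_window[2])

  person_id <- sprintf("P%07d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
  birth_year <- config$birth_year_range[1] +
    floor(stats::runif(n) * (diff(config$birth_year_range) + 1L))
  birth_date <- as.Date(paste0(birth_year, "-01-01")) +
    floor(stats::runif(n) * 365)

  # registration: everyone enters at window start; a geometric dropout clock
  # may end the first interval, after which persons may re-register following
  # a gap of >= 1 full fiscal year
  drop1_year <- if (config$dropout_rate > 0) {
    y0 + stats::rgeom(n, config$dropout_rate)
  } else rep(Inf, n)
  death_year <- if (config$death_rate > 0) {
    y0 + stats::rgeom(n, config$death_rate)
  } else rep(Inf, n)
  death_date <- rep(as.Date(NA), n)
  died <- is.finite(death_year) & death_year <= y1
  if (any(died)) {
    dy <- death_year[died]
    span <- as.integer(fiscal_year_end(dy)) - as.integer(fiscal_year_start(dy)) + 1L
    death_date[died] <- fiscal_year_start(dy) +
      floor(stats::runif(sum(died)) * span)
  }

  int1_start <- rep(as.integer(config$study_window[1]), n)
  dropped <- is.finite(drop1_year) & drop1_year <= y1
  int1_end <- rep(win_end, n)
  if (any(dropped)) {
    dy <- drop1_year[dropped]
    lo <- pmax(as.integer(fiscal_year_start(dy)), int1_start[dropped])
    hi <- as.integer(fiscal_year_end(dy))
    int1_end[dropped] <- lo + floor(stats::runif(sum(dropped)) * (hi - lo + 1))
  }
  gap_years <- 1L + stats::rgeom(n, 0.5)
  reentry_year <- ifelse(dropped, drop1_year + 1L + gap_years, Inf)
  has_int2 <- is.finite(reentry_year) & reentry_year <= y1
  int2_start <- rep(NA_integer_, n)
  int2_end <- rep(NA_integer_, n)
  int2_start[has_int2] <- as.integer(fiscal_year_start(reentry_year[has_int2]))
  int2_end[has_int2] <- win_end

  # deaths truncate registration
  dd <- as.integer(death_date)
  cut1 <- !is.na(dd) & dd < int1_end
  int1_end[cut1] <- dd[cut1]
  drop2 <- has_int2 & !is.na(dd) & dd < int2_start
  has_int2[drop2] <- FALSE
  cut2 <- has_int2 & !is.na(dd) & dd < int2_end
  int2_end[cut2] <- dd[cut2]
  gone1 <- int1_end < int1_start
  int1_end[gone1] <- int1_start[gone1] # degenerate one-day interval at entry

  female <- sex == "female"
  sex_ok <- matrix(TRUE, n, nd)
  for (d in seq_len(nd)) {
    if (restriction[d] == "female-only") sex_ok[, d] <- female
    if (restriction[d] == "male-only") sex_ok[, d] <- !female
  }

  eff_src <- integer(0); eff_tgt <- integer(0); eff_mult <- numeric(0)
  if (!is.null(config$planted_effects)) {
    eff_src <- match(config$planted_effects$source, diseases)
    eff_tgt <- match(config$planted_effects$target, diseases)
    eff_mult <- config$planted_effects$multiplier
  }

  inc_year <- matrix(NA_integer_, n, nd)
  inc_day <- matrix(NA_integer_, n, nd)

  for (y in y0:y1) {
    fy_lo <- as.integer(fiscal_year_start(y))
    fy_hi <- as.integer(fiscal_year_end(y))
    in1 <- int1_start <= fy_hi & int1_end >= fy_lo
    in2 <- has_int2 & !is.na(int2_start) & int2_start <= fy_hi & int2_end >= fy_lo
    at_risk <- in1 | in2
    if (!any(at_risk)) next
    lo <- pmax(fy_lo, ifelse(in1, int1_start, int2_start), win_start)
    hi <- pmin(fy_hi, ifelse(in1, int1_end, int2_end), win_end)
    age <- y - birth_year
    for (d in seq_len(nd)) {
      p0 <- config$base_hazards[[d]]
      if (p0 <= 0) next
      elig <- at_risk & sex_ok[, d] & age >= cutoff[d] & is.na(inc_year[, d])
      idx <- which(elig)
      if (length(idx) == 0) next
      p <- rep(p0, length(idx))
      hits <- which(eff_tgt == d)
      for (h in hits) {
        src_year <- inc_year[idx, eff_src[h]]
        boosted <- !is.na(src_year) & src_year < y
        p[boosted] <- p[boosted] * eff_mult[h]
      }
      p <- pmin(p, 1)
      ev <- idx[stats::runif(length(idx)) < p]
      if (length(ev) == 0) next
      inc_year[ev, d] <- y
      inc_day[ev, d] <- lo[ev] +
        floor(stats::runif(length(ev)) * (hi[ev] - lo[ev] + 1L))
    }
  }

  has_case <- which(!is.na(inc_day))
  cases <- data.frame(
    person = ((has_case - 1L) %% n) + 1L,
    disease_idx = ((has_case - 1L) %/% n) + 1L
  )
  cases$incident_day <- inc_day[has_case]
  cases <- cases[order(cases$person, cases$incident_day, cases$disease_idx), ]

  # same-day ties: copy another case date of the same person, but only when
  # the copied date still satisfies the case's age cut-off
  if (config$same_day_tie_prob > 0 && nrow(cases) > 1) {
    grp_size <- tabulate(cases$person, nbins = n)[cases$person]
    pos <- stats::ave(seq_len(nrow(cases)), cases$person, FUN = seq_along)
    candidate <- which(grp_size >= 2 & pos > 1 &
                         stats::runif(nrow(cases)) < config$same_day_tie_prob)
    if (length(candidate) > 0) {
      grp_start <- match(cases$person, cases$person)
      for (r in candidate) {
        others <- seq.int(grp_start[r], grp_start[r] + grp_size[r] - 1L)
        others <- setdiff(others, r)
        d <- cases$disease_idx[r]
        ok <- others[
          fiscal_year(as.Date(cases$incident_day[others],
                              origin = "1970-01-01")) -
            birth_year[cases$person[r]] >= cutoff[d]
        ]
        if (length(ok) == 0) next
        pick <- ok[sample.int(length(ok), 1L)]
        cases$incident_day[r] <- cases$incident_day[pick]
      }
    }
  }

  persons_rows <- data.frame(
    person_id = person_id,
    sex = sex,
    birth_date = birth_date,
    reg_start = as.Date(int1_start, origin = "1970-01-01"),
    reg_end = as.Date(int1_end, origin = "1970-01-01"),
    death_date = death_date,
    stringsAsFactors = FALSE
  )
  if (any(has_int2)) {
    persons_rows <- rbind(persons_rows, data.frame(
      person_id = person_id[has_int2],
      sex = sex[has_int2],
      birth_date = birth_date[has_int2],
      reg_start = as.Date(int2_start[has_int2], origin = "1970-01-01"),
      reg_end = as.Date(int2_end[has_int2], origin = "1970-01-01"),
      death_date = death_date[has_int2],
      stringsAsFactors = FALSE
    ))
  }
  persons_rows <- persons_rows[order(persons_rows$person_id, persons_rows$reg_start), ]
  rownames(persons_rows) <- NULL

  cases_df <- data.frame(
    person_id = person_id[cases$person],
    disease = diseases[cases$disease_idx],
    incident_date = as.Date(cases$incident_day, origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  rownames(cases_df) <- NULL

  cohort_extract(persons_rows, cases_df, config$study_window)
}
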