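# Independent brute-force oracles and toy-fixture builders. These deliberately
# avoid the package's own code paths (no merges, no hclust, no igraph) so that
# agreement is evidence, not tautology.

toy_person <- function(id, sex = "female", birth = "1950-06-15",
                       reg_start = "2001-04-01", reg_end = "2021-03-31",
                       death = NA) {
  data.frame(person_id = id, sex = sex, birth_date = as.Date(birth),
             reg_start = as.Date(reg_start), reg_end = as.Date(reg_end),
             death_date = as.Date(death), stringsAsFactors = FALSE)
}

toy_case <- function(id, disease, date) {
  data.frame(person_id = id, disease = disease, incident_date = as.Date(date),
             stringsAsFactors = FALSE)
}

# A random handcrafted extract: <= n_max persons, random diseases and dates,
# some deliberate same-day ties. Everyone passes registration/age inclusion so
# the pair-counting comparison exercises dates, not eligibility.
random_toy_extract <- function(seed, n_max = 50) {
  set.seed(seed)
  reg <- disease_registry()
  n <- sample(5:n_max, 1)
  persons <- do.call(rbind, lapply(seq_len(n), function(i) {
    toy_person(sprintf("T%03d", i),
               sex = sample(c("female", "male"), 1),
               birth = sprintf("19%02d-03-01", sample(20:70, 1)))
  }))
  win <- default_study_window()
  days <- as.integer(win[2] - win[1])
  cases <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    ds <- sample(reg$disease, k)
    dates <- win[1] + sample.int(days, k, replace = TRUE)
    # inject occasional same-day ties
    if (k >= 2 && stats::runif(1) < 0.4) dates[2] <- dates[1]
    toy_case(sprintf("T%03d", i), ds, dates)
  }))
  if (is.null(cases)) cases <- toy_case(character(0), character(0), as.Date(character(0)))
  cohort_extract(persons, cases, win)
}

# per-person enumeration of directed pair counts
oracle_pair_counts <- function(cohort, sex = NULL, age_group = NULL) {
  p <- cohort$persons
  keep <- p$multimorbid
  if (!is.null(sex)) keep <- keep & p$sex == sex
  if (!is.null(age_group)) keep <- keep & !is.na(p$age_group) & p$age_group == age_group
  ids <- p$person_id[keep]
  diseases <- if (is.null(sex)) sort(cohort$registry$disease) else
    sex_disease_list(cohort$registry, sex)
  n <- matrix(0L, length(diseases), length(diseases),
              dimnames = list(diseases, diseases))
  for (id in ids) {
    cc <- cohort$qualifying_cases[cohort$qualifying_cases$person_id == id, ]
    if (nrow(cc) < 2) next
    for (a in seq_len(nrow(cc))) {
      for (b in seq_len(nrow(cc))) {
        if (a == b) next
        if (cc$incident_date[a] < cc$incident_date[b]) {
          n[cc$disease[a], cc$disease[b]] <- n[cc$disease[a], cc$disease[b]] + 1L
        }
      }
    }
  }
  n
}

# textbook Ward agglomeration (Lance-Williams recurrence on squared
# dissimilarities, heights on the distance scale), returning the cophenetic
# distance matrix it implies
oracle_ward_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d <- D
  diag(d) <- Inf
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  while (length(active) > 1) {
    sub <- d[active, active, drop = FALSE]
    pos <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[min(pos)]; j <- active[max(pos)]
    h <- d[i, j]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- h
    }
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dk2 <- ((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 - nk * h^2) /
        (ni + nj + nk)
      d[i, k] <- d[k, i] <- sqrt(dk2)
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  coph
}

# direct summation of the dissimilarity-based Calinski-Harabasz decomposition
oracle_ch <- function(labels, D) {
  D <- as.matrix(D)
  n <- length(labels)
  k <- length(unique(labels))
  total <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) total <- total + D[a, b]^2
  total <- total / n
  W <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2) next
    s <- 0
    for (a in idx) for (b in idx) if (a < b) s <- s + D[a, b]^2
    W <- W + s / length(idx)
  }
  (max(total - W, 0) / (k - 1)) / (W / (n - k))
}

# exhaustive per-person check of cluster membership constraints
oracle_members <- function(cohort, links, sex = NULL, age_group = NULL) {
  p <- cohort$persons
  keep <- p$multimorbid
  if (!is.null(sex)) keep <- keep & p$sex == sex
  if (!is.null(age_group)) keep <- keep & !is.na(p$age_group) & p$age_group == age_group
  diseases <- unique(c(links$from, links$to))
  out <- character(0)
  for (id in p$person_id[keep]) {
    cc <- cohort$qualifying_cases[cohort$qualifying_cases$person_id == id, ]
    if (!all(diseases %in% cc$disease)) next
    ok <- TRUE
    for (r in seq_len(nrow(links))) {
      di <- cc$incident_date[cc$disease == links$from[r]]
      dj <- cc$incident_date[cc$disease == links$to[r]]
      if (!(di < dj)) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, id)
  }
  out
}

# registry in which the directional null truly holds: identical hazards and
# age cut-offs, no sex restriction, so disease incident times are exchangeable
# and P(i before j) = 1/2 for every pair
null_registry <- function(n_diseases = 25) {
  data.frame(
    disease = sprintf("D%02d", seq_len(n_diseases)),
    source = "chronic-disease-registry",
    sex_restriction = "none",
    age_cutoff = 1L,
    stringsAsFactors = FALSE
  )
}

null_hazards <- function(n_diseases = 25, hazard = 0.01) {
  stats::setNames(rep(hazard, n_diseases), sprintf("D%02d", seq_len(n_diseases)))
}

toy_cohort_from_extract <- function(extract, registry = disease_registry()) {
  assign_stratum(apply_inclusion(extract, registry))
}

# planted two-community link set sharing a bridge node; unit lift weights
planted_two_hub_links <- function() {
  data.frame(
    disease_i = c("H1", "H1", "H1", "H1", "H2", "H2", "H2", "Bridge"),
    disease_j = c("A", "B", "C", "Bridge", "D", "E", "F", "H2"),
    prevalence_pct = 1, lift = 1, p_value = 1e-8, n_ij = 10L,
    retained = TRUE, stringsAsFactors = FALSE
  )
}
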