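test_that("strict ordering and same-day exclusion drive directed pair counts", {
  persons <- rbind(toy_person("P1"), toy_person("P2"))
  cases <- rbind(
    toy_case("P1", c("Asthma", "Gout"), c("2003-01-10", "2003-04-20")),
    toy_case("P2", c("Asthma", "Gout"), c("2004-06-06", "2004-06-06"))  # tie
  )
  coh <- toy_cohort_from_extract(cohort_extract(persons, cases))
  pt <- count_directed_pairs(coh, "female", "70+")
  expect_equal(pt$n["Asthma", "Gout"], 1L)   # P1 only; P2's tie counts nowhere
  expect_equal(pt$n["Gout", "Asthma"], 0L)
  expect_equal(pt$N, 1L)
})

test_that("pair count marginal identities hold and match brute force on random toys", {
  for (seed in c(101, 202)) {
    coh <- toy_cohort_from_extract(random_toy_extract(seed))
    for (sex in c("female", "male")) {
      pt <- count_directed_pairs(coh, sex, "70+")
      expect_equal(pt$n_ix, rowSums(pt$n))
      expect_equal(pt$n_xj, colSums(pt$n))
      expect_equal(pt$N, sum(pt$n))
      expect_equal(pt$n, oracle_pair_counts(coh, sex, "70+"))
    }
  }
})

test_that("pair prevalence is a percentage of the binding denominator", {
  expect_equal(pair_prevalence(0, 5000), 0)
  expect_equal(pair_prevalence(327, 10000), 3.27)
  expect_true(is.na(pair_prevalence(0, 0)))
  expect_error(pair_prevalence(11, 10), "integrity")
})

test_that("the denominator uses the higher age cut-off of the pair", {
  # stratum 45-69 holds reference ages 48 and 62; Osteoporosis (50+) paired
  # with Asthma (1+) must use the 50+ denominator (1), Gout (20+) the full bin
  persons <- do.call(rbind, mapply(
    function(id, by) toy_person(id, birth = by),
    c("P1", "P2", "P3"), c("1972-02-01", "1958-02-01", "1948-02-01"),
    SIMPLIFY = FALSE
  ))  # reference ages 48, 62, 72
  cases <- rbind(
    toy_case("P1", c("Asthma", "Gout"), c("2005-05-01", "2007-01-01")),
    toy_case("P2", c("Asthma", "Osteoporosis"), c("2005-05-01", "2012-01-01")),
    toy_case("P3", c("Asthma", "Gout"), c("2005-05-01", "2007-01-01"))
  )
  coh <- toy_cohort_from_extract(cohort_extract(persons, cases))
  pt <- count_directed_pairs(coh, "female", "45-69")
  links <- pair_links(pt, coh)
  ost <- links[links$disease_i == "Asthma" & links$disease_j == "Osteoporosis", ]
  gout <- links[links$disease_i == "Asthma" & links$disease_j == "Gout", ]
  expect_equal(ost$denominator, 1L)   # only the 62-year-old passes the 50+ cut
  expect_equal(gout$denominator, 2L)  # both stratum members pass the 20+ cut
  expect_lt(ost$denominator, gout$denominator)
})

test_that("lift evaluates the observed/expected ratio and its edge cases", {
  expect_equal(lift(10, 20, 25, 100), 2.0)
  expect_equal(lift(20 * 25 / 100, 20, 25, 100), 1.0)  # exact independence
  expect_true(is.na(lift(0, 0, 25, 100)))              # zero margin: absent
  # scale consistency: multiplying all counts by k leaves lift unchanged
  for (k in c(2, 10, 37)) {
    expect_equal(lift(7 * k, 30 * k, 12 * k, 200 * k), lift(7, 30, 12, 200))
  }
})

test_that("direction test is the exact one-sided binomial tail at p = 1/2", {
  expect_equal(direction_test(10, 0), 0.5^10)
  expect_equal(direction_test(5, 5), 638 / 1024)  # P(X >= 5 | n = 10)
  expect_true(is.na(direction_test(0, 0)))
  # one-sided tails overlap at the observed value: p_ij + p_ji >= 1 always
  for (n in 1:30) {
    for (a in 0:n) {
      expect_gte(direction_test(a, n - a) + direction_test(n - a, a), 1)
    }
  }
})

test_that("link filtering requires exclusive significance and lift above 1", {
  mk <- function(i, j, nij, nji, lift_ij) {
    data.frame(disease_i = i, disease_j = j, n_ij = nij, n_ji = nji,
               denominator = 1000, prevalence_pct = 0.1, lift = lift_ij,
               p_value = direction_test(nij, nji), stringsAsFactors = FALSE)
  }
  links <- rbind(
    mk("A", "B", 30, 0, 1.5), mk("B", "A", 0, 30, 0.9),   # A->B retained
    mk("C", "D", 30, 0, 0.8), mk("D", "C", 0, 30, 1.4),   # lift <= 1: dropped
    mk("E", "F", 6, 4, 1.9), mk("F", "E", 4, 6, 1.9),     # not significant
    mk("G", "H", 25, 25, 2.0), mk("H", "G", 25, 25, 2.0), # symmetric
    mk("I", "J", 40, 1, 3.0), mk("J", "I", 1, 40, 3.0),   # I->J retained
    mk("K", "L", 2, 0, 5.0), mk("L", "K", 0, 2, 5.0)      # too few cases
  )
  out <- filter_links(links, alpha = 0.05)
  retained <- out[out$retained, c("disease_i", "disease_j")]
  expect_equal(nrow(retained), 2)
  expect_setequal(paste(retained$disease_i, retained$disease_j),
                  c("A B", "I J"))
  # at most one direction of a pair can ever be retained
  expect_false(any(paste(retained$disease_j, retained$disease_i) %in%
                     paste(retained$disease_i, retained$disease_j)))
  # fixed threshold override is honoured
  out2 <- filter_links(links, p_threshold = 1.7e-5)
  expect_equal(attr(out2, "p_threshold"), 1.7e-5)
  expect_error(filter_links(links, m_tests = 0), "positive")
})

test_that("one-direction-only retention holds across random link tables", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    a <- rbinom(1, n, 0.5)
    links <- rbind(
      data.frame(disease_i = "X", disease_j = "Y", n_ij = a, n_ji = n - a,
                 denominator = 100, prevalence_pct = 1,
                 lift = runif(1, 0.5, 3), p_value = direction_test(a, n - a)),
      data.frame(disease_i = "Y", disease_j = "X", n_ij = n - a, n_ji = a,
                 denominator = 100, prevalence_pct = 1,
                 lift = runif(1, 0.5, 3), p_value = direction_test(n - a, a))
    )
    out <- filter_links(links, alpha = 0.05, m_tests = 10)
    expect_lte(sum(out$retained), 1)
  }
})
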