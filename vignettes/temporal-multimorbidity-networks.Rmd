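---
title: "Temporal multimorbidity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal multimorbidity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbnet)
```

## The problem

Multimorbidity — two or more co-occurring chronic conditions in one person —
is usually summarised pairwise and without regard to which disease came
first. `morbnet` implements a temporal, network-based summary of
multimorbidity for person-level disease-incidence extracts of the kind held
by administrative health registries: one row per person (sex, birth date,
registration intervals, optional death date) and one row per incident
disease case (the first date the person met a disease's case definition).

The pipeline has five analytic stages, each exposed as ordinary functions
and orchestrated by `run_pipeline()`:

1. **Cohort construction** (`apply_inclusion()`, `assign_stratum()`) —
   inclusion criteria, sex and age-group stratification, and
   disease-specific eligibility denominators.
2. **Directed pair statistics** (`count_directed_pairs()`, `lift()`,
   `direction_test()`, `filter_links()`) — ordered co-occurrence counts,
   pair prevalence, lift, and a direction-exclusive significance filter.
3. **Network construction** (`build_network()`, `node_metrics()`,
   `network_density()`) — per-stratum weighted directed graphs and their
   descriptive metrics.
4. **Link communities** (`link_similarity()`, `cluster_links()`,
   `cut_link_communities()`) — overlapping disease clusters found by
   clustering network *links*.
5. **Cluster prevalence** (`assign_members()`, `cluster_prevalence()`) —
   strict temporal cluster membership with small-cell suppression.

A synthetic cohort generator (`generate_cohort()`) stands in for restricted
administrative data, with plantable directed associations so that every
stage can be tested against known ground truth.

## Cohort model

The disease registry fixture (`disease_registry()`) lists 25 chronic
conditions: 18 from a chronic-disease registry, each with a case-definition
age cut-off in {1, 10, 20, 35, 40, 50} years, and 7 cancer subtypes with no
cut-off. Breast cancer is female-only and prostate cancer male-only, so each
sex-stratified analysis covers 24 diseases.

Persons are included when they (a) are over age 20 by the end of their
observation, (b) hold a single continuous registration interval of at least
10 years overlapping the study window (fiscal 2001/02–2020/21 by default),
and (c) have at least two qualifying incident diseases. A case qualifies
when its sex restriction holds and the person's age at the incident date
reaches the disease's cut-off; cases failing the cut-off are dropped rather
than deferred, since a registry incident date below the counting age is by
definition not a countable case.

**Age convention.** All ages use the fiscal-year convention: a person's age
at an event is `fiscal_year(event) - birth_year`. The generator, case
qualification and stratification share this single definition so that
eligibility is checkable row by row.

**Age-group reference date.** The age at which a person is binned into
20–44 / 45–69 / 70+ is measured, by default, at the end of observation (the
earliest of study end, death, and last registered day). This is
deterministic and uses the fullest history, but it is a genuine design
choice: a person observed for 20 years was younger for most of them.
Alternatives (`at-second-disease`, `window-midpoint`) are provided as
explicit configuration rather than a silent guess. Each person occupies
exactly one stratum per run; letting persons age through successive bins is
deliberately not modelled.

**Registration gaps.** "Continuously registered" is read as a single
gap-free interval; a configurable `gap_tolerance` (default 0 days) can
bridge short administrative gaps, which registries commonly do.

**Denominators.** Prevalence denominators count the eligible general
population of the stratum whose reference age reaches the maximum age
cut-off over the diseases in the statistic (`eligible_denominator()`); the
scope can be switched to the multimorbid cohort where that reading of
"population" is wanted. Denominators are antitone in the cut-off.

## Directed pair statistics

For each ordered disease pair (i, j), `n_ij` counts persons whose incident
case of i strictly precedes that of j. Same-day pairs (about 1.5% of pair
records in administrative data; injected at that rate by the generator)
contribute to neither direction because temporality cannot be established.
Margins are derived from the pair counts: `n_ix = Σ_j n_ij`,
`n_xj = Σ_i n_ij`, `N = Σ_ij n_ij`.

Two link weights are computed:

* **Pair prevalence** — `100 · n_ij / denominator`, the percentage of the
  eligible population with the ordered pair.
* **Lift** — `(n_ij · N) / (n_ix · n_xj)`, the observed ordered count over
  its expectation under random co-occurrence given the margins. Lift above
  1 means the ordered pair occurs more than chance predicts.

**Direction test.** The two directional counts of a pair are treated as a
Bernoulli trial with null probability 1/2, and the one-sided exact binomial
tail `P(X ≥ n_ij | n_ij + n_ji, ½)` is reported for each direction. The
one-sided reading is the only one under which "i→j significant and j→i not"
is coherent: a two-sided test would give both directions identical
p-values. Because one-sided tails overlap at the observed value
(`p_ij + p_ji ≥ 1`), at most one direction of a pair can ever pass any
threshold below 0.5.

**Filter.** A link is retained when `p_ij < α/m`, `p_ji ≥ α/m`, and
`lift_ij > 1`. Both the prevalence-weighted and the lift-weighted networks
are built from the same retained link set. The Bonferroni denominator `m`
defaults to the number of direction tests actually performed in the run;
a fixed `p_threshold` can be supplied instead when an externally stated
cut (for example 1.70e-5) must be reproduced exactly — the test count
behind such an external constant is generally not reconstructible, so it is
surfaced as configuration, not guessed.

**A subtlety of lift worth knowing.** Even under perfect independence of
diseases, the *population* value of this lift is not exactly 1: self-pairs
(i, i) are structurally excluded from the margins, which inflates the ratio
by roughly `D/(D−1)` for `D` diseases (about 1.04 at D = 25). With
heterogeneous onset-age profiles the deviation can differ by pair. The
package computes the statistic exactly as defined; tests of the generator's
null behaviour check concentration around `D/(D−1)`, not around 1.

## Network metrics

Retained links form a weighted directed graph per stratum over the full
24-disease node set (isolated nodes included), held as an `igraph` object.
Density is `|links| / (n(n−1))`; node in/out degree count incoming/outgoing
links, and in/out strength sum their weights. With prevalence weights the
ceiling is 100% on each of the 23 possible links, i.e. a maximal node
strength of 2300. Single-disease prevalence is attached to nodes for
reporting and uses the same denominator scope as pair prevalence. Exports:
GraphML per network, delimited edge and node-metric tables, ranked top-k
link reports (weight descending, ties broken alphabetically).

## Link communities

Clusters are communities of *links*, which lets one disease belong to
several clusters and does not force every disease into a cluster.

* **Similarity.** Two links sharing a node are compared by the Tanimoto
  coefficient `a·b / (|a|² + |b|² − a·b)` of the inclusive-neighborhood
  weight vectors of their non-shared endpoints; the self-entry of a node's
  vector is the mean of its incident link weights. Links sharing no node
  have similarity 0. Direction is ignored when building neighborhoods —
  after the direction-exclusive filter at most one direction of a pair
  survives, so collapsing to an undirected weighted graph is a relabelling,
  not an aggregation — but direction is preserved in community membership,
  naming and the temporal membership rule. Similarity is computed on the
  lift network's weights by default (clusters are detected from lift
  networks); any `disease_network` can be passed.
* **Clustering.** Ward's minimum-variance linkage (`hclust`,
  `"ward.D2"`) on distance `1 − similarity`, with links in deterministic
  alphabetical order.
* **Cut.** All cluster counts k from 2 to n−1 are scored with a
  dissimilarity-based Calinski–Harabasz index: within-cluster dispersion
  `W = Σ_c (Σ squared within-cluster distances)/|c|`, between dispersion
  `B = total − W`, `CH = (B/(k−1))/((W/(n−k)))`. No Euclidean embedding of
  links exists, so the average-pairwise-squared-distance decomposition is
  used; it reduces to the classical variance-ratio criterion in Euclidean
  settings. Perfectly tight, separated partitions score `+Inf` and win;
  CH ties resolve toward fewer clusters; if every score is undefined (all
  links mutually similar at distance 0) all links form one community.
* **Naming.** Communities of fewer than 2 links are discarded. Each
  community is named by its central disease — the one appearing in the most
  member links — or by the tied diseases joined alphabetically when no
  unique center exists.

## Cluster prevalence

A person belongs to a cluster only if they have *all* of its diseases and
every member link's temporal order holds strictly (link-wise checking: the
community's links need not define a total order, and the weakest faithful
reading of "in the specified temporal sequence" is to require exactly the
orders the links assert). Same-day ties fail the strict inequality.
Additional diseases beyond the cluster are permitted. Membership is
therefore monotone: adding a link can only remove members. Prevalence is
reported against the stratum denominator at the maximum cut-off over
cluster diseases, and any cluster with fewer than five members is
suppressed — no count or prevalence is emitted, and written pipeline tables
additionally mask any person count below five.

## The synthetic generator

`generate_cohort()` draws cohorts under a discrete annual hazard model: in
each fiscal year of each registration interval, each disease the person is
eligible for occurs with probability `base_hazard × Π multipliers`, where a
planted multiplier (source → target) applies only when the source disease
became incident in an *earlier* fiscal year. This is the simplest mechanism
that produces temporal ordering with plantable, directionally asymmetric
associations. Incident dates are uniform within the intersection of the
event year, the covering registration interval and the study window.
Same-day ties are injected explicitly (default probability 0.015, matching
the rate reported for administrative pair records) so the exclusion rule is
exercised; a tie is only planted when the copied date still satisfies the
case's age cut-off. Registration begins at the window start with a
geometric annual dropout (default 0.01) and possible re-registration after
a gap of at least one fiscal year; deaths (annual rate 0.005) truncate
registration. Defaults — birth years uniform on 1920–1990, sex ratio 0.5,
per-disease hazards of plausible population magnitude (0.0003–0.025 per
year) — were chosen once as realistic study conditions and are not
calibrated to any jurisdiction's prevalence.

**What the generator does and does not emulate.** It reproduces the
structural features the pipeline depends on: age cut-offs, sex-specific
diseases, registration gaps, same-day ties, and directional associations of
controllable strength. It does not model health-care-access bias, secular
trends, seasonality, disease-specific mortality, or correlated risk
profiles. Passing tests therefore demonstrate that the statistics recover
planted structure under clean sampling assumptions — not that real
administrative extracts satisfy those assumptions.

**The directional null.** Calibration of the direction test uses a
homogeneous registry (equal hazards, equal cut-offs, no sex restriction):
only then are the two incident times of a pair exchangeable and
`P(i before j) = 1/2` exactly. With the heterogeneous default registry,
differing age cut-offs and hazards create *true* temporal asymmetries
(for example, a disease counted only from age 50 tends to follow one
counted from age 1) — rejections there are correct detections, not false
positives, so the default registry is not a null. Under the homogeneous
null with 20 seeds of 20,000 persons, the pipeline retains on average
fewer links per run than the Bonferroni error budget (α = 0.05).

## Numerical choices and problem sizes

* Exact binomial tails come from `pbinom`; no normal approximation.
* Lift is undefined (link absent) when a margin is zero; prevalence is
  absent when its denominator is zero.
* Ward heights follow the distance-scale Lance–Williams recurrence
  (`ward.D2`); tests verify agreement with an independent textbook
  implementation to 1e-10, and the Calinski–Harabasz scorer against direct
  dispersion summation at the same tolerance.
* Test and demonstration problem sizes — 50,000 persons for planted-effect
  recovery, 20 seeds of 20,000 persons for null calibration, 100,000
  persons for the null-lift concentration check — were chosen so that
  binomial sampling error is small relative to the effects being measured
  while a full run of the suite remains a desk-scale computation.

## Known limitations

* The annual-hazard generator cannot produce within-year ordering signal:
  multipliers act from the following fiscal year.
* One stratum per person: analyses of persons aging across bins require a
  different design.
* Bonferroni control is the only multiplicity correction offered; FDR and
  permutation approaches are out of scope, as are time-window-restricted
  trajectories, undirected burden measures, and node-based community
  detection.
* Cluster membership is binary; probabilistic or partial membership is not
  modelled. A person may belong to several clusters simultaneously, which
  overlapping communities imply.
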