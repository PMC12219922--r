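mk_net <- function(from, to, w = 1) {
  links <- data.frame(disease_i = from, disease_j = to, prevalence_pct = w,
                      lift = w, p_value = 1e-8, n_ij = 10L, retained = TRUE,
                      stringsAsFactors = FALSE)
  build_network(links, sort(unique(c(from, to))), weight_kind = "lift")
}

test_that("Tanimoto similarity obeys its boundary rules", {
  # in a unit-weight triangle the non-shared endpoints of any two links have
  # identical inclusive neighborhoods, so their similarity is exactly 1
  net <- mk_net(c("A", "B", "X"), c("B", "X", "A"))
  S <- link_similarity(net)
  expect_true(all(abs(S - 1) < 1e-12))
  expect_true(all(diag(S) == 1))
  expect_equal(S, t(S))
  # links sharing no node have similarity 0
  net2 <- mk_net(c("A", "C"), c("B", "D"))
  S2 <- link_similarity(net2)
  expect_equal(S2["A -> B", "C -> D"], 0)
})

test_that("Tanimoto on a 4-node unit-weight toy equals hand arithmetic", {
  # path A -> B -> C plus B -> D; compare links (A->B, B->C): shared node B,
  # endpoints A and C. a_A = (A: 1, B: 1); a_C = (B: 1, C: 1).
  # dot = 1 (entry B); |a_A|^2 = |a_C|^2 = 2; sim = 1 / (2 + 2 - 1) = 1/3
  net <- mk_net(c("A", "B", "B"), c("B", "C", "D"))
  S <- link_similarity(net)
  expect_equal(S["A -> B", "B -> C"], 1 / 3)
  # links (B->C, B->D): endpoints C and D, both leaves of B: identical vectors
  # except the self entries. a_C = (B:1, C:1), a_D = (B:1, D:1): dot 1 -> 1/3
  expect_equal(S["B -> C", "B -> D"], 1 / 3)
})

test_that("Ward dendrogram matches a textbook Lance-Williams implementation", {
  set.seed(42)
  for (rep in 1:5) {
    L <- sample(6:12, 1)
    nodes <- LETTERS[1:(L + 1)]
    # random connected link set: a chain plus extra random links
    from <- nodes[seq_len(L)]
    to <- nodes[seq_len(L) + 1]
    w <- runif(L, 0.5, 3)
    net <- mk_net(from, to, w)
    cl <- cluster_links(net)
    D <- 1 - cl$similarity
    coph_pkg <- as.matrix(stats::cophenetic(cl$hclust))
    coph_oracle <- oracle_ward_cophenetic(D)
    dimnames(coph_oracle) <- dimnames(coph_pkg)
    expect_equal(coph_pkg, coph_oracle, tolerance = 1e-10)
  }
})

test_that("block-structured similarities merge within blocks first", {
  # two disjoint unit triangles: within-block similarity 1, between-block 0
  net <- mk_net(c("A", "B", "X", "C", "D", "Y"),
                c("B", "X", "A", "D", "Y", "C"))
  cl <- cluster_links(net)
  S <- cl$similarity
  expect_equal(S["A -> B", "B -> X"], 1)
  expect_equal(S["A -> B", "C -> D"], 0)
  h <- cl$hclust$height
  expect_equal(h[1:4], rep(0, 4))      # within-block merges all at height 0
  expect_gt(h[5], 0)                   # the two blocks join last
  # the CH cut recovers the two planted blocks exactly
  comms <- cut_link_communities(cl)
  expect_length(comms$communities, 2)
  sizes <- vapply(comms$communities, function(com) nrow(com$links), integer(1))
  expect_equal(sort(sizes), c(3L, 3L))
})

test_that("a single pair of links yields one merge and one community", {
  net <- mk_net(c("A", "A"), c("B", "C"))
  cl <- cluster_links(net)
  expect_equal(length(cl$hclust$height), 1)
  comms <- cut_link_communities(cl)
  expect_length(comms$communities, 1)
  expect_equal(comms$communities[[1]]$name, "A")
})

test_that("Calinski-Harabasz agrees with direct dispersion summation", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    pts <- matrix(rnorm(n * 2), n)
    D <- as.matrix(dist(pts))
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(calinski_harabasz(labels, D), oracle_ch(labels, D),
                 tolerance = 1e-10)
  }
})

test_that("CH edge cases: perfect separation diverges, equidistance is flat", {
  # two tight clusters: all within-distances 0, between 1
  D <- matrix(1, 6, 6); D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0; diag(D) <- 0
  expect_equal(calinski_harabasz(rep(1:2, each = 3), D), Inf)
  expect_true(is.na(calinski_harabasz(rep(1, 6), D)))      # k < 2
  expect_true(is.na(calinski_harabasz(1:6, D)))            # k = n
  # equidistant points: CH is constant in k, so the earliest k is selected
  n <- 6
  Deq <- matrix(2, n, n); diag(Deq) <- 0
  scores <- vapply(2:(n - 1), function(k) {
    calinski_harabasz(c(rep(1, n - k + 1), seq_len(k - 1) + 1), Deq)
  }, numeric(1))
  expect_true(all(abs(scores - scores[1]) < 1e-12))
})

test_that("communities are named by the most frequent disease, ties joined", {
  # common predecessor
  net1 <- mk_net(c("A", "A"), c("B", "C"))
  c1 <- cut_link_communities(cluster_links(net1))
  expect_equal(c1$communities[[1]]$name, "A")
  # common consequence
  net2 <- mk_net(c("A", "C"), c("B", "B"))
  c2 <- cut_link_communities(cluster_links(net2))
  expect_equal(c2$communities[[1]]$name, "B")
  # 3-cycle: every disease in 2 links, tie-named alphabetically
  net3 <- mk_net(c("A", "B", "C"), c("B", "C", "A"))
  c3 <- cut_link_communities(cluster_links(net3))
  expect_length(c3$communities, 1)
  expect_equal(c3$communities[[1]]$central_diseases, c("A", "B", "C"))
  expect_equal(c3$communities[[1]]$name, "A / B / C")
})

test_that("planted two-hub communities are recovered with a shared bridge node", {
  links <- planted_two_hub_links()
  net <- build_network(links, sort(unique(c(links$disease_i, links$disease_j))),
                       weight_kind = "lift")
  comms <- cut_link_communities(cluster_links(net))
  expect_length(comms$communities, 2)
  membership <- lapply(comms$communities, function(com) {
    sort(unique(c(com$links$from, com$links$to)))
  })
  expect_true(any(vapply(membership, function(m) setequal(m, c("A", "B", "C", "H1", "Bridge")), logical(1))))
  expect_true(any(vapply(membership, function(m) setequal(m, c("D", "E", "F", "H2", "Bridge")), logical(1))))
  # the bridge node belongs to both communities (multiple membership)
  expect_true(all(vapply(membership, function(m) "Bridge" %in% m, logical(1))))
  expect_setequal(vapply(comms$communities, function(com) com$name, character(1)),
                  c("H1", "H2"))
})

test_that("similarity matrices stay valid and communities keep at least 2 links", {
  set.seed(99)
  for (rep in 1:10) {
    n_nodes <- sample(4:8, 1)
    nodes <- LETTERS[1:n_nodes]
    pairs <- expand.grid(i = nodes, j = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$i < pairs$j, ]
    m <- sample(2:min(10, nrow(pairs)), 1)
    pick <- pairs[sample.int(nrow(pairs), m), ]
    net <- mk_net(pick$i, pick$j, w = runif(m, 0.5, 4))
    S <- link_similarity(net)
    expect_true(all(S >= -1e-12 & S <= 1 + 1e-12))
    expect_equal(S, t(S))
    expect_true(all(diag(S) == 1))
    comms <- cut_link_communities(cluster_links(net))
    for (com in comms$communities) expect_gte(nrow(com$links), 2)
    # community links are a subset of network links
    all_mem <- unlist(lapply(comms$communities, function(com) {
      paste(com$links$from, com$links$to)
    }))
    expect_true(all(all_mem %in% paste(pick$i, pick$j)))
  }
})
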