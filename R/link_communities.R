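#' Tanimoto similarity between network links
#'
#' Link-community detection clusters the links of the network rather than its
#' nodes. The similarity of two links sharing a node is the Tanimoto
#' coefficient of the inclusive-neighborhood weight vectors of their
#' non-shared endpoints: direction is ignored for neighborhood construction,
#' each endpoint's vector holds its link weight to every neighbor, and the
#' self-entry is the mean of the endpoint's link weights. Links sharing no
#' node have similarity 0; identical links have similarity 1.
#'
#' @param network A \code{disease_network}.
#' @return A symmetric similarity matrix over the network's links, with unit
#'   diagonal and entries in [0, 1]; row/column names are \code{"i -> j"}
#'   link labels. \code{NULL} when the network has no links.
#' @export
link_similarity <- function(network) {
  e <- igraph::as_data_frame(network$graph, what = "edges")
  if (nrow(e) == 0) return(NULL)
  e <- e[order(e$from, e$to), ]
  nodes <- network$diseases
  nn <- length(nodes)

  # underlying undirected weighted graph (at most one direction survives the
  # filter, so collapsing directions is a relabeling, not an aggregation)
  W <- matrix(0, nn, nn, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(e))) {
    W[e$from[r], e$to[r]] <- W[e$from[r], e$to[r]] + e$weight[r]
    W[e$to[r], e$from[r]] <- W[e$to[r], e$from[r]] + e$weight[r]
  }
  # inclusive neighborhood vectors: self-entry = mean incident link weight
  A <- W
  deg <- rowSums(W > 0)
  diag(A) <- ifelse(deg > 0, rowSums(W) / pmax(deg, 1), 0)

  L <- nrow(e)
  labels <- paste(e$from, "->", e$to)
  S <- diag(1, L)
  dimnames(S) <- list(labels, labels)
  dots <- A %*% t(A)
  norms <- diag(dots)
  for (a in seq_len(L - 1)) {
    ea <- c(e$from[a], e$to[a])
    for (b in (a + 1):L) {
      eb <- c(e$from[b], e$to[b])
      shared <- intersect(ea, eb)
      if (length(shared) == 0) next
      if (length(shared) == 2) { S[a, b] <- S[b, a] <- 1; next }
      u <- setdiff(ea, shared)
      v <- setdiff(eb, shared)
      d <- dots[u, v]
      S[a, b] <- S[b, a] <- d / (norms[u] + norms[v] - d)
    }
  }
  S
}

#' Hierarchical clustering of network links
#'
#' Builds an agglomerative dendrogram over the network's links using Ward's
#' minimum-variance linkage on the distance \code{1 - similarity}. The result
#' is deterministic for a fixed link ordering (links are sorted
#' alphabetically).
#'
#' @param network A \code{disease_network} with at least 2 links.
#' @return A list with elements \code{hclust} (the dendrogram),
#'   \code{similarity} (the link similarity matrix) and \code{links}
#'   (the edge table in dendrogram order), or \code{NULL} with a message when
#'   the network has fewer than 2 links.
#' @export
cluster_links <- function(network) {
  S <- link_similarity(network)
  if (is.null(S) || nrow(S) < 2) {
    message("fewer than 2 links: no link clustering performed")
    return(NULL)
  }
  D <- stats::as.dist(1 - S)
  hc <- stats::hclust(D, method = "ward.D2")
  e <- igraph::as_data_frame(network$graph, what = "edges")
  e <- e[order(e$from, e$to), ]
  rownames(e) <- NULL
  list(hclust = hc, similarity = S, links = e)
}

#' Calinski-Harabasz index for a partition of dissimilarities
#'
#' Dissimilarity-based Calinski-Harabasz score:
#' \code{CH = (B / (k - 1)) / (W / (n - k))} where the within-cluster
#' dispersion \code{W} sums, over clusters, the within-cluster squared
#' distances divided by the cluster size, and \code{B} is the total
#' squared-distance dispersion minus \code{W}. In a Euclidean embedding this
#' reduces to the classical variance-ratio criterion.
#'
#' @param labels Integer/character cluster labels, one per object.
#' @param distances Square distance matrix (or \code{dist}) over the objects.
#' @return The CH score; \code{Inf} when clusters are perfectly tight
#'   (\code{W = 0}) but separated; \code{NA} when \code{k < 2} or
#'   \code{k >= n}.
#' @export
calinski_harabasz <- function(labels, distances) {
  d <- as.matrix(distances)
  n <- length(labels)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  d2 <- d^2
  total <- sum(d2[upper.tri(d2)]) / n
  W <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      W <- W + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  B <- total - W
  if (W <= .Machine$double.eps * total) {
    return(if (B > 0) Inf else NA_real_)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Cut the link dendrogram and name the communities
#'
#' Scans all cluster counts \code{k} from 2 to \code{n - 1}, scores each
#' partition with [calinski_harabasz()] on the \code{1 - similarity}
#' distances, and keeps the partition with the maximal score (ties broken
#' toward fewer clusters). Communities with fewer than 2 links are discarded,
#' so not every link (or disease) need belong to a community, and a disease
#' may appear in several. Each community is named after its central
#' disease(s): the disease(s) appearing in the most member links, joined
#' alphabetically when tied.
#'
#' @param clustering Result of [cluster_links()].
#' @param min_links Minimum links per community (default 2).
#' @return An object of class \code{link_communities}: a list of communities
#'   (each with \code{community_id}, \code{links}, \code{disease_frequency},
#'   \code{central_diseases}, \code{name}) plus the chosen \code{k} and the
#'   CH score profile. An empty list when no clustering was possible.
#' @export
cut_link_communities <- function(clustering, min_links = 2) {
  if (is.null(clustering)) {
    return(structure(list(communities = list(), k = 0L, ch = numeric(0)),
                     class = "link_communities"))
  }
  e <- clustering$links
  n <- nrow(e)
  D <- 1 - clustering$similarity
  if (n == 2) {
    labels <- rep(1L, 2)
    ch <- numeric(0)
  } else {
    ks <- 2:(n - 1)
    ch <- vapply(ks, function(k) {
      calinski_harabasz(stats::cutree(clustering$hclust, k = k), D)
    }, numeric(1))
    names(ch) <- ks
    if (all(is.na(ch))) {
      # degenerate geometry (e.g. all links mutually similar): one community
      labels <- rep(1L, n)
    } else {
      best <- ks[which.max(ch)] # first maximum: ties resolve to fewer clusters
      labels <- stats::cutree(clustering$hclust, k = best)
    }
  }

  communities <- list()
  cid <- 0L
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < min_links) next
    cid <- cid + 1L
    mem <- e[idx, , drop = FALSE]
    freq <- table(c(mem$from, mem$to))
    central <- sort(names(freq)[freq == max(freq)])
    communities[[cid]] <- list(
      community_id = cid,
      links = mem,
      disease_frequency = freq,
      central_diseases = central,
      name = paste(central, collapse = " / ")
    )
  }
  structure(
    list(communities = communities,
         k = if (length(communities)) length(unique(labels)) else 0L,
         ch = ch),
    class = "link_communities"
  )
}

#' @export
print.link_communities <- function(x, ...) {
  cat("<link_communities>", length(x$communities), "communities\n")
  for (com in x$communities) {
    cat(sprintf("  #%d %s (%d links)\n", com$community_id, com$name,
                nrow(com$links)))
  }
  invisible(x)
}

#' Community table
#'
#' Flattens a \code{link_communities} object to one row per community, the
#' machine-readable twin of a published cluster table.
#'
#' @param communities A \code{link_communities} object.
#' @return Data frame with \code{community_id}, \code{name},
#'   \code{central_diseases}, \code{n_links}, \code{member_links}.
#' @export
community_table <- function(communities) {
  rows <- lapply(communities$communities, function(com) {
    data.frame(
      community_id = com$community_id,
      name = com$name,
      central_diseases = paste(com$central_diseases, collapse = "; "),
      n_links = nrow(com$links),
      member_links = paste(paste(com$links$from, "->", com$links$to),
                           collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0) {
    return(data.frame(community_id = integer(0), name = character(0),
                      central_diseases = character(0), n_links = integer(0),
                      member_links = character(0)))
  }
  do.call(rbind, rows)
}
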