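#' Build a directed disease network from retained links
#'
#' Assembles the retained directed links of one stratum into a weighted
#' directed graph over the stratum's full disease node set (alphabetical
#' ordering; with the packaged registry, 24 nodes per sex-stratified network).
#' Link weights are the pair prevalence (percent) or the lift, and p-value,
#' lift and counts travel as edge attributes. Single-disease prevalence can be
#' attached to nodes for reporting.
#'
#' @param links Filtered link table ([filter_links()]); only rows with
#'   \code{retained == TRUE} become edges.
#' @param diseases Character vector of node names (the stratum's disease
#'   list).
#' @param weight_kind \code{"prevalence"} or \code{"lift"}.
#' @param sex,age_group Optional stratum labels carried as metadata.
#' @param node_prevalence Optional named numeric vector of single-disease
#'   prevalence (percent) per node.
#' @return An object of class \code{disease_network} wrapping an
#'   \pkg{igraph} graph.
#' @export
build_network <- function(links, diseases,
                          weight_kind = c("prevalence", "lift"),
                          sex = NULL, age_group = NULL,
                          node_prevalence = NULL) {
  weight_kind <- match.arg(weight_kind)
  diseases <- sort(diseases)
  edges <- if ("retained" %in% names(links)) {
    links[which(links$retained), , drop = FALSE]
  } else {
    links
  }
  if (nrow(edges) > 0) {
    if (anyDuplicated(edges[, c("disease_i", "disease_j")])) {
      stop("duplicate directed link in input")
    }
    if (any(edges$disease_i == edges$disease_j)) stop("self-links not allowed")
    missing <- setdiff(c(edges$disease_i, edges$disease_j), diseases)
    if (length(missing) > 0) {
      stop("links reference diseases outside the node set: ",
           paste(missing, collapse = ", "))
    }
  }
  w <- if (weight_kind == "prevalence") edges$prevalence_pct else edges$lift
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$disease_i, to = edges$disease_j,
               weight = if (nrow(edges)) w else numeric(0),
               lift = edges$lift, prevalence_pct = edges$prevalence_pct,
               p_value = edges$p_value, n_ij = edges$n_ij,
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = diseases
  )
  if (!is.null(node_prevalence)) {
    igraph::V(g)$prevalence_pct <- unname(node_prevalence[diseases])
  }
  structure(
    list(graph = g, weight_kind = weight_kind, sex = sex,
         age_group = age_group, diseases = diseases),
    class = "disease_network"
  )
}

#' @export
print.disease_network <- function(x, ...) {
  cat("<disease_network>", x$weight_kind, "weights")
  if (!is.null(x$sex)) cat(";", x$sex, if (!is.null(x$age_group)) x$age_group)
  cat("\n  nodes:", length(x$diseases),
      " links:", igraph::ecount(x$graph),
      " density:", signif(network_density(x), 3), "\n")
  invisible(x)
}

#' Network density
#'
#' The number of directed links present over the \code{n * (n - 1)} possible
#' directed links among \code{n} nodes.
#'
#' @param network A \code{disease_network}.
#' @return Density in [0, 1].
#' @export
network_density <- function(network) {
  n <- length(network$diseases)
  if (n < 2) stop("density undefined for fewer than 2 nodes")
  igraph::ecount(network$graph) / (n * (n - 1))
}

#' Node degree and strength metrics
#'
#' In/out degree count a disease's incoming/outgoing retained links (the
#' number of diseases observed before/after it); in/out strength sum the
#' corresponding link weights. With prevalence weights the maximum attainable
#' strength is 100 percent on each of the \code{n - 1} possible links (2300
#' for a 24-node network).
#'
#' @param network A \code{disease_network}.
#' @return Data frame with one row per disease: \code{in_degree},
#'   \code{out_degree}, \code{in_strength}, \code{out_strength}.
#' @export
node_metrics <- function(network) {
  g <- network$graph
  data.frame(
    disease = network$diseases,
    in_degree = as.integer(igraph::degree(g, mode = "in")),
    out_degree = as.integer(igraph::degree(g, mode = "out")),
    in_strength = as.numeric(igraph::strength(g, mode = "in")),
    out_strength = as.numeric(igraph::strength(g, mode = "out")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Top-k links by weight
#'
#' Ranks links by weight (descending), breaking ties alphabetically by the
#' (first, second) disease pair.
#'
#' @param network A \code{disease_network}.
#' @param k Number of links to report.
#' @return Data frame of the top links with their weights.
#' @export
top_links <- function(network, k = 10) {
  e <- igraph::as_data_frame(network$graph, what = "edges")
  if (nrow(e) == 0) return(e)
  e <- e[order(-e$weight, e$from, e$to), ]
  utils::head(e, k)
}

#' Export a network as GraphML
#'
#' @param network A \code{disease_network}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
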