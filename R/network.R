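#' Jaccard similarity of binary enrichment profiles
#'
#' Pairwise `J(x, y) = |x AND y| / |x OR y|` over the rows of a binary
#' matrix (one profile per compound). Two all-zero profiles are defined as
#' identical (`J = 1`, reported with a message). The result is symmetric
#' with a unit diagonal.
#'
#' @param profiles binary matrix, compounds in rows, features (e.g. anchor
#'   partnerships) in columns; or a named list of equal-length binary
#'   vectors.
#' @return symmetric numeric matrix of Jaccard indices in \[0, 1\].
#' @examples
#' jaccard_matrix(rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0)))  # J(a,b) = 1/3
#' @export
jaccard_matrix <- function(profiles) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    if (length(unique(lengths(profiles))) != 1) {
      stop_bad_arg("profiles must have equal length")
    }
    profiles <- do.call(rbind, profiles)
  }
  m <- profiles
  if (!all(m %in% c(0, 1))) stop_bad_arg("profiles must be binary (0/1)")
  storage.mode(m) <- "numeric"
  inter <- tcrossprod(m)
  rs <- rowSums(m)
  uni <- outer(rs, rs, "+") - inter
  J <- inter / uni
  if (any(uni == 0)) {
    inform(sprintf("%d pair(s) of all-zero profiles; their Jaccard index is defined as 1",
                   sum(uni == 0 & upper.tri(uni, diag = TRUE))))
    J[uni == 0] <- 1
  }
  dimnames(J) <- list(rownames(m), rownames(m))
  J
}

#' Build the functional drug network from a similarity matrix
#'
#' Undirected weighted graph: an edge joins compounds i and j when their
#' similarity strictly exceeds `edge_threshold`, with the similarity as
#' weight. Isolated compounds are retained as nodes. The threshold used is
#' stored as a graph attribute.
#'
#' @param sim symmetric similarity matrix (e.g. [jaccard_matrix()]).
#' @param edge_threshold minimum similarity for an edge, in \[0, 1)
#'   (default 0: any positive similarity).
#' @return an [igraph::igraph] graph.
#' @export
build_network <- function(sim, edge_threshold = 0) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) stop_bad_arg("`sim` must be square")
  if (max(abs(sim - t(sim))) > 1e-12) stop_bad_arg("`sim` must be symmetric")
  if (edge_threshold < 0 || edge_threshold >= 1) {
    stop_bad_arg("`edge_threshold` must be in [0, 1)")
  }
  adj <- sim
  adj[adj <= edge_threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::set_graph_attr(g, "edge_threshold", edge_threshold)
  g
}

#' Greedy-modularity community detection
#'
#' Clauset-Newman-Moore agglomerative modularity maximization on the edge
#' weights (via [igraph::cluster_fast_greedy()]). Vertices are ordered
#' lexicographically by name before clustering, making the agglomeration
#' tie-break deterministic; community ids are then relabelled by decreasing
#' community size, ties by smallest member id, so outputs are diff-stable.
#' An edgeless network yields one singleton community per node.
#'
#' @param net a [build_network()] graph.
#' @param weighted use edge weights (default `TRUE`).
#' @return tibble: `compound_id`, `community` (integer id, 1 = largest).
#' @export
detect_communities <- function(net, weighted = TRUE) {
  nm <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  net <- igraph::permute(net, match(nm, sort(nm)))
  nm <- sort(nm)
  if (igraph::ecount(net) == 0) {
    inform("edgeless network: every node is its own community")
    memb <- seq_along(nm)
  } else {
    cl <- igraph::cluster_fast_greedy(
      net, weights = if (weighted) igraph::E(net)$weight else NA)
    # cut the agglomeration explicitly at the modularity maximum (the first
    # maximum on ties, i.e. the finer partition)
    memb <- igraph::cut_at(cl, steps = which.max(cl$modularity) - 1)
  }
  # stable relabelling: by decreasing size, ties by smallest member id
  sizes <- table(memb)
  first_member <- vapply(names(sizes), function(k) min(nm[memb == as.integer(k)]),
                         character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  tibble(compound_id = nm,
         community = as.integer(relabel[as.character(memb)]))
}

#' Node centrality metrics
#'
#' Degree (edge count) and normalized betweenness (fraction of all-pairs
#' shortest paths through the node). Shortest paths use unweighted hops by
#' default; `weighted = TRUE` uses distance `1/weight` so strong similarity
#' means short distance.
#'
#' @param net a [build_network()] graph.
#' @param weighted use `1/weight` shortest-path distances.
#' @return tibble: `compound_id`, `degree`, `betweenness`.
#' @export
network_centrality <- function(net, weighted = FALSE) {
  nm <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  wts <- if (weighted) 1 / igraph::E(net)$weight else NA
  btw <- igraph::betweenness(net, weights = wts, normalized = TRUE)
  tibble(compound_id = nm,
         degree = as.integer(igraph::degree(net)),
         betweenness = unname(btw))
}

#' Annotate network nodes with mechanism-of-action labels
#'
#' Sets a `moa` vertex attribute from a compound-to-label table; compounds
#' without a label become `"unannotated"`, labels for unknown compounds are
#' ignored with a warning.
#'
#' @param net a [build_network()] graph.
#' @param moa data frame with columns `compound_id`, `moa`, or `NULL`.
#' @return the annotated graph.
#' @export
annotate_moa <- function(net, moa = NULL) {
  nm <- igraph::V(net)$name
  labels <- setNames(rep("unannotated", length(nm)), nm)
  if (!is.null(moa) && nrow(moa)) {
    unknown <- setdiff(moa$compound_id, nm)
    if (length(unknown)) {
      warn(sprintf("MoA labels for %d compound(s) not in the network were ignored",
                   length(unknown)))
    }
    known <- moa[moa$compound_id %in% nm, ]
    labels[known$compound_id] <- known$moa
  }
  igraph::set_vertex_attr(net, "moa", value = unname(labels[nm]))
}

#' Mechanism-of-action abundance per community
#'
#' @param net an [annotate_moa()]-annotated graph.
#' @param communities a [detect_communities()] tibble.
#' @return tibble of counts per (community, moa).
#' @export
moa_abundance <- function(net, communities) {
  moa <- igraph::vertex_attr(net, "moa") %||% rep("unannotated", igraph::vcount(net))
  tibble(compound_id = igraph::V(net)$name, moa = moa) |>
    dplyr::inner_join(communities, by = "compound_id") |>
    dplyr::count(.data$community, .data$moa, name = "n") |>
    arrange(.data$community, desc(.data$n))
}

#' Plot the functional drug network
#'
#' Deterministic Fruchterman-Reingold layout (seeded), nodes coloured by
#' community and sized by degree.
#'
#' @param net a [build_network()] graph.
#' @param communities optional [detect_communities()] tibble.
#' @param seed layout seed.
#' @return a ggplot.
#' @export
plot_drug_network <- function(net, communities = NULL, seed = 1) {
  xy <- with_substream(seed, igraph::layout_with_fr(net))
  nm <- igraph::V(net)$name
  nodes <- tibble(compound_id = nm, x = xy[, 1], y = xy[, 2],
                  degree = as.integer(igraph::degree(net)))
  if (!is.null(communities)) {
    nodes <- dplyr::left_join(nodes, communities, by = "compound_id")
  } else {
    nodes$community <- 1L
  }
  el <- igraph::as_edgelist(net)
  edges <- tibble(x = nodes$x[match(el[, 1], nm)], y = nodes$y[match(el[, 1], nm)],
                  xend = nodes$x[match(el[, 2], nm)],
                  yend = nodes$y[match(el[, 2], nm)],
                  weight = igraph::E(net)$weight)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = factor(.data$community),
                                     size = .data$degree)) +
    ggplot2::scale_linewidth(range = c(0.1, 1), guide = "none") +
    ggplot2::labs(colour = "community", size = "degree",
                  title = "Functional drug network") +
    ggplot2::theme_void()
}

#' Export a drug network to GraphML
#'
#' Writes node attributes (moa, community, betweenness, degree) and edge
#' weights.
#'
#' @param net a [build_network()] graph.
#' @param path output path.
#' @param communities optional [detect_communities()] tibble.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, communities = NULL) {
  cent <- network_centrality(net)
  net <- igraph::set_vertex_attr(net, "degree", value = cent$degree)
  net <- igraph::set_vertex_attr(net, "betweenness", value = cent$betweenness)
  if (!is.null(communities)) {
    memb <- communities$community[match(igraph::V(net)$name,
                                        communities$compound_id)]
    net <- igraph::set_vertex_attr(net, "community", value = memb)
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
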