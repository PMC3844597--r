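#' Spearman correlation distance between transcript profiles
#'
#' All-pairs distance \eqn{d(u, v) = 1 - \rho_{Spearman}(u, v) \in [0, 2]}
#' over the rows of a profile matrix (transcripts x conditions). Constant
#' profiles have undefined correlation; their distances are set to the
#' sentinel value 1 (uninformative) with a warning. The diagonal is zero.
#'
#' @param profiles transcripts x conditions matrix, e.g. from
#'   \code{\link{transcriptProfiles}}
#' @return symmetric distance matrix with zero diagonal
#' @export
spearmanDistance <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3) stop("need >= 3 conditions per profile")
  const <- apply(profiles, 1, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(t(profiles), method = "spearman"))
  d <- 1 - rho
  if (any(const)) {
    warning(sum(const), " constant profile(s): sentinel distance 1 assigned")
    d[const, ] <- 1
    d[, const] <- 1
  }
  diag(d) <- 0
  d
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with a fixed tie-break: among equal-weight edges the
#' lexicographically smallest (by the sorted node-name pair) is taken first,
#' so the tree is reproducible even when the distance matrix has ties.
#'
#' @param distances full symmetric numeric matrix with zero diagonal and
#'   row/column names (transcript ids)
#' @return a \linkS4class{CoexpressionTree}
#' @export
buildMST <- function(distances) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 2) stop("need >= 2 nodes")
  if (anyNA(distances)) stop("distances contain NA")
  if (max(abs(distances - t(distances))) > 1e-12)
    stop("distance matrix must be symmetric")
  nodes <- rownames(distances)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  iu <- which(upper.tri(distances))
  ii <- ((iu - 1L) %% n) + 1L
  jj <- ((iu - 1L) %/% n) + 1L
  w <- distances[iu]
  a <- pmin(nodes[ii], nodes[jj])
  b <- pmax(nodes[ii], nodes[jj])
  ord <- order(w, a, b)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  picked <- integer(n - 1L)
  np <- 0L
  for (e in ord) {
    ri <- find(ii[e]); rj <- find(jj[e])
    if (ri != rj) {
      parent[ri] <- rj
      np <- np + 1L
      picked[np] <- e
      if (np == n - 1L) break
    }
  }
  edges <- cbind(ii[picked], jj[picked])
  g <- igraph::graph_from_edgelist(matrix(nodes[edges], ncol = 2),
                                   directed = FALSE)
  igraph::E(g)$weight <- w[picked]
  ## graph_from_edgelist orders vertices by first appearance; normalise
  g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
  new("CoexpressionTree", graph = g, nodes = nodes)
}

#' Walk length between tree nodes
#'
#' The number of edges on the unique tree path between each pair of nodes --
#' the metric used to cluster transcripts on the co-expression map.
#'
#' @param tree a \linkS4class{CoexpressionTree}
#' @param from,to node name vectors; pairwise distances are returned as a
#'   matrix. Defaults to all nodes.
#' @return integer matrix of path lengths (edge counts)
#' @export
walkLength <- function(tree, from = NULL, to = NULL) {
  stopifnot(is(tree, "CoexpressionTree"))
  g <- treeGraph(tree)
  if (is.null(from)) from <- treeNodes(tree)
  if (is.null(to)) to <- from
  unknown <- setdiff(c(from, to), treeNodes(tree))
  if (length(unknown))
    stop("unknown node(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  d <- igraph::distances(g, v = from, to = to, weights = NA)
  storage.mode(d) <- "integer"
  d
}

#' Extract co-expressed networks from the tree
#'
#' Single-linkage clustering of the selected transcripts under the
#' walk-length metric, cut at \code{cutoff} -- equivalently, connected
#' components of the graph joining selected pairs at walk length at most
#' \code{cutoff}. Clusters smaller than \code{minNetworkSize} are labelled
#' \code{"unassigned"}; the remaining networks are named \code{net_1},
#' \code{net_2}, ... in decreasing size order (size ties broken by smallest
#' member id).
#'
#' @param tree a \linkS4class{CoexpressionTree}
#' @param selected transcript ids to cluster (subset of the tree nodes)
#' @param cutoff maximal internode walk length within a network (default 4)
#' @param minNetworkSize smallest reported network (default 10)
#' @return data.frame(probe_id, network) with an attribute \code{"sizes"}
#'   (named vector of network sizes, decreasing)
#' @export
extractNetworks <- function(tree, selected, cutoff = 4, minNetworkSize = 10) {
  stopifnot(is(tree, "CoexpressionTree"))
  if (cutoff < 1) stop("cutoff must be >= 1")
  unknown <- setdiff(selected, treeNodes(tree))
  if (length(unknown))
    stop("selected transcript(s) not in tree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  selected <- sort(unique(selected))
  d <- walkLength(tree, selected, selected)
  adj <- d <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  members <- split(selected, comp)
  sizes <- lengths(members)
  first <- vapply(members, function(m) min(m), "")
  ord <- order(-sizes, first)
  members <- members[ord]
  sizes <- sizes[ord]
  big <- sizes >= minNetworkSize
  labels <- rep("unassigned", length(members))
  labels[big] <- paste0("net_", seq_len(sum(big)))
  assign <- stats::setNames(rep(labels, lengths(members)),
                            unlist(members, use.names = FALSE))
  out <- data.frame(probe_id = selected,
                    network = unname(assign[selected]),
                    row.names = NULL)
  attr(out, "sizes") <- stats::setNames(sizes[big], labels[big])
  out
}

#' Write the co-expression tree to disk
#'
#' Emits a tab-delimited edge list (u, v, weight) and, optionally, GraphML.
#'
#' @param tree a \linkS4class{CoexpressionTree}
#' @param edgePath path for the edge-list TSV
#' @param graphmlPath optional path for a GraphML export
#' @return invisibly, the edge-list path
#' @export
writeTree <- function(tree, edgePath, graphmlPath = NULL) {
  g <- treeGraph(tree)
  el <- igraph::as_edgelist(g)
  .writeTsv(data.frame(u = el[, 1], v = el[, 2],
                       weight = igraph::E(g)$weight), edgePath)
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  invisible(edgePath)
}
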