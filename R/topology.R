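#' Node degrees
#'
#' @param net An igraph network.
#' @return Named integer vector of degrees (sum equals twice the edge
#'   count).
#' @export
node_degrees <- function(net) {
  d <- igraph::degree(net)
  storage.mode(d) <- "integer"
  d
}

#' Hub nodes
#'
#' Hubs are the high-degree nodes of a scale-free network; the default
#' threshold of 8 reflects the degree at which roughly the top third of a
#' PPI network's proteins sit.
#'
#' @param net An igraph network.
#' @param degree_threshold Minimum degree to count as a hub; default 8.
#' @return Character vector of hub node names.
#' @export
hub_nodes <- function(net, degree_threshold = 8) {
  d <- node_degrees(net)
  names(d)[d >= degree_threshold]
}

#' Articulation points
#'
#' The cut vertices whose removal increases the number of connected
#' components, found by the linear-time DFS low-link method.  In signaling
#' networks these are communication bottlenecks that candidate pathways
#' should be able to pass through.
#'
#' @param net An igraph network.
#' @return Character vector of articulation-point names (sorted).
#' @export
articulation_points <- function(net) {
  ap <- igraph::articulation_points(net)
  sort(igraph::V(net)$name[as.integer(ap)])
}

#' Longest shortest path (hop diameter)
#'
#' The maximum over all node pairs in the largest connected component of
#' the minimum hop count between them.  This is the number of *edges* on
#' the longest shortest path; the corresponding node count is one more.
#' The value bounds how long a search length is ever needed, and sets the
#' default path length and color count.
#'
#' @param net A non-empty igraph network.
#' @return Integer hop diameter of the largest component.
#' @export
longest_shortest_path <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  as.integer(igraph::diameter(sub, weights = NA, unconnected = FALSE))
}
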