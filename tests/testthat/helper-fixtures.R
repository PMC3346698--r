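# Small named graphs built in code, plus independent brute-force oracles.
# The oracles deliberately avoid the package's own code paths (and igraph's
# specialised algorithms) so implementation-vs-oracle checks stay dual-route.

named_graph <- function(edges, weights = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- if (is.null(weights)) NA_real_ else weights
  g
}

path_graph <- function(n, weights = rep(1, n - 1),
                       names = LETTERS[seq_len(n)]) {
  named_graph(cbind(names[-n], names[-1]), weights)
}

star_graph <- function(n_leaves = 5) {
  leaves <- paste0("L", seq_len(n_leaves))
  named_graph(cbind("HUB", leaves), rep(1, n_leaves))
}

triangle_graph <- function() {
  named_graph(cbind(c("A", "B", "C"), c("B", "C", "A")), rep(1, 3))
}

# Erdos-Renyi-ish random graph with unique positive weights
random_weighted_graph <- function(n, p = 0.35, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
    named_graph(pairs[keep, , drop = FALSE],
                stats::runif(sum(keep), 0.1, 3))
  })
}

graph_nodes <- function(g) igraph::V(g)$name

# ---- oracles --------------------------------------------------------------

# articulation points by deleting each node and counting components:
# removing an isolated node lowers the count, removing any other node
# keeps or raises it -- it is a cut vertex exactly when the count rises
oracle_articulation <- function(g) {
  nodes <- graph_nodes(g)
  deg <- igraph::degree(g)
  base <- igraph::components(g)$no
  out <- character(0)
  for (v in nodes) {
    if (deg[v] == 0) next
    if (igraph::components(igraph::delete_vertices(g, v))$no > base) {
      out <- c(out, v)
    }
  }
  sort(out)
}

# hop distance by hand-rolled BFS (independent of igraph::distances)
oracle_bfs_ecc <- function(g, v) {
  nodes <- graph_nodes(g)
  adj <- lapply(igraph::adjacent_vertices(g, nodes),
                function(x) nodes[as.integer(x)])
  names(adj) <- nodes
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  dist[v] <- 0L
  frontier <- v
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[u] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_diameter <- function(g) {
  nodes <- graph_nodes(g)
  max(vapply(nodes, function(v) {
    d <- oracle_bfs_ecc(g, v)
    max(d, na.rm = TRUE)
  }, integer(1)))
}

# enumerate all simple paths of exactly l nodes from s to t (node names)
enumerate_simple_paths <- function(g, s, t, l) {
  nodes <- graph_nodes(g)
  adj <- lapply(igraph::adjacent_vertices(g, nodes),
                function(x) nodes[as.integer(x)])
  names(adj) <- nodes
  out <- list()
  recur <- function(path) {
    v <- path[length(path)]
    if (length(path) == l) {
      if (v == t) out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (u in adj[[v]]) {
      if (!(u %in% path)) recur(c(path, u))
    }
  }
  recur(s)
  out
}

oracle_path_weight <- function(g, path) {
  ids <- igraph::get_edge_ids(g, c(rbind(path[-length(path)], path[-1])))
  sum(igraph::E(g)$weight[ids])
}

oracle_location_ok <- function(path, locations) {
  if (is.null(locations)) return(TRUE)
  r <- unname(locations[path])
  r <- r[!is.na(r)]
  length(r) <= 1 || all(diff(r) >= 0)
}

# brute-force minimum-weight colorful location-valid l-path
oracle_min_colorful <- function(g, coloring, s, t, l, locations = NULL) {
  col <- coloring$color
  cand <- enumerate_simple_paths(g, s, t, l)
  cand <- Filter(function(p) length(unique(col[p])) == l, cand)
  cand <- Filter(function(p) oracle_location_ok(p, locations), cand)
  if (length(cand) == 0) return(NULL)
  w <- vapply(cand, function(p) oracle_path_weight(g, p), numeric(1))
  best <- which(abs(w - min(w)) <= 1e-9)
  keys <- vapply(cand[best], paste, character(1), collapse = "\r")
  list(path = cand[best][[order(keys)[1]]], weight = min(w))
}

# exact hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(overlap, n_term, n_bg, n_path) {
  q <- overlap:min(n_term, n_path)
  sum(choose(n_term, q) * choose(n_bg - n_term, n_path - q)) /
    choose(n_bg, n_path)
}
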