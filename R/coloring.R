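#' Topology-aware network coloring
#'
#' Assigns each node one of `k` colors for color-coding search.  Nodes are
#' processed in descending-degree order (ties by node id), and every node
#' of degree >= 2 draws uniformly among the colors not already used by its
#' colored neighbours (uniform over all `k` if none is free).  Degree-1
#' leaves cannot extend a path, so in `paper_faithful` mode they simply
#' copy their neighbour's color -- spending no color budget on them -- while
#' `strict_leaf` mode forces them to differ too.  A final pass recolors any
#' articulation point that collides with a neighbour, provided a free color
#' exists: paths must be able to traverse these bottlenecks, so they must
#' stay distinguishable from their neighbourhoods.
#'
#' `method = "uniform"` ignores topology entirely and colors every node
#' i.i.d. uniformly -- the classical randomized color-coding baseline.
#'
#' @param net An igraph network with named nodes.
#' @param k Number of colors (>= 2).
#' @param degree_threshold Hub degree threshold (reporting only; the
#'   coloring itself treats all degree >= 2 nodes alike); default 8.
#' @param seed Integer seed; one seeded generator drives every random
#'   choice in the coloring.
#' @param mode `"paper_faithful"` (leaves copy their neighbour's color,
#'   the default) or `"strict_leaf"` (leaves must differ too).
#' @param method `"topology"` (default) or `"uniform"`.
#' @return An object of class `pc_coloring`: list with `color` (named
#'   integer vector in 1..k), `k`, `mode`, `method`, `seed`.
#' @export
color_network <- function(net, k, degree_threshold = 8, seed = NULL,
                          mode = c("paper_faithful", "strict_leaf"),
                          method = c("topology", "uniform")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  colorer <- coloring_factory(net, k, mode = mode, method = method)
  colorer(seed)
}

# Precomputes the topology (degrees, processing order, neighbour lists,
# articulation points) once and returns a closure that produces one
# coloring per call; restart-heavy callers draw thousands of colorings
# from a single factory.
coloring_factory <- function(net, k, mode = "paper_faithful",
                             method = "topology") {
  if (k < 2) stop("k must be >= 2")
  k <- as.integer(k)
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  all_colors <- seq_len(k)
  deg <- ord <- nbrs <- ap_idx <- interior <- NULL
  if (method == "topology") {
    deg <- unname(node_degrees(net)[nodes])
    ord <- order(-deg, nodes, method = "radix")
    nbrs <- lapply(igraph::adjacent_vertices(net, nodes), as.integer)
    ap_idx <- match(articulation_points(net), nodes)
    interior <- deg >= 2
  }
  draw <- function() {
    if (method == "uniform") {
      return(stats::setNames(sample.int(k, n, replace = TRUE), nodes))
    }
    col <- rep(NA_integer_, n)
    for (v in ord) {
      nb_col <- col[nbrs[[v]]]
      nb_col <- nb_col[!is.na(nb_col)]
      if (!interior[v] && mode == "paper_faithful") {
        # a leaf can never sit in a path interior: copy the hub's color
        col[v] <- if (length(nb_col) > 0) nb_col[1] else sample.int(k, 1)
        next
      }
      free <- if (length(nb_col) > 0) all_colors[-nb_col] else all_colors
      col[v] <- if (length(free) > 0) sample_one(free) else sample.int(k, 1)
    }
    # recoloring pass: articulation points must differ from their
    # neighbours.  In paper_faithful mode leaves share their hub's color
    # on purpose, so only degree >= 2 neighbours count as collisions.
    for (v in ap_idx) {
      nb <- nbrs[[v]]
      if (mode == "paper_faithful") nb <- nb[interior[nb]]
      nb_col <- unique(col[nb])
      if (col[v] %in% nb_col) {
        free <- all_colors[-nb_col]
        if (length(free) > 0) col[v] <- sample_one(free)
      }
    }
    stats::setNames(col, nodes)
  }
  function(seed = NULL) {
    col <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    structure(list(color = col, k = k, mode = mode, method = method,
                   seed = seed),
              class = "pc_coloring")
  }
}

#' @export
print.pc_coloring <- function(x, ...) {
  cat("<pc_coloring> ", length(x$color), " nodes, k = ", x$k,
      ", mode = ", x$mode, ", method = ", x$method, "\n", sep = "")
  invisible(x)
}

#' Count coloring-constraint violations
#'
#' QA surface for [color_network()]: counts hub--neighbour and
#' articulation-point--neighbour pairs sharing a color.
#'
#' @param net An igraph network.
#' @param coloring A `pc_coloring`.
#' @param degree_threshold Hub degree threshold; default 8.
#' @return A one-row tibble: `hub_violations`, `articulation_violations`.
#' @export
coloring_report <- function(net, coloring, degree_threshold = 8) {
  col <- coloring$color
  el <- igraph::as_edgelist(net)
  same <- col[el[, 1]] == col[el[, 2]]
  hubs <- hub_nodes(net, degree_threshold)
  aps <- articulation_points(net)
  hub_v <- sum(same & (el[, 1] %in% hubs | el[, 2] %in% hubs))
  ap_v <- sum(same & (el[, 1] %in% aps | el[, 2] %in% aps))
  tibble::tibble(hub_violations = as.integer(hub_v),
                 articulation_violations = as.integer(ap_v))
}

#' Is a path colorful?
#'
#' @param path Ordered vector of node names.
#' @param coloring A `pc_coloring` (or named integer vector of colors).
#' @return `TRUE` iff all colors along the path are pairwise distinct.
#' @export
is_colorful <- function(path, coloring) {
  col <- if (inherits(coloring, "pc_coloring")) coloring$color else coloring
  pc <- col[path]
  if (anyNA(pc)) stop("uncolored node(s) on path: ",
                      paste(path[is.na(pc)], collapse = ", "))
  length(unique(pc)) == length(path)
}

#' Probability a fixed k-path is colorful under uniform coloring
#'
#' Under i.i.d. uniform coloring with k colors, a fixed path of k nodes is
#' colorful with probability `k!/k^k`, which Stirling's bound keeps above
#' `exp(-k)`.
#'
#' @param k Number of colors = path length in nodes (>= 1).
#' @return `k!/k^k`.
#' @export
colorful_probability_bound <- function(k) {
  stopifnot(k >= 1)
  exp(lfactorial(k) - k * log(k))
}

#' Repetitions needed to cap the failure probability
#'
#' A single uniform coloring misses a fixed k-path with probability at
#' most `1 - exp(-k)`; after t independent colorings the overall failure
#' probability is `(1 - exp(-k))^t`.  Returns the smallest t pushing that
#' below `failure_cap`: `t = ceil(log(failure_cap) / log(1 - exp(-k)))`.
#'
#' @param k Path length in nodes (= number of colors).
#' @param failure_cap Acceptable overall failure probability in (0, 1);
#'   default 0.05.
#' @return Integer number of repetitions (0 if `failure_cap >= 1`).
#' @export
required_repetitions <- function(k, failure_cap = 0.05) {
  stopifnot(k >= 1, failure_cap > 0)
  if (failure_cap >= 1) return(0L)
  lr <- log1p(-exp(-k))           # log(1 - e^-k), accurate for large k
  t <- as.integer(ceiling(log(failure_cap) / lr))
  # guard floating-point slop at the boundary
  while (t > 1 && (t - 1) * lr <= log(failure_cap)) t <- t - 1L
  t
}

#' Monte-Carlo colorful-path success rate
#'
#' Fraction of independent colorings under which at least one colorful
#' simple path of `l` nodes exists between a start node drawn from
#' `start_set` and an end node drawn from `end_set` (existence is checked
#' exactly by dynamic programming over color subsets).  Start/end pairs and
#' coloring seeds are drawn up front from `seed`, so two calls with the
#' same seed but different coloring `method` are paired trial-by-trial.
#'
#' @param net An igraph network with named nodes.
#' @param trials Number of independent colorings (>= 1).
#' @param l Path length in nodes.
#' @param start_set,end_set Candidate start/end node names; default all
#'   nodes.
#' @param seed Integer seed.
#' @param method,mode,k,degree_threshold Passed to [color_network()];
#'   `k` defaults to `l`.
#' @return Fraction of successful colorings in `[0, 1]`.
#' @export
success_rate <- function(net, trials, l, start_set = NULL, end_set = NULL,
                         seed = 1L, method = c("topology", "uniform"),
                         mode = "paper_faithful", k = l,
                         degree_threshold = 8) {
  method <- match.arg(method)
  stopifnot(trials >= 1)
  nodes <- igraph::V(net)$name
  if (is.null(start_set)) start_set <- nodes
  if (is.null(end_set)) end_set <- nodes
  stopifnot(length(start_set) > 0, length(end_set) > 0)
  draws <- withr::with_seed(seed, {
    s <- sample(start_set, trials, replace = TRUE)
    t <- vapply(s, function(si) {
      cand <- setdiff(end_set, si)
      if (length(cand) == 0) stop("cannot draw an end node distinct from ", si)
      sample_one(cand)
    }, character(1), USE.NAMES = FALSE)
    list(s = s, t = t, cs = sample.int(.Machine$integer.max - 1L, trials))
  })
  idx <- build_adjacency(net)
  colorer <- coloring_factory(net, k, mode = mode, method = method)
  ok <- vapply(seq_len(trials), function(i) {
    coloring <- colorer(draws$cs[i])
    colorful_path_exists(net, coloring, draws$s[i], draws$t[i], l,
                         adjacency = idx)
  }, logical(1))
  mean(ok)
}

#' Exact colorful-path existence under a fixed coloring
#'
#' Dynamic programming over color subsets (`O(2^k m l)`), independent of
#' the weighted A* search.
#'
#' @param net An igraph network with named nodes.
#' @param coloring A `pc_coloring` covering the network.
#' @param s,t Start/end node names (distinct).
#' @param l Path length in nodes.
#' @param adjacency Optional precomputed [build_adjacency()] result.
#' @return `TRUE` iff a colorful simple path of `l` nodes from `s` to `t`
#'   exists.
#' @export
colorful_path_exists <- function(net, coloring, s, t, l, adjacency = NULL) {
  a <- if (is.null(adjacency)) build_adjacency(net) else adjacency
  if (coloring$k > 20) stop("k too large for subset DP (max 20)")
  si <- match(s, a$nodes); ti <- match(t, a$nodes)
  if (is.na(si) || is.na(ti)) stop("start or end node not in network")
  if (s == t) stop("start and end must differ")
  col <- unname(coloring$color[a$nodes])
  cpp_colorful_exists(a$adj, as.integer(col), si, ti, as.integer(l),
                      coloring$k)
}

#' Serialize a coloring
#'
#' Writes node/color pairs as TSV plus a JSON sidecar recording k, mode,
#' method and seed.
#'
#' @param coloring A `pc_coloring`.
#' @param path Output TSV path (`<path>.json` gets the sidecar).
#' @return `path`, invisibly.
#' @export
write_coloring <- function(coloring, path) {
  df <- tibble::tibble(node = names(coloring$color),
                       color = unname(coloring$color))
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  jsonlite::write_json(coloring[c("k", "mode", "method", "seed")],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
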