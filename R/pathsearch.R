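#' Adjacency lists in lexicographic node order
#'
#' Internal representation consumed by the compiled search kernels.  Nodes
#' are re-indexed in lexicographic name order so that weight ties resolve
#' to the lexicographically smallest node sequence.
#'
#' @param net An igraph network with named nodes.
#' @return List with `nodes` (sorted names), `adj` (list of 1-based
#'   neighbour index vectors, ascending) and `wts` (parallel weight
#'   vectors).
#' @export
build_adjacency <- function(net) {
  nodes <- sort(igraph::V(net)$name, method = "radix")
  n <- length(nodes)
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(NA_real_, nrow(el))
  a <- match(el[, 1], nodes)
  b <- match(el[, 2], nodes)
  from <- c(a, b); to <- c(b, a); ww <- c(w, w)
  o <- order(from, to, method = "radix")
  f <- factor(from[o], levels = seq_len(n))
  adj <- split(to[o], f)
  wts <- split(ww[o], f)
  list(nodes = nodes,
       adj = lapply(adj, as.integer),
       wts = lapply(wts, as.numeric))
}

#' Sample random simple-path statistics
#'
#' Draws `n_samples` random simple paths of `l` nodes by self-avoiding
#' random walk (random start, uniform unvisited neighbour at each step,
#' restart on dead ends, capped attempts) over the *uncolored* network,
#' and pools the weights of all traversed edges.  These statistics
#' calibrate the search bound: typical paths score near
#' `w_avg * (l - 1)` per path, and no path can beat `w_min` per edge.
#'
#' @param net Weighted igraph network.
#' @param l Path length in nodes (>= 2).
#' @param n_samples Number of sampled paths (>= 1); default 5000.
#' @param seed Integer seed.
#' @param start_set Optional start-node pool (default all nodes).
#' @param end_set Optional end-node pool; when given, sampled paths must
#'   terminate inside it.
#' @param max_attempts Cap on restart attempts; default `50 * n_samples`.
#' @return Object of class `pc_path_stats`: list with `w_min`, `w_avg`,
#'   `w_std`, `n_samples`, `l`.
#' @export
sample_path_stats <- function(net, l, n_samples = 5000, seed = 1L,
                              start_set = NULL, end_set = NULL,
                              max_attempts = 50 * n_samples) {
  stopifnot(n_samples >= 1, l >= 2)
  a <- build_adjacency(net)
  if (is.null(start_set)) start_set <- a$nodes
  start_idx <- match(start_set, a$nodes)
  end_idx <- if (is.null(end_set)) NULL else match(end_set, a$nodes)
  all_w <- unlist(a$wts, use.names = FALSE)
  if (length(all_w) == 0 || anyNA(all_w)) {
    stop("network must have weights assigned on all edges")
  }
  w_min <- min(all_w)
  edge_w <- withr::with_seed(seed, {
    got <- 0L
    attempts <- 0L
    acc <- vector("list", n_samples)
    while (got < n_samples) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not sample ", n_samples, " simple paths of ", l,
             " nodes within ", max_attempts, " attempts")
      }
      v <- start_idx[[sample.int(length(start_idx), 1L)]]
      path_w <- numeric(l - 1)
      visited <- v
      ok <- TRUE
      for (step in seq_len(l - 1)) {
        nb <- a$adj[[v]]
        keep <- !(nb %in% visited)
        if (!any(keep)) { ok <- FALSE; break }
        pick <- sample_one(which(keep))
        path_w[step] <- a$wts[[v]][pick]
        u <- nb[pick]
        visited <- c(visited, u)
        v <- u
      }
      if (ok && !is.null(end_idx) && !(v %in% end_idx)) ok <- FALSE
      if (ok) {
        got <- got + 1L
        acc[[got]] <- path_w
      }
    }
    unlist(acc, use.names = FALSE)
  })
  structure(list(w_min = w_min,
                 w_avg = mean(edge_w),
                 w_std = if (length(edge_w) > 1) sd(edge_w) else 0,
                 n_samples = as.integer(n_samples),
                 l = as.integer(l)),
            class = "pc_path_stats")
}

#' @export
print.pc_path_stats <- function(x, ...) {
  cat(sprintf(
    "<pc_path_stats> l = %d, n = %d: w_min = %.4g, w_avg = %.4g, w_std = %.4g\n",
    x$l, x$n_samples, x$w_min, x$w_avg, x$w_std))
  invisible(x)
}

#' Bound score for path pruning
#'
#' The calibrated ceiling on acceptable path weight,
#' `(w_avg + alpha * w_std) * l`: alpha widens the net around the typical
#' sampled per-edge weight.  `l` multiplies as a node count, which makes
#' the bound slightly looser than the `l - 1` edges a path actually has --
#' never unsound; set `per_edge = TRUE` for the strict `l - 1` variant.
#'
#' @param stats A `pc_path_stats`.
#' @param alpha Nonnegative bound multiplier; default 0.5.
#' @param l Path length in nodes; defaults to `stats$l`.
#' @param per_edge Multiply by `l - 1` instead of `l`.
#' @return The bound score (a single number).
#' @export
bound_score <- function(stats, alpha = 0.5, l = stats$l, per_edge = FALSE) {
  stopifnot(alpha >= 0)
  mult <- if (per_edge) l - 1 else l
  (stats$w_avg + alpha * stats$w_std) * mult
}

#' Search configuration
#'
#' @param l Path length in nodes (>= 2).
#' @param d Pre-traverse depth: bound pruning is disabled while the
#'   partial path has `d` nodes or fewer, forcing short prefixes to be
#'   explored exhaustively; default 3.
#' @param alpha Bound multiplier for [bound_score()]; default 0.5.
#' @param max_results Result-list cap for [search_with_restarts()];
#'   default 100.
#' @param enforce_location Apply the non-decreasing cellular-location
#'   constraint; default `FALSE` (turned on automatically when a location
#'   map is supplied).
#' @return A `pc_search_config` list.
#' @export
search_config <- function(l, d = 3, alpha = 0.5, max_results = 100,
                          enforce_location = FALSE) {
  stopifnot(l >= 2, d >= 1, d < l, alpha >= 0, max_results >= 1)
  structure(list(l = as.integer(l), d = as.integer(d), alpha = alpha,
                 max_results = as.integer(max_results),
                 enforce_location = isTRUE(enforce_location)),
            class = "pc_search_config")
}

#' Bounded A* search for a minimum-weight colorful path
#'
#' Depth-first branch-and-bound over simple paths of exactly `l` nodes
#' from `s` to `t`.  A partial path extends only to unvisited neighbours
#' whose color is unused on the path and (when locations are enforced)
#' whose compartment rank is not below the current one; beyond the
#' pre-traverse depth `d`, a branch is pruned when
#' `f = g + w_min * (l - depth)` exceeds the bound.  Since no edge weighs
#' less than `w_min`, the heuristic never overestimates the remaining
#' weight (it is admissible, and consistent), so whenever the bound is at
#' least the optimum the returned path is the true minimum-weight
#' colorful, location-valid `l`-path.  Weight ties resolve to the
#' lexicographically smallest node sequence.
#'
#' @param net Weighted igraph network.
#' @param coloring A `pc_coloring` covering the network.
#' @param s,t Distinct start and end node names.
#' @param config A [search_config()] (supplies `l` and `d`).
#' @param bound Pruning bound; `Inf` disables bound pruning (the search is
#'   then exhaustive over colorful location-valid paths).
#' @param locations Optional named integer vector of location ranks
#'   (`NA` = wildcard); enables the location constraint.
#' @param w_min Minimum per-edge weight used by the heuristic; defaults to
#'   the network's true minimum edge weight.
#' @param adjacency Optional precomputed [build_adjacency()].
#' @return A one-row tibble (`weight`, `colorful`, `location_valid`,
#'   `nodes` list-column), or `NULL` when no qualifying path survives the
#'   bound.
#' @export
astar_colorful_path <- function(net, coloring, s, t, config,
                                bound = Inf, locations = NULL,
                                w_min = NULL, adjacency = NULL) {
  stopifnot(inherits(config, "pc_search_config"))
  a <- if (is.null(adjacency)) build_adjacency(net) else adjacency
  si <- match(s, a$nodes); ti <- match(t, a$nodes)
  if (is.na(si)) stop("start node not in network: ", s)
  if (is.na(ti)) stop("end node not in network: ", t)
  if (s == t) stop("start and end must differ")
  col <- unname(coloring$color[a$nodes])
  if (anyNA(col)) stop("coloring does not cover the network")
  all_w <- unlist(a$wts, use.names = FALSE)
  if (anyNA(all_w)) stop("network has unweighted edges; run assign_weights()")
  if (is.null(w_min)) w_min <- min(all_w)
  enforce <- !is.null(locations)
  loc <- if (enforce) {
    as.integer(unname(locations[a$nodes]))
  } else {
    rep(NA_integer_, length(a$nodes))
  }
  res <- cpp_astar(a$adj, a$wts, as.integer(col), loc,
                   si, ti, config$l, config$d, bound, w_min, enforce)
  if (!res$found) return(NULL)
  nodes <- a$nodes[res$path]
  tibble::tibble(weight = res$weight,
                 colorful = TRUE,
                 location_valid = path_location_valid(nodes, locations),
                 nodes = list(nodes))
}

#' Check location monotonicity of a path
#'
#' @param path Ordered node names.
#' @param locations Named integer rank vector (`NA`/absent = wildcard), or
#'   `NULL` (trivially valid).
#' @return `TRUE` iff the non-wildcard ranks along the path never
#'   decrease.
#' @export
path_location_valid <- function(path, locations = NULL) {
  if (is.null(locations)) return(TRUE)
  r <- unname(locations[path])
  r <- r[!is.na(r)]
  length(r) <= 1 || !is.unsorted(r)
}

#' Color-coding search with repeated colorings
#'
#' Runs [color_network()] + [astar_colorful_path()] under `n_colorings`
#' independent colorings (fresh seeds derived from `seed`), dedupes the
#' paths found, and returns them sorted by weight.  The best weight found
#' so far tightens the pruning bound across restarts.
#'
#' @param net Weighted igraph network.
#' @param s,t Start and end node names.
#' @param config A [search_config()].
#' @param n_colorings Number of coloring repetitions; default
#'   `required_repetitions(config$l, 0.05)`, the count that caps the
#'   overall miss probability at 5% even for uniform coloring.
#' @param seed Master integer seed.
#' @param degree_threshold Hub threshold for the coloring; default 8.
#' @param locations Optional location-rank vector (enables the
#'   location constraint).
#' @param stats Optional precomputed [sample_path_stats()]; sampled here
#'   (1000 paths) when `NULL` and `bound` is not given.
#' @param bound Initial pruning bound; defaults to
#'   `bound_score(stats, config$alpha, config$l)`.
#' @param mode,method Coloring mode and method (see [color_network()]).
#' @param k Number of colors; defaults to `config$l`.
#' @return A `pc_paths` tibble: `rank`, `weight`, `colorful`,
#'   `location_valid`, `nodes` (list-column), sorted by weight and
#'   truncated to `config$max_results`.  May have zero rows.
#' @export
search_with_restarts <- function(net, s, t, config,
                                 n_colorings = required_repetitions(config$l, 0.05),
                                 seed = 1L, degree_threshold = 8,
                                 locations = NULL, stats = NULL,
                                 bound = NULL, mode = "paper_faithful",
                                 method = "topology", k = config$l) {
  stopifnot(inherits(config, "pc_search_config"), n_colorings >= 1)
  a <- build_adjacency(net)
  if (is.null(bound)) {
    if (is.null(stats)) {
      stats <- sample_path_stats(net, config$l, n_samples = 1000,
                                 seed = derive_seeds(seed, 1))
    }
    bound <- bound_score(stats, config$alpha, config$l)
  }
  w_min <- if (!is.null(stats)) stats$w_min else NULL
  seeds <- derive_seeds(seed, n_colorings + 1)[-1]
  colorer <- coloring_factory(net, k, mode = mode, method = method)
  found <- list()
  best <- Inf
  for (i in seq_len(n_colorings)) {
    coloring <- colorer(seeds[i])
    hit <- astar_colorful_path(net, coloring, s, t, config,
                               bound = min(bound, best),
                               locations = locations, w_min = w_min,
                               adjacency = a)
    if (!is.null(hit)) {
      best <- min(best, hit$weight)
      found[[length(found) + 1]] <- hit
    }
  }
  if (length(found) == 0) {
    res <- tibble::tibble(rank = integer(0), weight = numeric(0),
                          colorful = logical(0), location_valid = logical(0),
                          nodes = list())
  } else {
    res <- dplyr::bind_rows(found)
    key <- vapply(res$nodes, paste, character(1), collapse = ">")
    res <- res[!duplicated(key), , drop = FALSE]
    res <- res[order(res$weight,
                     vapply(res$nodes, paste, character(1), collapse = "\r"),
                     method = "radix"), , drop = FALSE]
    res <- head(res, config$max_results)
    res <- tibble::add_column(res, rank = seq_len(nrow(res)), .before = 1)
  }
  structure(res,
            class = c("pc_paths", class(tibble::tibble()))) -> out
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "n_colorings") <- n_colorings
  attr(out, "bound") <- bound
  out
}

#' @exportS3Method generics::tidy
tidy.pc_paths <- function(x, ...) {
  tibble::tibble(rank = x$rank,
                 weight = x$weight,
                 length = vapply(x$nodes, length, integer(1)),
                 colorful = x$colorful,
                 location_valid = x$location_valid,
                 path = vapply(x$nodes, paste, character(1),
                               collapse = " -> "))
}

#' @exportS3Method generics::glance
glance.pc_paths <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(n_paths = nrow(x),
                 best_weight = if (nrow(x) > 0) min(x$weight) else NA_real_,
                 l = if (!is.null(cfg)) cfg$l else NA_integer_,
                 n_colorings = attr(x, "n_colorings") %||% NA_integer_,
                 bound = attr(x, "bound") %||% NA_real_)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pc_paths <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rank, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "path rank", y = "path weight (−log |r| sum)") +
    ggplot2::theme_minimal()
}

#' Assemble detected paths into a subnetwork
#'
#' Keeps the paths whose node set hits at least half (rounded up) of the
#' reference main chain, and returns the union of their nodes and
#' consecutive edges as a network.  Edge weights are copied from `net`
#' when supplied.
#'
#' @param paths A `pc_paths` tibble (or list of node-name vectors).
#' @param main_chain Ordered node names of the reference main chain
#'   (non-empty).
#' @param net Optional source network supplying edge weights.
#' @return An igraph subnetwork (possibly empty).
#' @export
assemble_network <- function(paths, main_chain, net = NULL) {
  if (length(main_chain) == 0) stop("main_chain must be non-empty")
  node_lists <- if (is.data.frame(paths)) paths$nodes else paths
  need <- ceiling(length(main_chain) / 2)
  keep <- purrr::keep(node_lists,
                      ~ length(intersect(.x, main_chain)) >= need)
  if (length(keep) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  a <- unlist(lapply(keep, function(p) p[-length(p)]), use.names = FALSE)
  b <- unlist(lapply(keep, function(p) p[-1]), use.names = FALSE)
  g <- edges_from_pairs(a, b)
  if (!is.null(net)) {
    el <- igraph::as_edgelist(g)
    ids <- igraph::get_edge_ids(net, c(t(el)))
    w <- rep(NA_real_, nrow(el))
    w[ids > 0] <- igraph::E(net)$weight[ids[ids > 0]]
    igraph::E(g)$weight <- w
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
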