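#' Generate a scale-free network
#'
#' Preferential-attachment (Barabasi-Albert) graph: each new node attaches
#' `m_attach` edges preferentially to high-degree nodes, giving the
#' heavy-tailed degree distribution characteristic of PPI networks (a few
#' hubs, many low-degree nodes).  Always connected; deterministic under
#' `seed`.
#'
#' @param n Number of nodes (`> m_attach`).
#' @param m_attach Edges added per new node (>= 1); default 2.
#' @param seed Integer seed.
#' @return An igraph network with nodes named `P001`, `P002`, ...
#' @export
generate_scale_free <- function(n, m_attach = 2, seed = 1L) {
  if (n <= m_attach) stop("n must exceed m_attach")
  if (m_attach < 1) stop("m_attach must be >= 1")
  g <- withr::with_seed(seed,
    igraph::sample_pa(n, m = m_attach, directed = FALSE))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("P%03d", seq_len(n))
  igraph::E(g)$weight <- NA_real_
  g
}

#' Plant a location-tagged path in a network
#'
#' Selects `l` nodes with no pre-existing edges among them (so the path
#' edges are the *only* connections inside the planted set -- sampled with
#' a retry cap, then greedily minimizing internal edges), wires them into
#' a simple path, and tags the first node membrane (rank 1), intermediate
#' nodes cytoplasm (rank 2) and the last node nucleus (rank 3), making the
#' path location-monotone by construction.
#'
#' @param net An igraph network with named nodes.
#' @param l Path length in nodes (`2 <= l <= n`).
#' @param seed Integer seed.
#' @return List with `net` (the network plus any added edges, weights
#'   unset on new edges), `path` (ordered node names) and `locations`
#'   (named rank vector for the path's nodes).
#' @export
plant_path <- function(net, l, seed = 1L) {
  n <- igraph::vcount(net)
  if (l > n) stop("l exceeds the number of nodes")
  stopifnot(l >= 2)
  nodes <- igraph::V(net)$name
  path <- withr::with_seed(seed, {
    best <- NULL
    best_internal <- Inf
    for (try in 1:200) {
      cand <- sample(nodes, l)
      sub <- igraph::induced_subgraph(net, cand)
      internal <- igraph::ecount(sub)
      if (internal < best_internal) {
        best <- cand
        best_internal <- internal
      }
      if (internal == 0) break
    }
    best
  })
  a <- path[-l]; b <- path[-1]
  ids <- igraph::get_edge_ids(net, c(rbind(a, b)))
  missing <- which(ids == 0)
  if (length(missing) > 0) {
    net <- igraph::add_edges(net, rbind(a[missing], b[missing]),
                             attr = list(weight = NA_real_))
  }
  ranks <- c(1L, rep(2L, l - 2), 3L)
  names(ranks) <- path
  list(net = net, path = path, locations = ranks)
}

#' Generate a correlated expression matrix with a planted path
#'
#' Planted genes load on one shared latent factor plus independent
#' Gaussian noise; the loading solves
#' `lambda^2 / (lambda^2 + noise_sd^2) = r_on`, so every planted pair has
#' expected correlation `r_on`.  All other genes are independent noise
#' with the same marginal variance.  This emulates the co-expression of
#' genes whose proteins act in one signaling cascade; missing cells are
#' masked uniformly at random.
#'
#' @param net An igraph network (its node names become the genes).
#' @param planted Node names of the planted path (may be empty).
#' @param n_samples Number of samples (columns); default 200.
#' @param r_on Target pairwise correlation among planted genes in (0, 1);
#'   default 0.9.
#' @param noise_sd Noise standard deviation; default 1.
#' @param missing_frac Fraction of cells masked as missing in `[0, 1)`;
#'   default 0.
#' @param seed Integer seed.
#' @return A genes x samples numeric matrix (`NA` = missing).
#' @export
generate_expression <- function(net, planted = character(0),
                                n_samples = 200, r_on = 0.9, noise_sd = 1,
                                missing_frac = 0, seed = 1L) {
  stopifnot(r_on > 0, r_on < 1, missing_frac >= 0, missing_frac < 1)
  genes <- igraph::V(net)$name
  stopifnot(all(planted %in% genes))
  lambda <- noise_sd * sqrt(r_on / (1 - r_on))
  s_marginal <- sqrt(lambda^2 + noise_sd^2)
  withr::with_seed(seed, {
    mat <- matrix(rnorm(length(genes) * n_samples, sd = s_marginal),
                  nrow = length(genes), dimnames = list(genes,
                    sprintf("S%03d", seq_len(n_samples))))
    if (length(planted) > 0) {
      z <- rnorm(n_samples)
      for (g in planted) {
        mat[g, ] <- lambda * z + rnorm(n_samples, sd = noise_sd)
      }
    }
    if (missing_frac > 0) {
      n_miss <- round(length(mat) * missing_frac)
      mat[sample.int(length(mat), n_miss)] <- NA_real_
    }
    mat
  })
}

#' One-call synthetic pathway-detection instance
#'
#' Convenience wrapper: scale-free network, planted location-tagged path,
#' correlated expression, and co-expression weights, ready for
#' [search_with_restarts()].
#'
#' @param n Number of nodes.
#' @param l Planted path length in nodes.
#' @param m_attach Attachment edges per node; default 2.
#' @param n_samples Expression samples; default 200.
#' @param r_on Planted pairwise correlation; default 0.9.
#' @param missing_frac Missing-cell fraction; default 0.
#' @param seed Integer seed.
#' @return List with `net` (weighted), `path`, `locations`, `expression`.
#' @export
synthetic_instance <- function(n, l, m_attach = 2, n_samples = 200,
                               r_on = 0.9, missing_frac = 0, seed = 1L) {
  seeds <- derive_seeds(seed, 3)
  g <- generate_scale_free(n, m_attach, seed = seeds[1])
  pl <- plant_path(g, l, seed = seeds[2])
  expr <- generate_expression(pl$net, pl$path, n_samples = n_samples,
                              r_on = r_on, missing_frac = missing_frac,
                              seed = seeds[3])
  if (missing_frac > 0) {
    expr_complete <- impute_knn(filter_missing(expr))
  } else {
    expr_complete <- expr
  }
  net <- assign_weights(pl$net, expr_complete)
  list(net = net, path = pl$path, locations = pl$locations,
       expression = expr)
}
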