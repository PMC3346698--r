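colorful_coloring <- function(g) {
  nodes <- sort(graph_nodes(g), method = "radix")
  structure(list(color = stats::setNames(seq_along(nodes), nodes),
                 k = length(nodes), mode = "paper_faithful",
                 method = "topology"),
            class = "pc_coloring")
}

random_coloring <- function(g, k, seed) {
  color_network(g, k = k, seed = seed, method = "uniform")
}

test_that("path statistics are exact on degenerate weights and seeded", {
  g <- named_graph(cbind(c("A", "B", "C", "A"), c("B", "C", "D", "D")),
                   rep(2.5, 4))
  st <- sample_path_stats(g, l = 3, n_samples = 200, seed = 1)
  expect_equal(st$w_avg, 2.5)
  expect_equal(st$w_std, 0)
  expect_equal(st$w_min, 2.5)
  st2 <- sample_path_stats(g, l = 3, n_samples = 200, seed = 1)
  expect_identical(unclass(st), unclass(st2))
  expect_error(sample_path_stats(path_graph(3), l = 4, n_samples = 5,
                                 max_attempts = 50),
               "could not sample")
})

test_that("sampled per-edge statistics approach the enumeration oracle", {
  g <- random_weighted_graph(6, 0.6, seed = 8)
  l <- 4
  # pool the edge weights of every simple l-path (both directions collapse)
  nodes <- graph_nodes(g)
  all_paths <- list()
  for (s in nodes) for (t in nodes) {
    if (s < t) all_paths <- c(all_paths, enumerate_simple_paths(g, s, t, l))
  }
  pooled <- unlist(lapply(all_paths, function(p) {
    ids <- igraph::get_edge_ids(g, c(rbind(p[-length(p)], p[-1])))
    igraph::E(g)$weight[ids]
  }))
  st <- sample_path_stats(g, l = l, n_samples = 5000, seed = 3)
  expect_lt(abs(st$w_avg - mean(pooled)), 3 * sd(pooled) / sqrt(5000) + 0.05)
  expect_equal(st$w_min, min(igraph::E(g)$weight))
})

test_that("bound score follows (w_avg + alpha w_std) * l", {
  st <- structure(list(w_min = 1, w_avg = 1.7, w_std = 0.2, n_samples = 10L,
                       l = 7L), class = "pc_path_stats")
  expect_equal(bound_score(st, alpha = 0.5, l = 7), 12.6)
  expect_equal(bound_score(st, alpha = 0), 1.7 * 7)
  expect_equal(bound_score(st, alpha = 0.5, l = 7, per_edge = TRUE),
               1.8 * 6)
  alphas <- seq(0, 2, by = 0.5)
  expect_true(all(diff(sapply(alphas, function(a) bound_score(st, a))) > 0))
})

test_that("the search returns the unique path of a colorful path graph", {
  g <- path_graph(5, weights = c(0.3, 0.7, 0.2, 0.9))
  res <- astar_colorful_path(g, colorful_coloring(g), "A", "E",
                             search_config(l = 5, d = 2))
  expect_equal(res$nodes[[1]], LETTERS[1:5])
  expect_equal(res$weight, sum(c(0.3, 0.7, 0.2, 0.9)))
  expect_true(res$colorful)
})

test_that("unbounded search equals the brute-force colorful optimum", {
  n_checked <- 0
  for (seed in 1:30) {
    g <- random_weighted_graph(sample(c(8, 10, 12), 1), 0.35, seed = seed)
    nodes <- graph_nodes(g)
    l <- sample(3:5, 1)
    coloring <- random_coloring(g, k = l + 1, seed = seed)
    st <- nodes[1]; en <- nodes[length(nodes)]
    oracle <- oracle_min_colorful(g, coloring, st, en, l)
    got <- astar_colorful_path(g, coloring, st, en,
                               search_config(l = l, d = 1), bound = Inf)
    if (is.null(oracle)) {
      expect_null(got, info = paste("seed", seed))
    } else {
      n_checked <- n_checked + 1
      expect_equal(got$weight, oracle$weight, info = paste("seed", seed))
      expect_equal(got$nodes[[1]], oracle$path, info = paste("seed", seed))
    }
  }
  expect_gt(n_checked, 5)   # the sweep must actually exercise hits
})

test_that("a bound below the optimum prunes everything; above keeps it", {
  g <- path_graph(6, weights = rep(1, 5))
  coloring <- colorful_coloring(g)
  cfg <- search_config(l = 6, d = 2)
  opt <- astar_colorful_path(g, coloring, "A", "F", cfg, bound = Inf)
  expect_equal(opt$weight, 5)
  expect_null(astar_colorful_path(g, coloring, "A", "F", cfg,
                                  bound = opt$weight - 0.5))
  again <- astar_colorful_path(g, coloring, "A", "F", cfg,
                               bound = opt$weight + 1e-6)
  expect_equal(again$nodes[[1]], opt$nodes[[1]])
})

test_that("weight ties resolve to the lexicographically smaller sequence", {
  # two disjoint A..D routes with identical total weight
  g <- named_graph(cbind(c("A", "B", "A", "C"),
                         c("B", "D", "C", "D")), rep(1, 4))
  coloring <- structure(list(color = c(A = 1L, B = 2L, C = 2L, D = 3L),
                             k = 3L), class = "pc_coloring")
  res <- astar_colorful_path(g, coloring, "A", "D", search_config(l = 3, d = 1))
  expect_equal(res$nodes[[1]], c("A", "B", "D"))
})

test_that("location monotonicity excludes rank-decreasing paths", {
  g <- named_graph(cbind(c("A", "B", "A", "C"),
                         c("B", "D", "C", "D")), c(1, 1, 5, 5))
  coloring <- structure(list(color = c(A = 1L, B = 2L, C = 2L, D = 3L),
                             k = 3L), class = "pc_coloring")
  # cheap route goes through B, but B sits below A's compartment
  loc <- c(A = 2L, B = 1L, C = NA_integer_, D = 3L)
  cfg <- search_config(l = 3, d = 1)
  free <- astar_colorful_path(g, coloring, "A", "D", cfg)
  expect_equal(free$nodes[[1]], c("A", "B", "D"))
  constrained <- astar_colorful_path(g, coloring, "A", "D", cfg,
                                     locations = loc)
  expect_equal(constrained$nodes[[1]], c("A", "C", "D"))  # wildcard C is fine
  expect_true(constrained$location_valid)
  expect_true(path_location_valid(c("A", "C", "D"), loc))
  expect_false(path_location_valid(c("A", "B", "D"), loc))
})

test_that("the unbounded search also matches the oracle under locations", {
  for (seed in 31:45) {
    g <- random_weighted_graph(10, 0.4, seed = seed)
    nodes <- graph_nodes(g)
    loc <- withr::with_seed(seed, stats::setNames(
      sample(c(1L, 2L, 3L, NA_integer_), length(nodes), replace = TRUE),
      nodes))
    coloring <- random_coloring(g, k = 5, seed = seed)
    s <- nodes[1]; t <- nodes[length(nodes)]
    oracle <- oracle_min_colorful(g, coloring, s, t, 4, loc)
    got <- astar_colorful_path(g, coloring, s, t,
                               search_config(l = 4, d = 1), locations = loc)
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(got$weight, oracle$weight, info = paste("seed", seed))
    }
  }
})

test_that("raising alpha never loses the optimum once the bound covers it", {
  g <- random_weighted_graph(10, 0.5, seed = 77)
  nodes <- graph_nodes(g)
  coloring <- random_coloring(g, k = 5, seed = 77)
  cfg0 <- search_config(l = 4, d = 1)
  s <- nodes[1]; t <- nodes[length(nodes)]
  opt <- astar_colorful_path(g, coloring, s, t, cfg0, bound = Inf)
  expect_false(is.null(opt))   # this instance does have colorful 4-paths
  st <- sample_path_stats(g, l = 4, n_samples = 500, seed = 1)
  weights <- c()
  for (alpha in c(0.5, 1, 2, 4)) {
    b <- bound_score(st, alpha, 4)
    res <- astar_colorful_path(g, coloring, s, t, cfg0, bound = b)
    if (b >= opt$weight) expect_equal(res$weight, opt$weight)
    if (!is.null(res)) weights <- c(weights, res$weight)
  }
  expect_true(all(diff(weights) <= 1e-9))  # non-increasing in alpha
})

test_that("restart search recovers the planted path and reproduces", {
  inst <- synthetic_instance(40, 5, seed = 5)
  cfg <- search_config(l = 5, d = 2)
  n_col <- required_repetitions(5, 0.05)   # 443 colorings
  res1 <- search_with_restarts(inst$net, inst$path[1], inst$path[5], cfg,
                               n_colorings = n_col, seed = 9,
                               locations = inst$locations)
  res2 <- search_with_restarts(inst$net, inst$path[1], inst$path[5], cfg,
                               n_colorings = n_col, seed = 9,
                               locations = inst$locations)
  expect_identical(res1$nodes, res2$nodes)
  expect_gt(nrow(res1), 0)
  expect_equal(res1$nodes[[1]], inst$path)
  expect_true(all(diff(res1$weight) >= 0))
  expect_false(any(duplicated(vapply(res1$nodes, paste, character(1),
                                     collapse = ">"))))
  td <- tidy(res1)
  expect_equal(td$length[1], 5L)
  expect_s3_class(ggplot2::autoplot(res1), "ggplot")
  expect_equal(glance(res1)$best_weight, res1$weight[1])
})

test_that("default repetition count comes from the failure-rate formula", {
  cfg <- search_config(l = 8, d = 3)
  expect_equal(eval(formals(search_with_restarts)$n_colorings,
                    list(config = cfg)),
               required_repetitions(8, 0.05))
})

test_that("assembly keeps only paths hitting half the main chain", {
  chain <- sprintf("M%02d", 1:11)
  p1 <- c(chain[1:6], sprintf("X%d", 1:3))            # 6/11 hits
  p2 <- c(chain[1:2], sprintf("Y%d", 1:5))            # 2/11 hits
  net <- assemble_network(list(p1, p2), chain)
  expect_setequal(igraph::V(net)$name, p1)
  expect_equal(igraph::ecount(net), length(p1) - 1)
  # empty path list -> empty network
  expect_equal(igraph::vcount(assemble_network(list(), chain)), 0)
  expect_error(assemble_network(list(p1), character(0)), "non-empty")
})

test_that("assembled subnetworks are unions of the retained paths", {
  inst <- synthetic_instance(30, 5, seed = 21)
  cfg <- search_config(l = 5, d = 2)
  res <- search_with_restarts(inst$net, inst$path[1], inst$path[5], cfg,
                              n_colorings = 10, seed = 3)
  sub <- assemble_network(res, inst$path, net = inst$net)
  keep <- Filter(function(p) length(intersect(p, inst$path)) >= 3, res$nodes)
  expect_setequal(igraph::V(sub)$name, unique(unlist(keep)))
  # subgraph of the input network: every edge must exist there
  el <- igraph::as_edgelist(sub)
  if (nrow(el) > 0) {
    expect_true(all(igraph::get_edge_ids(inst$net, c(t(el))) > 0))
  }
})
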