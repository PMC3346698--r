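#' Read an undirected PPI edge list from TSV
#'
#' Expects two tab-separated columns (protein_a, protein_b) with no header;
#' an optional third column supplies precomputed edge weights.  Duplicate
#' rows and reversed duplicates collapse to one undirected edge; self-loops
#' are dropped with a message.  Edge weights default to `NA` until
#' [assign_weights()] fills them.
#'
#' @param path Path to the edge-list TSV.
#' @return An undirected [igraph::igraph] with a `weight` edge attribute.
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (ncol(df) < 2) stop("edge list needs at least 2 columns")
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]))
  if (length(bad) > 0) stop("malformed edge-list row at line ", bad[1])
  w <- if (ncol(df) >= 3) suppressWarnings(as.numeric(df[[3]])) else
    rep(NA_real_, nrow(df))
  loops <- df[[1]] == df[[2]]
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
  }
  edges_from_pairs(df[[1]][!loops], df[[2]][!loops], w[!loops])
}

# Build a simple undirected weighted graph from endpoint vectors,
# collapsing duplicates and reversed duplicates (first weight wins).
edges_from_pairs <- function(a, b, w = rep(NA_real_, length(a))) {
  if (length(a) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(lo[keep], hi[keep]), directed = FALSE)
  igraph::E(g)$weight <- w[keep]
  g
}

#' Write a network as an edge-list TSV
#'
#' @param net An igraph network.
#' @param path Output path.
#' @param weights Include the weight column (default `TRUE` when any
#'   weight is set).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path,
                            weights = !is.null(igraph::E(net)$weight)) {
  el <- igraph::as_edgelist(net)
  df <- tibble::tibble(a = el[, 1], b = el[, 2])
  if (weights) df$w <- igraph::E(net)$weight
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Weight network edges by expression correlation
#'
#' Each edge (u, v) with both endpoints in the expression matrix receives
#' weight `-log(max(|r|, epsilon))` where r is the Pearson correlation of
#' the two genes.  The absolute value captures inhibition as well as
#' activation; the negative log turns strong co-expression into small
#' weight so pathway detection becomes minimum-weight path search.  Edges
#' whose endpoints lack expression data, or whose correlation is
#' undefined, receive the cap weight `-log(epsilon)` (kept rather than
#' deleted so articulation structure is preserved; see `drop_unmatched`).
#'
#' @param net Undirected igraph network.
#' @param mat Imputed (complete) expression matrix.
#' @param epsilon Correlation floor in (0, 1); default 1e-4, giving a cap
#'   weight of about 9.21 in natural log.
#' @param base `"natural"` (default) or `"10"`; the base uniformly rescales
#'   all weights and cannot change any minimum-weight path.
#' @param drop_unmatched If `TRUE`, delete edges without expression support
#'   instead of capping them.
#' @return The network with finite nonnegative `weight` on every edge.
#' @export
assign_weights <- function(net, mat, epsilon = 1e-4,
                           base = c("natural", "10"),
                           drop_unmatched = FALSE) {
  base <- match.arg(base)
  stopifnot(epsilon > 0, epsilon < 1)
  logf <- if (base == "natural") log else log10
  el <- igraph::as_edgelist(net)
  cap <- -logf(epsilon)
  n_unmatched <- 0L
  w <- vapply(seq_len(nrow(el)), function(i) {
    u <- el[i, 1]; v <- el[i, 2]
    if (!(u %in% rownames(mat)) || !(v %in% rownames(mat))) {
      n_unmatched <<- n_unmatched + 1L
      return(NA_real_)
    }
    r <- pairwise_correlation(mat, u, v)
    if (is.na(r)) return(NA_real_)
    -logf(max(abs(r), epsilon))
  }, numeric(1))
  if (n_unmatched > 0) {
    message(n_unmatched, " edge(s) without expression support ",
            if (drop_unmatched) "dropped" else "kept at the cap weight")
  }
  if (drop_unmatched) {
    keep <- !is.na(w)
    net <- igraph::delete_edges(net, which(!keep))
    igraph::E(net)$weight <- w[keep]
  } else {
    w[is.na(w)] <- cap
    igraph::E(net)$weight <- w
  }
  net
}

#' Read a cellular-location map from TSV
#'
#' Two tab-separated columns, no header: protein id, then either an integer
#' rank or a compartment name from the ordered vocabulary membrane (1),
#' cytoplasm (2), nucleus (3).  "intracellular" maps to the wildcard `NA`,
#' compatible with any rank; proteins absent from the map are likewise
#' treated as wildcards downstream.
#'
#' @param path Path to the location TSV.
#' @return A named integer vector of ranks (possibly `NA` for wildcards).
#' @export
read_locations <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) return(stats::setNames(integer(0), character(0)))
  if (ncol(df) < 2) stop("location TSV needs 2 columns")
  val <- df[[2]]
  rank <- suppressWarnings(as.integer(val))
  named <- is.na(rank) & !is.na(val)
  if (any(named)) {
    unknown <- setdiff(unique(tolower(val[named])), names(location_vocabulary))
    if (length(unknown) > 0) stop("unknown compartment(s): ",
                                  paste(unknown, collapse = ", "))
    rank[named] <- location_vocabulary[tolower(val[named])]
  }
  stats::setNames(rank, df[[1]])
}

#' Write a location map as TSV
#'
#' @param locations Named integer vector of location ranks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locations <- function(locations, path) {
  df <- tibble::tibble(protein = names(locations),
                       rank = unname(locations))
  readr::write_tsv(df, path, col_names = FALSE, na = "NA", progress = FALSE)
  invisible(path)
}
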