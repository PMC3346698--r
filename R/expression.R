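#' Read a gene-expression matrix from TSV
#'
#' Expression values are log2 ratios, one gene per row.  The first column
#' holds the gene identifier, the header row the sample identifiers.
#' Empty cells or the string `"NA"` mark missing values.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes x samples) with gene ids as rownames,
#'   sample ids as colnames and `NA` for missing entries.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene-id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in expression TSV")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' Write an expression matrix as TSV
#'
#' Round-trips with [read_expression_tsv()].
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Drop genes with too many missing values
#'
#' Keeps exactly the genes whose fraction of missing entries is *strictly*
#' below `max_missing_frac`; a gene missing 2 of 10 entries is removed at
#' the default 0.2 threshold.  Sample set and gene order are preserved.
#'
#' @param mat Expression matrix (genes x samples, `NA` = missing).
#' @param max_missing_frac Missingness threshold in `[0, 1]`; default 0.2.
#' @return The filtered matrix.  Warns (does not error) if no gene survives.
#' @export
filter_missing <- function(mat, max_missing_frac = 0.2) {
  stopifnot(is.matrix(mat), max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(mat))
  keep <- frac < max_missing_frac
  if (!any(keep)) warning("no genes pass the missingness filter")
  mat[keep, , drop = FALSE]
}

# Mean squared difference between gene g and every other row over mutually
# observed samples; Inf when no sample is shared (neighbour ineligible).
knn_distances <- function(mat, g) {
  x <- mat[g, ]
  sq <- sweep(mat, 2, x)^2
  shared <- rowSums(!is.na(sq))
  d <- rowMeans(sq, na.rm = TRUE)
  d[shared == 0] <- Inf
  d[g] <- Inf
  d
}

#' Impute missing expression values by K nearest neighbours
#'
#' For each missing cell, the k genes nearest in mean squared difference
#' over mutually observed samples -- among genes observed at that sample --
#' supply the imputed value as their unweighted mean.  Distance ties break
#' by gene-id lexicographic order, so the result is deterministic.  With
#' fewer than k eligible neighbours all eligible ones are used; with none,
#' the gene's own observed median is used.
#'
#' @param mat Expression matrix (genes x samples, `NA` = missing), already
#'   filtered with [filter_missing()].
#' @param k_neighbors Number of neighbours (>= 1); default 15, the
#'   neighbourhood size at which imputation error bottoms out on arrays
#'   with ~20% missingness.
#' @param seed Unused (imputation is deterministic); accepted so callers
#'   can treat all pipeline stages uniformly.
#' @param weighted If `TRUE`, neighbour values are averaged with weights
#'   `1/(d + 1e-12)` instead of the default unweighted mean.
#' @return The completed matrix (no `NA` left); observed cells unchanged.
#' @export
impute_knn <- function(mat, k_neighbors = 15, seed = NULL, weighted = FALSE) {
  stopifnot(is.matrix(mat), k_neighbors >= 1)
  miss <- is.na(mat)
  if (!any(miss)) return(mat)
  empty <- rowSums(!miss) == 0
  if (any(empty)) {
    stop("gene(s) with zero observed entries: ",
         paste(head(rownames(mat)[empty], 5), collapse = ", "))
  }
  out <- mat
  ids <- rownames(mat)
  lex <- order(ids)               # tie-break order
  lex_rank <- integer(length(ids)); lex_rank[lex] <- seq_along(lex)
  for (g in which(rowSums(miss) > 0)) {
    d <- knn_distances(mat, g)
    ord <- order(d, lex_rank)     # nearest first, ties lexicographic
    for (j in which(miss[g, ])) {
      elig <- ord[is.finite(d[ord]) & !miss[ord, j]]
      if (length(elig) == 0) {
        out[g, j] <- median(mat[g, ], na.rm = TRUE)
      } else {
        nb <- elig[seq_len(min(k_neighbors, length(elig)))]
        if (weighted) {
          w <- 1 / (d[nb] + 1e-12)
          out[g, j] <- sum(w * mat[nb, j]) / sum(w)
        } else {
          out[g, j] <- mean(mat[nb, j])
        }
      }
    }
  }
  out
}

#' Summarize a gene's expression
#'
#' Reports the median of the observed log2 ratios and an over/under call:
#' "over" when the summed magnitude of positive log2 ratios exceeds the
#' summed magnitude of negative ones, "under" otherwise (ties fall to
#' "under").
#'
#' @param mat Expression matrix.
#' @param gene Gene identifier (must be present with >= 1 observed entry).
#' @return A one-row tibble: `gene_id`, `median_log2`, `call`.
#' @export
summarize_gene <- function(mat, gene) {
  if (!gene %in% rownames(mat)) stop("unknown gene: ", gene)
  x <- mat[gene, ]
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("gene has no observed entries: ", gene)
  pos <- sum(x[x > 0])
  neg <- -sum(x[x < 0])
  tibble::tibble(gene_id = gene,
                 median_log2 = median(x),
                 call = if (pos > neg) "over" else "under")
}

#' Pearson correlation between two genes
#'
#' Computed over mutually observed samples.  Returns `NA` (an explicit
#' undefined-correlation signal, distinct from 0) when fewer than 3 samples
#' are shared or either gene has zero variance on the shared samples.
#'
#' @param mat Expression matrix.
#' @param u,v Gene identifiers.
#' @return Pearson r in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pairwise_correlation <- function(mat, u, v) {
  for (g in c(u, v)) if (!g %in% rownames(mat)) stop("unknown gene: ", g)
  x <- mat[u, ]; y <- mat[v, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Imputation accuracy by deletion experiment
#'
#' Deletes `n_deleted` observed cells uniformly at random from a complete
#' matrix, re-imputes them with [impute_knn()], and returns the root mean
#' squared error between imputed and original values.
#'
#' @param mat Complete expression matrix (no `NA`).
#' @param n_deleted Number of cells to delete (<= total cell count).
#' @param k_neighbors Neighbourhood size for imputation.
#' @param seed Integer seed driving the random deletions.
#' @return RMSE as a single number; deterministic given `seed`.
#' @export
evaluate_imputation_rmse <- function(mat, n_deleted, k_neighbors = 15,
                                     seed = 1L) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) stop("matrix must be complete (no missing values)")
  if (n_deleted > length(mat)) stop("n_deleted exceeds the cell count")
  if (n_deleted == 0) return(0)
  del <- withr::with_seed(seed, sample.int(length(mat), n_deleted))
  holed <- mat
  holed[del] <- NA_real_
  imp <- impute_knn(holed, k_neighbors = k_neighbors)
  sqrt(mean((imp[del] - mat[del])^2))
}

#' RMSE curve over a range of neighbourhood sizes
#'
#' Runs the deletion experiment of [evaluate_imputation_rmse()] once per
#' `k`, reusing the same random deletions so the curve isolates the effect
#' of the neighbourhood size.
#'
#' @param mat Complete expression matrix.
#' @param k_values Integer vector of neighbourhood sizes to sweep.
#' @param n_deleted Number of cells to delete.
#' @param seed Integer seed (same deletions for every `k`).
#' @return A tibble with columns `k` and `rmse`, classed for [autoplot()].
#' @export
imputation_rmse_curve <- function(mat, k_values = 1:20, n_deleted,
                                  seed = 1L) {
  res <- purrr::map_dfr(k_values, function(k) {
    tibble::tibble(k = as.integer(k),
                   rmse = evaluate_imputation_rmse(mat, n_deleted,
                                                   k_neighbors = k,
                                                   seed = seed))
  })
  class(res) <- c("pc_rmse_curve", class(res))
  res
}

#' @exportS3Method ggplot2::autoplot
autoplot.pc_rmse_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of nearest neighbours (k)",
                  y = "imputation RMSE") +
    ggplot2::theme_minimal()
}
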