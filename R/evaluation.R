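#' F-measure from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`; 0 when both are 0.  Accepts either
#' proportions or percentages (both arguments on the same scale).
#'
#' @param precision,recall Values in `[0, 1]` (or both in `[0, 100]`).
#' @return The F-measure on the proportion scale.
#' @export
f_measure <- function(precision, recall) {
  if (max(precision, recall) > 1) {       # percentage inputs
    precision <- precision / 100
    recall <- recall / 100
  }
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and F against a reference pathway
#'
#' Precision is the fraction of detected proteins that are in the
#' reference main chain; recall the fraction of the main chain that was
#' detected; F their harmonic mean.
#'
#' @param detected Node set (character vector) detected by the method.
#' @param reference Non-empty reference node set (the main chain).
#' @return A one-row tibble: `precision`, `recall`, `f_measure`,
#'   `n_detected`, `n_reference`, `n_hit`.
#' @export
precision_recall_f <- function(detected, reference) {
  if (length(reference) == 0) stop("reference set must be non-empty")
  detected <- unique(detected)
  reference <- unique(reference)
  hit <- length(intersect(detected, reference))
  p <- if (length(detected) > 0) hit / length(detected) else 0
  r <- hit / length(reference)
  tibble::tibble(precision = p, recall = r,
                 f_measure = f_measure(p, r),
                 n_detected = length(detected),
                 n_reference = length(reference),
                 n_hit = hit)
}

#' Hypergeometric enrichment of a gene set
#'
#' Term-by-term upper-tail hypergeometric test: the probability of seeing
#' at least the observed overlap between the path's genes and each term's
#' annotated genes, given `|path|` draws from the background.  Optional
#' Bonferroni correction multiplies each P by the number of terms (capped
#' at 1).
#'
#' @param path_genes Genes on the detected path (subset of `background`).
#' @param term_sets Named list of annotation gene sets (each a subset of
#'   `background`).
#' @param background Non-empty background gene universe.
#' @param correct Apply Bonferroni correction; default `TRUE`.
#' @return A tibble with one row per term: `term`, `n_term`, `n_overlap`,
#'   `p_value`, `p_adjusted`.
#' @export
hypergeometric_enrichment <- function(path_genes, term_sets, background,
                                      correct = TRUE) {
  if (length(background) == 0) stop("background must be non-empty")
  background <- unique(background)
  path_genes <- unique(path_genes)
  if (!all(path_genes %in% background)) {
    stop("path_genes must be a subset of background")
  }
  n_terms <- length(term_sets)
  res <- purrr::imap_dfr(term_sets, function(set, term) {
    set <- unique(set)
    if (!all(set %in% background)) {
      stop("term set '", term, "' is not a subset of background")
    }
    q <- length(intersect(path_genes, set))
    # P(X >= q) with X ~ Hypergeom(|set| successes, N - |set| failures,
    # |path| draws)
    p <- stats::phyper(q - 1, length(set),
                       length(background) - length(set),
                       length(path_genes), lower.tail = FALSE)
    tibble::tibble(term = term, n_term = length(set),
                   n_overlap = as.integer(q), p_value = p)
  })
  res$p_adjusted <- if (correct) pmin(res$p_value * n_terms, 1) else
    res$p_value
  res
}

#' Read a reference main-chain pathway
#'
#' One protein per line, in pathway order.
#'
#' @param path File path.
#' @return Character vector of protein ids.
#' @export
read_main_chain <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}
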