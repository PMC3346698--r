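make_matrix <- function(values, genes, samples = NULL) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE)
  rownames(m) <- genes
  colnames(m) <- if (is.null(samples)) sprintf("S%d", seq_len(ncol(m))) else
    samples
  m
}

test_that("missingness filter is strict, order-preserving and idempotent", {
  m <- make_matrix(rep(1, 50), paste0("G", 1:5))
  m["G3", 1:3] <- NA          # 3/10 missing
  m["G5", 1:2] <- NA          # exactly 20% missing
  out <- filter_missing(m, 0.2)
  expect_setequal(rownames(out), c("G1", "G2", "G4"))  # strict "<"
  expect_identical(rownames(out), c("G1", "G2", "G4")) # order kept
  expect_identical(colnames(out), colnames(m))
  expect_identical(filter_missing(out, 0.2), out)      # idempotent
  # nothing missing -> identity
  complete <- make_matrix(rnorm(20), paste0("G", 1:2))
  expect_identical(filter_missing(complete, 0.2), complete)
  expect_warning(filter_missing(m, 0), "no genes")
})

test_that("KNN imputation matches the nearest-row oracle and its fallbacks", {
  m <- make_matrix(c(1, 2, 3, 4,
                     1.1, 2.1, 3.1, 4.1,
                     10, 9, 8, 7), c("A", "B", "C"))
  holed <- m
  holed["A", 2] <- NA
  out <- impute_knn(holed, k_neighbors = 1)
  # brute-force nearest row over all candidates observed at column 2
  d <- sapply(c("B", "C"), function(h)
    mean((holed["A", ] - holed[h, ])^2, na.rm = TRUE))
  expect_equal(out["A", 2], holed[names(which.min(d)), 2])
  expect_identical(out[!is.na(holed)], holed[!is.na(holed)])
  expect_false(anyNA(out))

  # no missing values -> identity
  expect_identical(impute_knn(m, 3), m)

  # all other genes masked at that column -> gene's own observed median
  h2 <- m
  h2["A", 2] <- NA
  h2["B", 2] <- NA
  h2["C", 2] <- NA
  out2 <- impute_knn(h2, k_neighbors = 2)
  expect_equal(out2["A", 2], median(h2["A", ], na.rm = TRUE))

  # a gene with zero observed entries is an error
  h3 <- m
  h3["A", ] <- NA
  expect_error(impute_knn(h3, 1), "zero observed")
})

test_that("imputation never alters observed cells and empties the mask", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, {
      mm <- matrix(rnorm(30 * 12), nrow = 30,
                   dimnames = list(sprintf("G%02d", 1:30),
                                   sprintf("S%02d", 1:12)))
      mm[sample.int(length(mm), 40)] <- NA
      mm
    })
    m <- filter_missing(m, 0.5)
    out <- impute_knn(m, k_neighbors = 4)
    expect_false(anyNA(out))
    obs <- !is.na(m)
    expect_identical(out[obs], m[obs])
  }
})

test_that("gene summaries use observed medians and the magnitude-sum call", {
  m <- make_matrix(c(1, 2, 4,
                     -1, -2, 3,
                     0.5, NA, NA), c("up", "down", "single"))
  s1 <- summarize_gene(m, "up")
  expect_equal(s1$median_log2, 2)
  expect_equal(s1$call, "over")
  expect_equal(summarize_gene(m, "down")$call, "under")  # |neg| ties |pos|
  s3 <- summarize_gene(m, "single")
  expect_equal(s3$median_log2, 0.5)
  expect_equal(s3$call, "over")
  expect_error(summarize_gene(m, "nope"), "unknown gene")
})

test_that("pairwise correlation matches the closed form and its invariances", {
  m <- make_matrix(c(1, 2, 3,
                     1, 2, 4,
                     1, 2, 3,
                     -1, -2, -3,
                     5, 5, 5), c("a", "b", "a2", "neg", "const"))
  expect_equal(pairwise_correlation(m, "a", "a2"), 1)
  expect_equal(pairwise_correlation(m, "a", "neg"), -1)
  expect_equal(pairwise_correlation(m, "a", "b"), 9 / sqrt(84))
  # symmetric, and invariant under positive affine rescaling
  expect_equal(pairwise_correlation(m, "a", "b"),
               pairwise_correlation(m, "b", "a"))
  m2 <- rbind(m, b_scaled = 3 * m["b", ] + 7)
  expect_equal(pairwise_correlation(m2, "a", "b_scaled"),
               pairwise_correlation(m2, "a", "b"))
  # undefined cases signal NA, not zero
  expect_true(is.na(pairwise_correlation(m, "a", "const")))
  m3 <- make_matrix(c(1, 2, NA, NA,
                      NA, NA, 3, 4), c("x", "y"))
  expect_true(is.na(pairwise_correlation(m3, "x", "y")))
})

test_that("imputation RMSE experiment is seeded and degenerate cases are 0", {
  m <- withr::with_seed(9, {
    z <- rnorm(20)
    rbind(g1 = z + rnorm(20, sd = 0.1),
          g2 = z + rnorm(20, sd = 0.1),
          g3 = z + rnorm(20, sd = 0.1),
          g4 = rnorm(20))
  })
  colnames(m) <- sprintf("S%d", 1:20)
  expect_equal(evaluate_imputation_rmse(m, 0), 0)
  const <- matrix(2, 4, 10, dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  expect_equal(evaluate_imputation_rmse(const, 5, k_neighbors = 2, seed = 3), 0)
  r1 <- evaluate_imputation_rmse(m, 10, k_neighbors = 2, seed = 11)
  r2 <- evaluate_imputation_rmse(m, 10, k_neighbors = 2, seed = 11)
  expect_identical(r1, r2)
  expect_error(evaluate_imputation_rmse(m, length(m) + 1), "exceeds")
})

test_that("the RMSE curve reuses deletions and reproduces under the seed", {
  n_genes <- 30
  m <- withr::with_seed(4, {
    z <- matrix(rnorm(8 * 25), 8)
    load <- matrix(rnorm(n_genes * 8, sd = 0.6), n_genes)
    load %*% z + matrix(rnorm(n_genes * 25, sd = 0.3), n_genes)
  })
  dimnames(m) <- list(sprintf("G%02d", 1:n_genes), sprintf("S%02d", 1:25))
  curve1 <- imputation_rmse_curve(m, k_values = c(1, 3, 6, 10), n_deleted = 40,
                                  seed = 2)
  curve2 <- imputation_rmse_curve(m, k_values = c(1, 3, 6, 10), n_deleted = 40,
                                  seed = 2)
  expect_equal(curve1$rmse, curve2$rmse)
  expect_true(all(curve1$rmse > 0))
  p <- ggplot2::autoplot(curve1)
  expect_s3_class(p, "ggplot")
})

test_that("expression TSV round-trips with missing values intact", {
  m <- make_matrix(c(1.5, NA, -2, 0, 3.25, NA), c("G1", "G2"),
                   c("S1", "S2", "S3"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(m, f)
  back <- read_expression_tsv(f)
  expect_equal(back, m)
})
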