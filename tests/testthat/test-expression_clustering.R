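make_mat <- function(values, genes, conds = NULL) {
  m <- matrix(values, nrow = length(genes))
  if (is.null(conds)) conds <- paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, conds)
  m
}

test_that("bottom-quantile filtering applies the all/any policy by rank", {
  m <- make_mat(c(10, 8, 6, 4, 1,
                  20, 16, 12, 9, 2), genes = LETTERS[1:5])
  got <- filter_low_expression(m, quantile = 0.20, policy = "all")
  expect_identical(got$removed, "E")     # lowest in both conditions
  expect_identical(rownames(got$matrix), LETTERS[1:4])
  # lowest in condition 1 but highest in condition 2
  m2 <- make_mat(c(1, 5, 6, 7, 8,
                   99, 4, 5, 6, 7), genes = LETTERS[1:5])
  expect_false("A" %in% filter_low_expression(m2, 0.2, "all")$removed)
  expect_true("A" %in% filter_low_expression(m2, 0.2, "any")$removed)
  expect_error(filter_low_expression(m, quantile = 1.2), "quantile")
})

test_that("tied expression is filtered deterministically by gene id", {
  m <- make_mat(rep(5, 10), genes = LETTERS[1:5])
  for (pol in c("all", "any")) {
    got <- filter_low_expression(m, 0.20, pol)
    expect_identical(got$removed, "A")   # floor(0.2*5) = 1, first id
  }
  # invariant under row permutation
  perm <- m[c(3, 1, 5, 2, 4), ]
  expect_identical(sort(filter_low_expression(perm, 0.2, "all")$removed),
                   "A")
})

test_that("standardization gives exact mean-0 sd-1 rows, excluding constants", {
  m <- make_mat(c(1, 5, 7, 5), genes = c("g1", "g2"))  # g1: log2 -> 1, 3
  got <- transform_standardize(m, pseudocount = 1)
  expect_equal(unname(got$matrix["g1", ]), c(-1, 1))
  expect_identical(got$excluded, "g2")
  set.seed(3)
  m2 <- make_mat(runif(40, 0, 50), genes = sprintf("g%02d", 1:8),
                 conds = paste0("c", 1:5))
  z <- transform_standardize(m2)$matrix
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(z^2)) - 1)), 1e-9)
})

test_that("well-separated planted archetypes are recovered exactly", {
  ex <- simulate_expression(expression_sim_config(
    n_genes = c(30L, 30L), gene_noise_sd = 0.1, planted = NULL,
    n_null_categories = 0L, seed = 7))
  z <- transform_standardize(ex$rpkm)$matrix
  cl <- cluster_genes(z, k = 2)
  expect_equal(adjusted_rand(cl$labels, ex$truth_labels[names(cl$labels)]),
               1.0)
})

test_that("small clusterings match a brute-force average-linkage oracle", {
  for (s in 1:6) {
    set.seed(s)
    z <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(letters[1:8], paste0("c", 1:5)))
    for (k in c(2, 3, 4)) {
      got <- cluster_genes(z, k)$labels
      parts <- brute_average_linkage(dist(z), k)
      oracle <- integer(8); names(oracle) <- letters[1:8]
      for (i in seq_along(parts)) oracle[parts[[i]]] <- i
      expect_identical(partition_signature(got),
                       partition_signature(oracle))
    }
  }
})

test_that("clustering is permutation-equivariant and duplication-invariant", {
  set.seed(11)
  ex <- simulate_expression(expression_sim_config(
    n_genes = c(15L, 15L, 15L), gene_noise_sd = 0.2, planted = NULL,
    n_null_categories = 0L, seed = 11))
  z <- transform_standardize(ex$rpkm)$matrix
  base <- cluster_genes(z, 3)$labels
  perm <- sample(nrow(z))
  shuffled <- cluster_genes(z[perm, ], 3)$labels
  expect_identical(partition_signature(base),
                   partition_signature(shuffled))
  # duplicating every gene leaves the originals' partition unchanged
  dup <- rbind(z, `rownames<-`(z, paste0(rownames(z), "_copy")))
  dup_labels <- cluster_genes(dup, 3)$labels[rownames(z)]
  expect_identical(partition_signature(base),
                   partition_signature(dup_labels))
  expect_error(cluster_genes(z, nrow(z) + 1), "exceeds")
})

test_that("eigengenes are unit-norm rank-1 summaries with a sign convention", {
  p <- c(2, -1, 0.5, -3)
  z <- make_mat(rep(p, each = 4), genes = paste0("g", 1:4),
                conds = paste0("c", 1:4))
  labels <- setNames(rep(1L, 4), rownames(z))
  got <- compute_eigengenes(z, labels)
  expect_equal(unname(got$eigengenes[1, ]), p / sqrt(sum(p^2)))
  expect_equal(unname(got$variance_explained[[1]]), 1.0)
  # sign: non-negative correlation with the cluster mean profile
  set.seed(5)
  ex <- simulate_expression(expression_sim_config(
    n_genes = c(40L, 40L), gene_noise_sd = 0.4, planted = NULL,
    n_null_categories = 0L, seed = 5))
  z2 <- transform_standardize(ex$rpkm)$matrix
  lab <- cluster_genes(z2, 2)$labels
  eg <- compute_eigengenes(z2, lab)
  for (cl in rownames(eg$eigengenes)) {
    mp <- colMeans(z2[names(lab)[lab == as.integer(cl)], , drop = FALSE])
    expect_gte(cor(eg$eigengenes[cl, ], mp), 0)
  }
})

test_that("eigengenes ignore positive per-gene scale factors", {
  ex <- simulate_expression(expression_sim_config(
    n_genes = c(25L, 25L), gene_noise_sd = 0.2, planted = NULL,
    n_null_categories = 0L, seed = 9))
  z <- transform_standardize(ex$rpkm, pseudocount = 0)$matrix
  lab <- cluster_genes(z, 2)$labels
  e1 <- compute_eigengenes(z, lab)$eigengenes
  set.seed(9)
  scaled <- ex$rpkm * runif(nrow(ex$rpkm), 0.2, 5)
  z2 <- transform_standardize(scaled, pseudocount = 0)$matrix
  e2 <- compute_eigengenes(z2, lab)$eigengenes
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("eigengene-phenotype correlation behaves like Pearson r", {
  v <- c(1, 2, 3, 5, 8)
  expect_equal(correlate_eigengene(v, 3 * v), 1)
  expect_equal(correlate_eigengene(v, -v), -1)
  # Gram-Schmidt orthogonal pair (after centring) has r = 0
  x <- c(1, 2, 3, 4, 5); xc <- x - mean(x)
  set.seed(2); y <- rnorm(5); yc <- y - mean(y)
  y_orth <- yc - sum(yc * xc) / sum(xc^2) * xc
  expect_lt(abs(correlate_eigengene(x, y_orth)), 1e-12)
  expect_warning(got <- correlate_eigengene(rep(1, 4), c(1, 2, 3, 4)),
                 "zero-variance")
  expect_true(is.na(got))
})

test_that("profile over-segmentation is healed by eigengene merging", {
  # six-way cut of a four-archetype matrix collapses back to four
  ex <- simulate_expression(expression_sim_config(
    n_genes = c(60L, 60L, 60L, 60L), gene_noise_sd = 0.3, planted = NULL,
    n_null_categories = 0L, seed = 13))
  res <- cluster_expression(ex$rpkm, k = 6, merge_r = 0.8)
  expect_equal(length(unique(res$profiles)), 6L)
  expect_equal(length(unique(res$labels)), 4L)
  expect_equal(adjusted_rand(res$labels, ex$truth_labels[names(res$labels)]),
               1.0)
})
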