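# Pearson r from the raw covariance definition
cor_oracle <- function(u, v) {
  cu <- u - mean(u)
  cv <- v - mean(v)
  sum(cu * cv) / sqrt(sum(cu^2) * sum(cv^2))
}

test_that("pairwise correlations match the definition-based oracle", {
  x <- tiny_matrix(n_genes = 3, n_a = 5, n_b = 3, seed = 44)
  r <- pairwise_correlation(x, gene_ids(x), "A")
  lx <- log2(x$values[, x$groups == "A"] + 1)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(r[i, j], cor_oracle(lx[i, ], lx[j, ]), tolerance = 1e-12)
  expect_true(all(diag(r) == 1))
  expect_equal(r, t(r))
})

test_that("perfectly mirrored profiles correlate at -1", {
  v <- exp(rbind(up = c(1, 2, 3, 4), down = c(4, 3, 2, 1)))
  colnames(v) <- paste0("s", 1:4)
  x <- expression_matrix(v, setNames(c("A", "A", "A", "B"), colnames(v)))
  lx <- log2(v[, 1:3] + 1)
  r <- cor_oracle(lx[1, ], lx[2, ])
  expect_lt(r, 0)
  # with exact mirroring on the analysis scale r is exactly -1
  v2 <- rbind(up = c(1, 2, 3, 9), down = c(3, 2, 1, 9))
  colnames(v2) <- paste0("s", 1:4)
  x2 <- expression_matrix(2^v2 - 1, setNames(c("A", "A", "A", "B"),
                                             colnames(v2)))
  r2 <- pairwise_correlation(x2, c("up", "down"), "A")
  expect_equal(r2["up", "down"], -1)
})

test_that("zero-variance genes give flagged missing correlations", {
  v <- rbind(flat = rep(2, 5), vary = c(1, 5, 2, 8, 3))
  colnames(v) <- paste0("s", 1:5)
  x <- expression_matrix(v, setNames(c(rep("A", 4), "B"), colnames(v)))
  expect_error(pairwise_correlation(x, rownames(v), "B"), "fewer than 3")
  r <- pairwise_correlation(x, rownames(v), "A")
  expect_true(is.na(r["flat", "vary"]))
  expect_equal(diag(r), c(flat = 1, vary = 1))
})

test_that("coordinate statistics summarise the off-diagonal pairs", {
  r1 <- matrix(1, 4, 4)
  st <- coordinate_statistic(r1)
  expect_equal(st$mean_r, 1)
  expect_equal(st$mean_r2, 1)
  expect_equal(st$n_pairs, 6)

  r2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  st2 <- coordinate_statistic(r2)
  expect_equal(st2$mean_r, 0.6)
  expect_equal(st2$mean_r2, 0.36)
  expect_equal(st2$squared_mean_r, 0.36)

  set.seed(50)
  x <- tiny_matrix(n_genes = 6, seed = 50)
  r <- pairwise_correlation(x, gene_ids(x), "A")
  st3 <- coordinate_statistic(r)
  ut <- r[upper.tri(r)]
  expect_equal(st3$mean_r, mean(ut))
  expect_equal(st3$mean_r2, mean(ut^2))
  expect_gte(st3$mean_r2, st3$squared_mean_r)  # Jensen
  # invariance under permutation of gene order
  perm <- sample(gene_ids(x))
  st4 <- coordinate_statistic(pairwise_correlation(x, perm, "A"))
  expect_equal(st4$mean_r, st3$mean_r)
  expect_error(coordinate_statistic(matrix(1, 1, 1)), "at least 2")
})

test_that("permutation test separates a planted module from chance", {
  cfg <- sim_config(n_genes = 150, de_fraction = 0, module_genes = 10,
                    module_correlation_a = 0.95, module_correlation_b = 0,
                    noise_sd = 0.5, seed = 60)
  gen <- generate_expression(cfg, generate_annotation(cfg))
  pt <- coordinate_permutation_test(gen$matrix, gen$truth$module_genes, "A",
                                    gene_ids(gen$matrix),
                                    n_permutations = 400, seed = 61)
  expect_equal(pt$perm_p, 1 / 401)

  # a single null draw larger than the observed statistic gives p = 1
  pt1 <- coordinate_permutation_test(gen$matrix, gen$truth$module_genes, "B",
                                     gene_ids(gen$matrix),
                                     n_permutations = 1, seed = 62)
  expect_lte(pt1$perm_p, 1)
  expect_gte(pt1$perm_p, 1 / 2)
  expect_error(
    coordinate_permutation_test(gen$matrix, gene_ids(gen$matrix), "A",
                                gene_ids(gen$matrix)[1:5]),
    "pool")
})

test_that("average-linkage clustering recovers planted blocks", {
  # two identical-profile genes merge first at distance 0
  v <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
             c = c(5, 1, 4, 2, 3))
  colnames(v) <- paste0("s", 1:5)
  x <- expression_matrix(v, setNames(c(rep("A", 4), "B"), colnames(v)))
  r <- pairwise_correlation(x, rownames(v), "A")
  cl <- cluster_correlation_matrix(r)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  first <- rownames(r)[-cl$hclust$merge[1, ]]
  expect_setequal(first, c("a", "b"))

  # block-diagonal correlation: each block contiguous in the leaf order
  set.seed(70)
  k <- 8
  blocks <- rep(c(1, 2), each = k / 2)
  f <- matrix(rnorm(2 * 12), 2)
  vals <- exp(f[blocks, ] + matrix(rnorm(k * 12, 0, 0.1), k))
  dimnames(vals) <- list(sprintf("g%d", 1:k), sprintf("s%02d", 1:12))
  xb <- expression_matrix(vals, setNames(rep(c("A", "B"), c(9, 3)),
                                         colnames(vals)))
  rb <- pairwise_correlation(xb, rownames(vals), "A")
  clb <- cluster_correlation_matrix(rb)
  pos <- match(rownames(vals), clb$order)
  expect_equal(max(pos[blocks == 1]) - min(pos[blocks == 1]), k / 2 - 1)
  expect_equal(max(pos[blocks == 2]) - min(pos[blocks == 2]), k / 2 - 1)

  # k = 2 is a single trivial merge
  cl2 <- cluster_correlation_matrix(rb[1:2, 1:2])
  expect_equal(length(cl2$order), 2)
})
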