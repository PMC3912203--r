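#' Pairwise Pearson correlation matrix of a gene set within one group
#'
#' Correlations are computed across the samples of the requested
#' phenotype group, by default on `log2(FPKM + 1)` values (set
#' `log_transform = FALSE` for linear FPKM). Genes with zero variance in
#' the group yield undefined correlations, returned as `NA`; the
#' diagonal is always 1.
#'
#' @param x an [expression_matrix()].
#' @param gene_set gene ids (all must be present in `x`).
#' @param group `"A"` or `"B"`; at least 3 samples required.
#' @param log_transform compute on `log2(FPKM + 1)` (default) or linear.
#' @return symmetric k x k correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(x, gene_set, group,
                                 log_transform = TRUE) {
  idx <- group_columns(x, group)
  if (length(idx) < 3)
    stop("group ", group, " has fewer than 3 samples", call. = FALSE)
  missing <- setdiff(gene_set, rownames(x$values))
  if (length(missing) > 0)
    stop("gene not in matrix: ", missing[1L], call. = FALSE)
  v <- x$values[gene_set, idx, drop = FALSE]
  if (log_transform) v <- log2(v + 1)
  r <- suppressWarnings(stats::cor(t(v)))
  diag(r) <- 1
  r
}

#' Coordinate-control summary statistics of a correlation matrix
#'
#' Summaries over the `k(k-1)/2` off-diagonal pairs (upper triangle):
#' the mean correlation `mean_r`, the mean squared correlation
#' `mean_r2`, and the square of the mean `squared_mean_r`. Both r-squared
#' readings are reported because "mean r2" is ambiguous between them;
#' `mean_r2 >= squared_mean_r` always (Jensen's inequality). Missing
#' entries are excluded and counted.
#'
#' @param r_matrix correlation matrix from [pairwise_correlation()].
#' @return list with `mean_r`, `mean_r2`, `squared_mean_r`, `n_pairs`,
#'   `n_missing`.
#' @export
coordinate_statistic <- function(r_matrix) {
  if (nrow(r_matrix) < 2)
    stop("need at least 2 genes", call. = FALSE)
  ut <- r_matrix[upper.tri(r_matrix)]
  n_missing <- sum(is.na(ut))
  if (n_missing == length(ut))
    stop("all pairwise correlations are missing", call. = FALSE)
  mean_r <- mean(ut, na.rm = TRUE)
  list(mean_r = mean_r,
       mean_r2 = mean(ut^2, na.rm = TRUE),
       squared_mean_r = mean_r^2,
       n_pairs = length(ut),
       n_missing = n_missing)
}

#' Permutation test of coordinate control against random gene sets
#'
#' Each permutation draws `|gene_set|` genes uniformly without
#' replacement from `universe` excluding the tested set, computes the
#' chosen statistic on the same group's samples, and the add-one
#' upper-tail empirical p-value is returned: the probability that a
#' random equally sized gene set is at least as co-expressed as the
#' tested one.
#'
#' @inheritParams pairwise_correlation
#' @param universe expressed-gene ids forming the null pool.
#' @param n_permutations number of random gene sets (default 10^4).
#' @param seed integer seed.
#' @param statistic `"mean_r"` (default) or `"mean_r2"`.
#' @return list with `perm_p`, `observed`, `null_stats`, `statistic`.
#' @export
coordinate_permutation_test <- function(x, gene_set, group, universe,
                                        n_permutations = 10000, seed = 1L,
                                        statistic = c("mean_r", "mean_r2"),
                                        log_transform = TRUE) {
  statistic <- match.arg(statistic)
  pool <- intersect(setdiff(universe, gene_set), rownames(x$values))
  k <- length(gene_set)
  if (length(pool) < k)
    stop("null pool (", length(pool), ") smaller than gene set (", k, ")",
         call. = FALSE)
  obs <- coordinate_statistic(
    pairwise_correlation(x, gene_set, group, log_transform))[[statistic]]
  idx <- group_columns(x, group)
  v <- x$values[pool, idx, drop = FALSE]
  if (log_transform) v <- log2(v + 1)
  set.seed(as.integer(seed))
  null_stats <- vapply(seq_len(n_permutations), function(i) {
    r <- suppressWarnings(stats::cor(t(v[sample.int(length(pool), k), ,
                                         drop = FALSE])))
    ut <- r[upper.tri(r)]
    if (statistic == "mean_r") mean(ut, na.rm = TRUE)
    else mean(ut^2, na.rm = TRUE)
  }, 0)
  list(perm_p = empirical_p(obs, null_stats), observed = obs,
       null_stats = null_stats, statistic = statistic)
}

#' Coordinate control of a gene cluster in both phenotype groups
#'
#' Convenience wrapper combining [pairwise_correlation()],
#' [coordinate_statistic()] and [coordinate_permutation_test()] per
#' group, mirroring the question "is this cluster co-expressed beyond
#' chance, and does that co-expression differ between groups?".
#'
#' @inheritParams coordinate_permutation_test
#' @return list of two `correlation_summary` objects, one per group.
#' @export
coordinate_control <- function(x, gene_set, universe,
                               n_permutations = 10000, seed = 1L,
                               statistic = c("mean_r", "mean_r2"),
                               log_transform = TRUE) {
  statistic <- match.arg(statistic)
  out <- lapply(c(A = "A", B = "B"), function(g) {
    r <- pairwise_correlation(x, gene_set, g, log_transform)
    st <- coordinate_statistic(r)
    pt <- coordinate_permutation_test(x, gene_set, g, universe,
                                      n_permutations, seed, statistic,
                                      log_transform)
    structure(c(list(gene_set = gene_set, group = g, r_matrix = r),
                st,
                list(perm_p = pt$perm_p, statistic = statistic,
                     n_permutations = n_permutations, seed = seed)),
              class = "correlation_summary")
  })
  out
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat("correlation_summary: group", x$group, "-", length(x$gene_set),
      "genes\n")
  cat(sprintf("  mean_r = %.3f  mean_r2 = %.3f  squared_mean_r = %.3f\n",
              x$mean_r, x$mean_r2, x$squared_mean_r))
  cat(sprintf("  permutation p (%s, %d permutations) = %.4g\n",
              x$statistic, x$n_permutations, x$perm_p))
  invisible(x)
}

#' Average-linkage clustering of a correlation matrix
#'
#' Agglomerative clustering on the distance `d = 1 - r`, as used to
#' display co-expression heatmaps. Missing correlations are replaced by
#' the maximum observed distance with a warning. Rows are ordered by
#' gene id before clustering so ties resolve deterministically.
#'
#' @param r_matrix correlation matrix with gene ids as dimnames.
#' @return list with `order` (leaf gene ids), `hclust` (the merge tree)
#'   and `r_ordered` (the reordered matrix, for heatmap export).
#' @export
cluster_correlation_matrix <- function(r_matrix) {
  if (nrow(r_matrix) < 2)
    stop("need at least 2 genes", call. = FALSE)
  ord0 <- order(rownames(r_matrix))
  r <- r_matrix[ord0, ord0, drop = FALSE]
  d <- 1 - r
  if (anyNA(d)) {
    warning("missing correlations replaced by maximum distance",
            call. = FALSE)
    d[is.na(d)] <- max(d, na.rm = TRUE)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ord <- rownames(r)[hc$order]
  list(order = ord, hclust = hc,
       r_ordered = r[ord, ord, drop = FALSE])
}
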