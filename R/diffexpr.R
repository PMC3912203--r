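#' Signed fold-change of group means
#'
#' Ratio of the comparison-group mean to the reference-group mean,
#' reported with the negative-reciprocal sign convention common in
#' expression studies: if `mean_b / mean_a >= 1` the ratio itself is
#' returned, otherwise `-mean_a / mean_b`, so `|fc| >= 1` always and the
#' sign gives the direction of change in group B. Vectorised.
#'
#' @param mean_a reference-group mean FPKM (> 0 unless `mean_b` > 0).
#' @param mean_b comparison-group mean FPKM.
#' @return signed fold-change; `NA` where both means are 0 (undefined).
#' @examples
#' signed_fold_change(32.6, 182.6)   # 5.6-fold up
#' signed_fold_change(358.2, 236.4)  # -1.5-fold (down)
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  r <- mean_b / mean_a
  fc <- ifelse(r >= 1, r, -1 / r)
  fc[mean_a == 0 & mean_b == 0] <- NA_real_
  fc
}

#' Absolute difference of group means
#'
#' Magnitude `|mean_b - mean_a|` in FPKM, used to rank genes by the size
#' of their expression change regardless of direction.
#'
#' @inheritParams signed_fold_change
#' @return non-negative FPKM difference.
#' @export
absolute_difference <- function(mean_a, mean_b) {
  abs(mean_b - mean_a)
}

#' Per-gene two-group test on log-transformed FPKM
#'
#' Welch (unequal-variance) two-sample t-test on `log2(FPKM + 1)` for
#' every gene, comparison group B vs reference group A, two-sided.
#' Vectorised over genes. Genes with zero variance in both groups and
#' equal means get `p = 1`.
#'
#' @param x an [expression_matrix()] with at least 2 samples per group.
#' @return named vector of two-sided p-values.
#' @export
de_test <- function(x) {
  ia <- group_columns(x, "A")
  ib <- group_columns(x, "B")
  na <- length(ia)
  nb <- length(ib)
  if (na < 2 || nb < 2)
    stop("both groups need at least 2 samples", call. = FALSE)
  la <- log2(x$values[, ia, drop = FALSE] + 1)
  lb <- log2(x$values[, ib, drop = FALSE] + 1)
  ma <- rowMeans(la)
  mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(ma[se2 == 0] == mb[se2 == 0], 1, 0)
  stats::setNames(p, rownames(x$values))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The step-up procedure: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped back to
#' the input order. Controls the false discovery rate at the level of the
#' q-value cutoff.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values in input order; `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  # multiply by the ratio m/j (>= 1 as a float) so q >= p holds exactly
  q_sorted <- rev(cummin(rev((m / seq_len(m)) * p[o])))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

#' Differential-expression table for a two-group FPKM matrix
#'
#' Computes, per gene: linear-scale group means, absolute difference,
#' signed fold-change (on the linear-scale means), Welch-t p-value on
#' `log2(FPKM + 1)`, BH step-up q-value, a significance call
#' (`|fc| > fc_cut` strictly, and `q < q_cut`) and its direction.
#'
#' @param x an [expression_matrix()].
#' @param fc_cut fold-change cutoff (strict `>` on `|fc|`); default 1.5.
#' @param q_cut adjusted-p cutoff (strict `<`); default 0.05.
#' @return a `de_table`: data.frame with one row per gene and columns
#'   `gene_id`, `mean_a`, `mean_b`, `abs_diff`, `signed_fc`, `p_value`,
#'   `q_value`, `significant`, `direction`.
#' @export
de_table <- function(x, fc_cut = 1.5, q_cut = 0.05) {
  ia <- group_columns(x, "A")
  ib <- group_columns(x, "B")
  mean_a <- rowMeans(x$values[, ia, drop = FALSE])
  mean_b <- rowMeans(x$values[, ib, drop = FALSE])
  fc <- signed_fold_change(mean_a, mean_b)
  p <- de_test(x)
  q <- bh_adjust(p)
  sig <- !is.na(fc) & abs(fc) > fc_cut & q < q_cut
  tab <- data.frame(
    gene_id = rownames(x$values),
    mean_a = mean_a, mean_b = mean_b,
    abs_diff = absolute_difference(mean_a, mean_b),
    signed_fc = fc, p_value = unname(p), q_value = q,
    significant = sig,
    direction = ifelse(!sig, "none", ifelse(fc > 0, "up", "down")),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(tab, class = c("de_table", "data.frame"),
            fc_cut = fc_cut, q_cut = q_cut)
}

#' @export
print.de_table <- function(x, ...) {
  s <- select_significant(x)
  cat("de_table:", nrow(x), "genes;", length(s$genes), "significant (",
      s$n_up, "up,", s$n_down, "down ) at |fc| >",
      attr(x, "fc_cut"), "and q <", attr(x, "q_cut"), "\n")
  invisible(x)
}

#' Select significant genes from a DE table
#'
#' @param table a [de_table()].
#' @param fc_cut,q_cut cutoffs; defaults from the table's attributes.
#' @return list with `genes` (significant gene ids), `n_up`, `n_down`.
#' @export
select_significant <- function(table,
                               fc_cut = attr(table, "fc_cut"),
                               q_cut = attr(table, "q_cut")) {
  if (is.null(fc_cut)) fc_cut <- 1.5
  if (is.null(q_cut)) q_cut <- 0.05
  sig <- !is.na(table$signed_fc) & abs(table$signed_fc) > fc_cut &
    table$q_value < q_cut
  list(genes = table$gene_id[sig],
       n_up = sum(sig & table$signed_fc > 0),
       n_down = sum(sig & table$signed_fc < 0))
}

#' Top differentially expressed genes by absolute difference
#'
#' Significant genes sorted by descending absolute FPKM difference, ties
#' broken lexicographically by gene id.
#'
#' @param table a [de_table()].
#' @param n number of genes to return (may exceed the significant count).
#' @param fc_cut,q_cut cutoffs passed to [select_significant()].
#' @return character vector of up to `n` gene ids.
#' @export
rank_top <- function(table, n = 50,
                     fc_cut = attr(table, "fc_cut"),
                     q_cut = attr(table, "q_cut")) {
  sig_genes <- select_significant(table, fc_cut, q_cut)$genes
  sub <- table[table$gene_id %in% sig_genes, , drop = FALSE]
  ord <- order(-sub$abs_diff, sub$gene_id)
  utils::head(sub$gene_id[ord], n)
}
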