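#' Default candidate-threshold grid
#'
#' 1000 log-spaced FPKM values spanning `[1e-4, 1e2]`.
#'
#' @param grid_min,grid_max range in FPKM.
#' @param n number of grid points.
#' @return ascending numeric vector.
#' @export
default_fpkm_grid <- function(grid_min = 1e-4, grid_max = 1e2, n = 1000) {
  exp(seq(log(grid_min), log(grid_max), length.out = n))
}

#' Estimate the expression-above-background threshold
#'
#' Compares FPKM values measured over known exons (true signal) with
#' values over intergenic regions (known background). For each candidate
#' threshold `t`, the false discovery rate is the fraction of intergenic
#' values `>= t` (background that would be called expressed) and the
#' false negative rate is the fraction of exonic values `< t` (signal
#' that would be discarded). The selected threshold is the grid point
#' minimising `|FDR(t) - FNR(t)|` — the intersection of the two curves —
#' taking the smallest such point on ties.
#'
#' @param exon_values,intergenic_values non-negative FPKM vectors.
#' @param grid ascending candidate thresholds; see [default_fpkm_grid()].
#' @return a `threshold_result` with elements `grid`, `fdr_curve`,
#'   `fnr_curve`, `threshold`, `n_expressed` (filled by
#'   [filter_expressed()], `NA` until then).
#' @examples
#' tr <- estimate_threshold(c(0.5, 1, 2, 8), c(0.01, 0.02, 0.03, 0.6),
#'                          grid = seq(0.05, 1, by = 0.05))
#' tr$threshold  # 0.55: FDR = FNR = 0.25
#' @export
estimate_threshold <- function(exon_values, intergenic_values,
                               grid = default_fpkm_grid()) {
  if (length(exon_values) == 0 || length(intergenic_values) == 0)
    stop("exon and intergenic value sets must be non-empty", call. = FALSE)
  if (any(exon_values < 0) || any(intergenic_values < 0))
    stop("FPKM values must be non-negative", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly ascending", call. = FALSE)
  # the crossing lives where background mass runs out: require the grid
  # to span the central 98% of the intergenic distribution
  iq <- stats::quantile(intergenic_values, c(0.01, 0.99), names = FALSE)
  if (min(grid) > iq[1] || max(grid) < iq[2])
    warning("grid does not span the background value distribution",
            call. = FALSE)
  fdr <- vapply(grid, function(t) mean(intergenic_values >= t), 0)
  fnr <- vapply(grid, function(t) mean(exon_values < t), 0)
  best <- which.min(abs(fdr - fnr))  # first index = smallest t on ties
  structure(list(grid = grid, fdr_curve = fdr, fnr_curve = fnr,
                 threshold = grid[best], n_expressed = NA_integer_),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  i <- match(x$threshold, x$grid)
  cat("threshold_result: threshold =", signif(x$threshold, 4), "FPKM",
      sprintf("(FDR = %.4f, FNR = %.4f)\n", x$fdr_curve[i], x$fnr_curve[i]))
  if (!is.na(x$n_expressed))
    cat("  genes expressed above background:", x$n_expressed, "\n")
  invisible(x)
}

#' @export
plot.threshold_result <- function(x, ...) {
  graphics::matplot(x$grid, cbind(x$fdr_curve, x$fnr_curve), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"), log = "x",
                    xlab = "FPKM threshold", ylab = "rate", ...)
  graphics::abline(v = x$threshold, lty = 2)
  graphics::legend("right", c("FDR (intergenic)", "FNR (exonic)"),
                   lty = 1, col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Filter an expression matrix to genes expressed above background
#'
#' A gene is scored as expressed when its mean FPKM across all samples is
#' `>=` the threshold (inclusive). Gene order is preserved.
#'
#' @param x an [expression_matrix()].
#' @param threshold FPKM threshold (>= 0), or a `threshold_result`.
#' @return the filtered `expression_matrix`.
#' @export
filter_expressed <- function(x, threshold) {
  if (inherits(threshold, "threshold_result")) threshold <- threshold$threshold
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  keep <- rowMeans(x$values) >= threshold
  if (!any(keep))
    stop("threshold ", threshold, " removes all genes", call. = FALSE)
  expression_matrix(x$values[keep, , drop = FALSE], x$groups)
}
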