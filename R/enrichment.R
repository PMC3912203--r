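# location label per annotated gene at the requested granularity
location_of <- function(annotation, level = c("chromosome", "subband")) {
  level <- match.arg(level)
  stats::setNames(annotation[[level]], annotation$gene_id)
}

#' Count genes of a set per chromosome or subband
#'
#' Genes absent from the annotation are dropped with a warning; every
#' location present in the annotation appears in the result (possibly
#' with a zero count), so counts from different sets are comparable.
#'
#' @param gene_set character vector of gene ids.
#' @param annotation a `gene_annotation`.
#' @param level `"chromosome"` or `"subband"`.
#' @return named integer vector of counts; sums to the number of
#'   annotated genes in the set.
#' @export
count_by_location <- function(gene_set, annotation,
                              level = c("chromosome", "subband")) {
  level <- match.arg(level)
  loc <- location_of(annotation, level)
  levels_all <- sort(unique(unname(loc)))
  unann <- setdiff(gene_set, names(loc))
  if (length(unann) > 0)
    warning(length(unann), " gene(s) not in annotation dropped",
            call. = FALSE)
  counts <- table(factor(loc[intersect(gene_set, names(loc))],
                         levels = levels_all))
  stats::setNames(as.integer(counts), levels_all)
}

#' Resampling null distribution of per-location gene counts
#'
#' Each iteration draws `m` genes uniformly without replacement from
#' `universe` minus `excluded` and records the per-location counts.
#' Because draws come from the expressed-gene universe itself, the null
#' automatically accounts for gene density per region. Unannotated pool
#' genes may be drawn but contribute to no location, so per-iteration
#' counts sum to `m` when the universe is fully annotated.
#'
#' @param universe expressed-gene ids (the sampling frame).
#' @param excluded gene ids removed from the pool (typically the tested
#'   set, so the null describes "other" genes).
#' @param m genes drawn per iteration.
#' @param annotation a `gene_annotation`.
#' @param level `"chromosome"` or `"subband"`.
#' @param n_iterations number of resamples.
#' @param seed integer seed; same seed reproduces the samples exactly.
#' @return integer matrix `n_iterations` x locations of null counts.
#' @export
permutation_null <- function(universe, excluded, m, annotation,
                             level = c("chromosome", "subband"),
                             n_iterations = 10000, seed = 1L) {
  level <- match.arg(level)
  pool <- setdiff(universe, excluded)
  if (length(pool) < m)
    stop("resampling pool (", length(pool), ") smaller than draw size ",
         m, call. = FALSE)
  loc <- location_of(annotation, level)
  levels_all <- sort(unique(unname(loc)))
  # integer codes; 0 (ignored by tabulate) marks unannotated pool genes
  code <- match(loc[pool], levels_all)
  code[is.na(code)] <- 0L
  nlev <- length(levels_all)
  npool <- length(pool)
  set.seed(as.integer(seed))
  out <- matrix(0L, n_iterations, nlev, dimnames = list(NULL, levels_all))
  for (i in seq_len(n_iterations))
    out[i, ] <- tabulate(code[sample.int(npool, m)], nbins = nlev)
  out
}

#' Add-one upper-tail empirical p-value
#'
#' `p = (1 + #\{null >= observed\}) / (n + 1)`: the standard permutation
#' estimator, never exactly zero, with minimum `1/(n + 1)`.
#'
#' @param observed observed count.
#' @param null_samples numeric vector of null counts.
#' @return empirical p-value.
#' @export
empirical_p <- function(observed, null_samples) {
  if (length(null_samples) == 0)
    stop("null_samples must be non-empty", call. = FALSE)
  (1 + sum(null_samples >= observed)) / (length(null_samples) + 1)
}

#' Positional enrichment of a gene set at chromosomes or subbands
#'
#' Tests whether `de_set` is over-represented at each location relative
#' to equally sized random gene sets drawn from the expressed universe
#' (excluding `de_set` itself). Reports, per location: the observed
#' count, its percentage of the set (nearest integer), the resampling
#' null summary (mean, quartiles, Tukey 1.5 IQR whiskers), the add-one
#' empirical p-value, the raw exceedance fraction, and a Bonferroni
#' column (`p * number of locations`, capped at 1) for transparency —
#' the primary report is the per-locus empirical p. Upper tail only:
#' this is an enrichment test, not a depletion test.
#'
#' @param de_set gene ids of the tested (e.g. dysregulated) set.
#' @param universe expressed-gene ids; should contain `de_set`.
#' @param annotation a `gene_annotation`.
#' @param level `"chromosome"` or `"subband"`.
#' @param n_iterations resampling iterations (default 10^4).
#' @param seed integer seed.
#' @return an `enrichment_result`: data.frame with one row per location,
#'   ordered by ascending empirical p then descending observed count.
#' @export
enrich <- function(de_set, universe, annotation,
                   level = c("chromosome", "subband"),
                   n_iterations = 10000, seed = 1L) {
  level <- match.arg(level)
  observed <- count_by_location(de_set, annotation, level)
  nulls <- permutation_null(universe, de_set, m = length(de_set),
                            annotation, level, n_iterations, seed)
  stopifnot(identical(names(observed), colnames(nulls)))
  qs <- apply(nulls, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  iqr <- qs[3, ] - qs[1, ]
  wlo <- whi <- numeric(ncol(nulls))
  for (j in seq_len(ncol(nulls))) {
    inside <- nulls[, j] >= qs[1, j] - 1.5 * iqr[j] &
      nulls[, j] <= qs[3, j] + 1.5 * iqr[j]
    wlo[j] <- min(nulls[inside, j])
    whi[j] <- max(nulls[inside, j])
  }
  p_emp <- vapply(seq_along(observed),
                  function(j) empirical_p(observed[j], nulls[, j]), 0)
  res <- data.frame(
    location = names(observed),
    observed = unname(observed),
    percent = round(100 * unname(observed) / length(de_set)),
    null_mean = colMeans(nulls),
    null_q1 = qs[1, ], null_median = qs[2, ], null_q3 = qs[3, ],
    null_whisker_lo = wlo, null_whisker_hi = whi,
    p_empirical = p_emp,
    p_raw = vapply(seq_along(observed),
                   function(j) mean(nulls[, j] >= observed[j]), 0),
    p_bonferroni = pmin(1, p_emp * length(observed)),
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$p_empirical, -res$observed, res$location), ]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            level = level, n_iterations = n_iterations, seed = seed,
            set_size = length(de_set))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result (", attr(x, "level"), " level, ",
      attr(x, "set_size"), " genes, ", attr(x, "n_iterations"),
      " iterations)\n", sep = "")
  top <- utils::head(as.data.frame(x)[, c("location", "observed", "percent",
                                          "null_mean", "p_empirical")], 5)
  print.data.frame(top, digits = 4)
  invisible(x)
}

#' @export
plot.enrichment_result <- function(x, ...) {
  n <- nrow(x)
  graphics::plot(seq_len(n), x$observed, pch = 19, col = "firebrick",
                 xaxt = "n", xlab = "", ylab = "genes",
                 ylim = range(0, x$observed, x$null_whisker_hi), ...)
  graphics::axis(1, at = seq_len(n), labels = x$location, las = 2,
                 cex.axis = 0.7)
  graphics::segments(seq_len(n), x$null_whisker_lo,
                     seq_len(n), x$null_whisker_hi, col = "grey50")
  graphics::rect(seq_len(n) - 0.25, x$null_q1, seq_len(n) + 0.25, x$null_q3,
                 col = "grey85", border = "grey40")
  graphics::points(seq_len(n), x$observed, pch = 19, col = "firebrick")
  invisible(x)
}
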