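#' Construct an expression matrix with phenotype groups
#'
#' The central data container of the pipeline: a non-negative FPKM matrix
#' (genes in rows, samples in columns) together with a two-level phenotype
#' assignment. Group `"A"` is the reference (nonsmoker-like) group and
#' `"B"` the comparison (smoker-like) group; fold-changes are always
#' reported as B relative to A.
#'
#' @param values numeric matrix of FPKM values; rownames are gene ids,
#'   colnames are sample ids. All values must be finite and >= 0.
#' @param groups named character vector mapping every sample id to
#'   `"A"` or `"B"`; both groups must be non-empty.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `groups` (character vector aligned to the
#'   matrix columns).
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' x <- expression_matrix(m, c(s1 = "A", s2 = "A", s3 = "B"))
#' x
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1L], call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L], call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-finite FPKM for gene ", gid[bad[1L, 1L]],
         ", sample ", sid[bad[1L, 2L]], call. = FALSE)
  if (is.null(names(groups)))
    stop("`groups` must be a named vector (names are sample ids)", call. = FALSE)
  missing_grp <- setdiff(sid, names(groups))
  if (length(missing_grp) > 0)
    stop("sample missing from groups: ", missing_grp[1L], call. = FALSE)
  groups <- groups[sid]
  unknown <- setdiff(unique(groups), c("A", "B"))
  if (length(unknown) > 0)
    stop("unknown group label: ", unknown[1L], " (expected \"A\" or \"B\")",
         call. = FALSE)
  if (!all(c("A", "B") %in% groups))
    stop("both groups A and B must be non-empty", call. = FALSE)
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  group A (reference):", sum(x$groups == "A"),
      " group B:", sum(x$groups == "B"), "\n")
  cat("  mean FPKM:", signif(mean(x$values), 4), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene and sample accessors
#' @param x an `expression_matrix`.
#' @return character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Restrict an expression matrix to a subset of genes
#'
#' @param x an `expression_matrix`.
#' @param genes gene ids to keep; order of `x` is preserved.
#' @return an `expression_matrix` with the retained genes.
#' @export
subset_genes <- function(x, genes) {
  keep <- rownames(x$values) %in% genes
  if (!any(keep)) stop("no genes left after subsetting", call. = FALSE)
  expression_matrix(x$values[keep, , drop = FALSE], x$groups)
}

# column indices of one phenotype group
group_columns <- function(x, group) {
  which(x$groups == group)
}
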