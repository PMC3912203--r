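#' Read an FPKM expression matrix and its sample groups from TSV
#'
#' The matrix file is tab-separated with a header row: first column
#' `gene_id`, remaining columns one per sample. The groups file is a
#' two-column TSV (`sample_id`, `group`) with group labels `A`
#' (reference) or `B`. Row and column order is preserved from the files.
#'
#' @param matrix_path path to the expression TSV.
#' @param groups_path path to the sample-to-group TSV.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(matrix_path, groups_path) {
  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("expression file needs a gene_id column and at least one sample",
         call. = FALSE)
  gid <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gid
  grp <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(grp) < 2)
    stop("groups file must have columns sample_id and group", call. = FALSE)
  if (anyDuplicated(grp[[1L]]))
    stop("duplicate sample id in groups file: ",
         grp[[1L]][duplicated(grp[[1L]])][1L], call. = FALSE)
  groups <- stats::setNames(as.character(grp[[2L]]), as.character(grp[[1L]]))
  expression_matrix(vals, groups)
}

#' Write an expression matrix (and groups) as TSV
#'
#' Inverse of [read_expression()]; write-then-read is the identity on all
#' typed content.
#'
#' @param x an `expression_matrix`.
#' @param matrix_path,groups_path output paths.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, matrix_path, groups_path) {
  out <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  grp <- data.frame(sample_id = names(x$groups), group = unname(x$groups),
                    stringsAsFactors = FALSE)
  utils::write.table(grp, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

strip_chr <- function(x) sub("^chr", "", x)

#' Read a gene annotation from a BED-like TSV
#'
#' Five tab-separated columns without header: chromosome, start, end,
#' gene id, cytogenetic subband (e.g. `19q13.2`). Coordinates are 0-based
#' half-open (BED convention). Lines starting with `#` are ignored. A
#' `chr` prefix on the chromosome is accepted and stripped to a canonical
#' bare label; the subband label must begin with its chromosome label.
#' The subband is taken from the explicit column, never inferred from the
#' coordinates.
#'
#' @param path path to the annotation file.
#' @return a `gene_annotation`: a data.frame with columns `gene_id`,
#'   `chromosome`, `subband`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(gene_annotation(data.frame(gene_id = character(),
                                      chromosome = character(),
                                      subband = character(),
                                      start = integer(), end = integer(),
                                      stringsAsFactors = FALSE)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5))
    stop("annotation line ", which(nf < 5)[1L], " has fewer than 5 fields",
         call. = FALSE)
  df <- data.frame(
    gene_id    = vapply(parts, `[[`, "", 4L),
    chromosome = strip_chr(vapply(parts, `[[`, "", 1L)),
    subband    = vapply(parts, `[[`, "", 5L),
    start      = as.integer(vapply(parts, `[[`, "", 2L)),
    end        = as.integer(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  # consistent duplicates collapse; conflicting duplicates are an error
  if (anyDuplicated(df$gene_id)) {
    key <- paste(df$gene_id, df$chromosome, df$subband)
    df2 <- df[!duplicated(key), , drop = FALSE]
    if (anyDuplicated(df2$gene_id))
      stop("conflicting locations for gene ",
           df2$gene_id[duplicated(df2$gene_id)][1L], call. = FALSE)
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
  }
  rownames(df) <- NULL
  gene_annotation(df)
}

#' Write a gene annotation as a BED-like TSV
#'
#' @param ann a `gene_annotation`.
#' @param path output path.
#' @return `ann`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  out <- data.frame(chrom = paste0("chr", ann$chromosome),
                    start = ann$start, end = ann$end,
                    gene_id = ann$gene_id, subband = ann$subband)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ann)
}

# validating constructor shared by read_annotation and the simulator
gene_annotation <- function(df) {
  stopifnot(all(c("gene_id", "chromosome", "subband") %in% names(df)))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in annotation: ",
         df$gene_id[duplicated(df$gene_id)][1L], call. = FALSE)
  bad <- which(substr(df$subband, 1L, nchar(df$chromosome)) != df$chromosome)
  if (length(bad) > 0)
    stop("subband '", df$subband[bad[1L]],
         "' does not begin with its chromosome label '",
         df$chromosome[bad[1L]], "' (gene ", df$gene_id[bad[1L]], ")",
         call. = FALSE)
  if (is.null(df$start)) df$start <- NA_integer_
  if (is.null(df$end)) df$end <- NA_integer_
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x), "genes,",
      length(unique(x$chromosome)), "chromosomes,",
      length(unique(x$subband)), "subbands\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}
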