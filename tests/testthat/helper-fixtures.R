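# in-code fixtures shared across test files

# small deterministic expression matrix: n_a + n_b samples, values drawn
# log-normally; optional per-gene group-B multiplier `fold` (named by gene)
tiny_matrix <- function(n_genes = 20, n_a = 5, n_b = 4, seed = 42,
                        fold = NULL, noise_sd = 0.4) {
  set.seed(seed)
  gid <- sprintf("g%03d", seq_len(n_genes))
  grp <- rep(c("A", "B"), c(n_a, n_b))
  sid <- sprintf("s%02d", seq_along(grp))
  base <- rnorm(n_genes, 2, 1)
  lx <- base + matrix(rnorm(n_genes * length(grp), 0, noise_sd),
                      n_genes, length(grp))
  if (!is.null(fold)) {
    sh <- rep(0, n_genes)
    sh[match(names(fold), gid)] <- log(fold)
    lx[, grp == "B"] <- lx[, grp == "B"] + sh
  }
  v <- exp(lx)
  dimnames(v) <- list(gid, sid)
  expression_matrix(v, setNames(grp, sid))
}

# annotation placing genes on locations round-robin by given proportions
tiny_annotation <- function(gene_ids, locations = c("1p36.1", "19q13.2"),
                            chromosomes = sub("[pq].*$", "", locations)) {
  k <- ((seq_along(gene_ids) - 1L) %% length(locations)) + 1L
  bandenrich:::gene_annotation(data.frame(
    gene_id = gene_ids, chromosome = chromosomes[k],
    subband = locations[k],
    start = (seq_along(gene_ids) - 1L) * 1000L,
    end = seq_along(gene_ids) * 1000L, stringsAsFactors = FALSE))
}

# hand-rolled de_table-shaped data.frame for selection/ranking tests
fake_de_table <- function(gene_id, mean_a, mean_b, q) {
  fc <- signed_fold_change(mean_a, mean_b)
  structure(data.frame(
    gene_id = gene_id, mean_a = mean_a, mean_b = mean_b,
    abs_diff = absolute_difference(mean_a, mean_b),
    signed_fc = fc, p_value = q, q_value = q,
    significant = NA, direction = NA, stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"), fc_cut = 1.5, q_cut = 0.05)
}
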