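#' Simulation configuration for the synthetic study generator
#'
#' Defaults emulate the study design the pipeline was built around:
#' 13,385 expressed genes, 10 reference-group vs 7 comparison-group
#' samples, log-normal FPKM with grand mean near 32 FPKM, about 5% of
#' genes planted as differentially expressed with the up:down asymmetry
#' of 662:14, planted enrichment of the DE set on one cytogenetic subband,
#' and a 13-gene module sharing a latent factor whose correlation weakens
#' in group B.
#'
#' FPKM is generated on the natural-log scale then exponentiated: gene
#' baseline `b_g ~ N(log_fpkm_mean, log_fpkm_sd^2)` plus per-sample noise
#' `N(0, noise_sd^2)`, so the expected FPKM is
#' `exp(log_fpkm_mean + (log_fpkm_sd^2 + noise_sd^2)/2)` (about 32.2 with
#' the defaults). Planted DE genes have their group-B values multiplied
#' (up) or divided (down) by a true fold-change drawn from
#' `de_fold_range`. Module genes add a shared standard-normal latent
#' factor with per-group loading `lambda = noise_sd * sqrt(r/(1-r))`, so
#' the within-group pairwise correlation is `r`; targets must therefore
#' lie in `[0, 1)`.
#'
#' @param n_genes number of genes.
#' @param n_group_a,n_group_b samples per phenotype group.
#' @param log_fpkm_mean,log_fpkm_sd natural-log-scale baseline parameters.
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param de_up_fraction fraction of planted DE genes up-regulated in group B.
#' @param de_fold_range interval of planted linear fold-changes (lower
#'   bound >= 1).
#' @param enriched_location subband receiving excess planted DE genes.
#' @param enrichment_multiplier relative over-assignment rate of DE genes
#'   to `enriched_location` (1 = no enrichment).
#' @param module_genes size of the planted correlated gene cluster.
#' @param module_correlation_a,module_correlation_b target mean pairwise
#'   Pearson correlation of the module in each group, in `[0, 1)`.
#' @param noise_sd residual log-scale noise standard deviation.
#' @param dropout_prob probability that any value is zeroed (dropout).
#' @param seed integer seed; all generator output is reproducible given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 13385,
                       n_group_a = 10,
                       n_group_b = 7,
                       log_fpkm_mean = log(32.2) - (1.5^2 + 0.5^2) / 2,
                       log_fpkm_sd = 1.5,
                       de_fraction = 676 / 13385,
                       de_up_fraction = 662 / 676,
                       de_fold_range = c(1.5, 6),
                       enriched_location = "19q13.2",
                       enrichment_multiplier = 5,
                       module_genes = 13,
                       module_correlation_a = 0.8,
                       module_correlation_b = 0.2,
                       noise_sd = 0.5,
                       dropout_prob = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_group_a = as.integer(n_group_a),
              n_group_b = as.integer(n_group_b),
              log_fpkm_mean = log_fpkm_mean, log_fpkm_sd = log_fpkm_sd,
              de_fraction = de_fraction, de_up_fraction = de_up_fraction,
              de_fold_range = de_fold_range,
              enriched_location = enriched_location,
              enrichment_multiplier = enrichment_multiplier,
              module_genes = as.integer(module_genes),
              module_correlation_a = module_correlation_a,
              module_correlation_b = module_correlation_b,
              noise_sd = noise_sd, dropout_prob = dropout_prob,
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1 || n_group_a < 1 || n_group_b < 1 || module_genes < 0)
      stop("counts must be positive", call. = FALSE)
    if (de_fraction < 0 || de_fraction > 1 ||
        de_up_fraction < 0 || de_up_fraction > 1 ||
        dropout_prob < 0 || dropout_prob > 1)
      stop("fractions must lie in [0, 1]", call. = FALSE)
    if (length(de_fold_range) != 2 || de_fold_range[1] < 1 ||
        de_fold_range[2] < de_fold_range[1])
      stop("de_fold_range must be an interval with lower bound >= 1",
           call. = FALSE)
    if (module_correlation_a < 0 || module_correlation_a >= 1 ||
        module_correlation_b < 0 || module_correlation_b >= 1)
      stop("module correlations must lie in [0, 1)", call. = FALSE)
    if (noise_sd < 0 || log_fpkm_sd < 0)
      stop("standard deviations must be non-negative", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Default synthetic cytogenetic band weights
#'
#' A small illustrative table of (chromosome, subband, weight) rows used
#' to place simulated genes; weights are loosely patterned after relative
#' gene densities of the human karyotype (gene-dense chromosomes 16, 17,
#' 19, 22 get heavier bands) but are synthetic, not measured densities.
#'
#' @return data.frame with columns `chromosome`, `subband`, `weight`.
#' @export
default_band_spec <- function() {
  path <- system.file("extdata", "synthetic_band_weights.tsv",
                      package = "bandenrich")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assign simulated genes to chromosomes and subbands
#'
#' Each gene is assigned a (chromosome, subband) multinomially with
#' probability proportional to the band weights. Synthetic 0-based
#' half-open coordinates are laid out as consecutive 10-kb intervals per
#' chromosome so the annotation round-trips through BED-like files.
#'
#' @param config a [sim_config()].
#' @param band_spec data.frame with columns `chromosome`, `subband`,
#'   `weight` (positive); defaults to [default_band_spec()].
#' @return a `gene_annotation`.
#' @export
generate_annotation <- function(config, band_spec = default_band_spec()) {
  if (is.null(band_spec) || nrow(band_spec) == 0)
    stop("band_spec is empty", call. = FALSE)
  if (any(band_spec$weight <= 0))
    stop("band weights must be positive", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_genes
  band <- sample.int(nrow(band_spec), n, replace = TRUE,
                     prob = band_spec$weight)
  gid <- sprintf("G%05d", seq_len(n))
  chrom <- band_spec$chromosome[band]
  # consecutive 10-kb gene intervals per chromosome
  start <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    start[idx] <- (seq_along(idx) - 1L) * 10000L
  }
  gene_annotation(data.frame(
    gene_id = gid, chromosome = as.character(chrom),
    subband = as.character(band_spec$subband[band]),
    start = start, end = start + 10000L, stringsAsFactors = FALSE))
}

#' Generate a synthetic FPKM matrix with planted structure
#'
#' Plants (i) a differentially expressed gene set, over-assigned to
#' `config$enriched_location` by `enrichment_multiplier` (DE genes are
#' drawn with sampling weight `multiplier` on that subband, 1 elsewhere);
#' and (ii) a latent-factor-correlated gene module whose genes are taken
#' preferentially from the enriched subband (DE genes there first), so
#' the default pipeline focus set corresponds to the planted cluster.
#'
#' @param config a [sim_config()].
#' @param annotation a `gene_annotation` covering `config$n_genes` genes,
#'   e.g. from [generate_annotation()].
#' @return list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (planted DE genes with true fold-change and direction,
#'   planted module genes, and the gene-to-subband assignment).
#' @export
generate_expression <- function(config, annotation) {
  n <- config$n_genes
  if (nrow(annotation) != n)
    stop("annotation must cover exactly n_genes genes", call. = FALSE)
  if (config$module_genes > n)
    stop("module_genes cannot exceed n_genes", call. = FALSE)
  set.seed(config$seed + 1L)

  gid <- annotation$gene_id
  n_a <- config$n_group_a
  n_b <- config$n_group_b
  ns <- n_a + n_b
  grp <- rep(c("A", "B"), c(n_a, n_b))
  sid <- sprintf("S%02d_%s", seq_len(ns), grp)

  base <- stats::rnorm(n, config$log_fpkm_mean, config$log_fpkm_sd)

  # planted DE set, over-assigned to the enriched subband
  n_de <- round(config$de_fraction * n)
  w <- ifelse(annotation$subband == config$enriched_location,
              config$enrichment_multiplier, 1)
  de_idx <- if (n_de > 0) sample(n, n_de, prob = w) else integer(0)
  n_up <- round(config$de_up_fraction * n_de)
  up_idx <- de_idx[seq_len(n_up)]
  down_idx <- setdiff(de_idx, up_idx)
  fold <- if (n_de > 0)
    stats::runif(n_de, config$de_fold_range[1], config$de_fold_range[2])
  else numeric(0)
  names(fold) <- gid[de_idx]

  # module genes: enriched-subband DE genes first, then the rest of the
  # subband, then anywhere — mirrors a dysregulated co-expressed locus
  on_band <- which(annotation$subband == config$enriched_location)
  tiers <- c(intersect(de_idx, on_band),
             setdiff(on_band, de_idx),
             setdiff(seq_len(n), on_band))
  mod_idx <- tiers[seq_len(config$module_genes)]

  logx <- base + matrix(stats::rnorm(n * ns, 0, config$noise_sd), n, ns)
  shift <- numeric(n)
  shift[up_idx] <- log(fold[match(up_idx, de_idx)])
  shift[down_idx] <- -log(fold[match(down_idx, de_idx)])
  logx[, grp == "B"] <- logx[, grp == "B"] + shift

  if (config$module_genes > 0 && config$noise_sd > 0) {
    lam <- function(r) config$noise_sd * sqrt(r / (1 - r))
    loading <- ifelse(grp == "A", lam(config$module_correlation_a),
                      lam(config$module_correlation_b))
    factor_s <- stats::rnorm(ns)
    logx[mod_idx, ] <- logx[mod_idx, ] +
      rep(loading * factor_s, each = length(mod_idx))
  }

  vals <- exp(logx)
  if (config$dropout_prob > 0) {
    drop <- matrix(stats::runif(n * ns) < config$dropout_prob, n, ns)
    vals[drop] <- 0
  }
  dimnames(vals) <- list(gid, sid)

  truth <- list(
    de_genes = data.frame(
      gene_id = gid[de_idx],
      fold_change = unname(fold),
      direction = ifelse(de_idx %in% up_idx, "up", "down"),
      stringsAsFactors = FALSE),
    module_genes = gid[mod_idx],
    location_assignment = stats::setNames(annotation$subband, gid))

  list(matrix = expression_matrix(vals, stats::setNames(grp, sid)),
       truth = truth)
}

#' Generate exonic and intergenic FPKM samples for threshold estimation
#'
#' Draws the two value sets used by [estimate_threshold()]: exonic values
#' from a log-normal, intergenic values from a mixture of a point mass at
#' zero and a (stochastically lower) log-normal.
#'
#' @param n_exon,n_intergenic positive counts.
#' @param exon_meanlog,exon_sdlog exonic log-normal parameters
#'   (natural-log scale).
#' @param intergenic_meanlog,intergenic_sdlog intergenic log-normal
#'   parameters.
#' @param intergenic_zero_prob point mass at zero for intergenic units.
#' @param seed integer seed.
#' @return list with numeric vectors `exon` and `intergenic`.
#' @export
generate_threshold_samples <- function(n_exon, n_intergenic,
                                       exon_meanlog = log(5),
                                       exon_sdlog = 1.5,
                                       intergenic_meanlog = log(0.005),
                                       intergenic_sdlog = 1,
                                       intergenic_zero_prob = 0,
                                       seed = 1L) {
  if (n_exon < 1 || n_intergenic < 1)
    stop("counts must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  exon <- stats::rlnorm(n_exon, exon_meanlog, exon_sdlog)
  inter <- stats::rlnorm(n_intergenic, intergenic_meanlog, intergenic_sdlog)
  if (intergenic_zero_prob > 0)
    inter[stats::runif(n_intergenic) < intergenic_zero_prob] <- 0
  list(exon = exon, intergenic = inter)
}
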