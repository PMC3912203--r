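#' Pipeline configuration
#'
#' Bundles inputs and parameters for [run_pipeline()]. Inputs are either
#' file paths (expression matrix + groups + annotation, optionally exon
#' and intergenic FPKM value files for threshold estimation) or a
#' [sim_config()] in `simulation`, in which case all inputs are
#' generated. Defaults match the standard cutoffs: fold-change 1.5,
#' adjusted p 0.05, 10^4 resampling iterations.
#'
#' @param matrix_file,groups_file,annotation_file input TSV paths
#'   (ignored when `simulation` is given).
#' @param exon_file,intergenic_file single-column TSVs of FPKM values for
#'   threshold estimation; if absent (and not simulating), `threshold`
#'   must be given.
#' @param simulation optional [sim_config()]; when set, expression,
#'   annotation and threshold samples are generated.
#' @param threshold optional fixed FPKM threshold overriding estimation.
#' @param fc_cut,q_cut significance cutoffs.
#' @param n_iterations enrichment resampling iterations.
#' @param levels enrichment levels to run, in order.
#' @param focus_genes optional gene ids for the coordinate-control stage;
#'   default: significant genes on the most-enriched subband.
#' @param n_permutations coordinate-control permutations.
#' @param statistic coordinate-control statistic (`"mean_r"`/`"mean_r2"`).
#' @param top_n size of the top-gene list.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param output_dir directory for all stage outputs and the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_file = NULL, groups_file = NULL,
                            annotation_file = NULL, exon_file = NULL,
                            intergenic_file = NULL, simulation = NULL,
                            threshold = NULL, fc_cut = 1.5, q_cut = 0.05,
                            n_iterations = 10000,
                            levels = c("chromosome", "subband"),
                            focus_genes = NULL, n_permutations = 10000,
                            statistic = "mean_r", top_n = 50, seed = 1L,
                            output_dir = tempfile("bandenrich_run_")) {
  cfg <- list(matrix_file = matrix_file, groups_file = groups_file,
              annotation_file = annotation_file, exon_file = exon_file,
              intergenic_file = intergenic_file, simulation = simulation,
              threshold = threshold, fc_cut = fc_cut, q_cut = q_cut,
              n_iterations = n_iterations, levels = levels,
              focus_genes = focus_genes, n_permutations = n_permutations,
              statistic = statistic, top_n = top_n, seed = as.integer(seed),
              output_dir = output_dir)
  if (is.null(cfg$simulation) &&
      (is.null(cfg$matrix_file) || is.null(cfg$groups_file) ||
       is.null(cfg$annotation_file)))
    stop("either `simulation` or matrix/groups/annotation files required",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path config file; keys as in [pipeline_config()]. A
#'   `simulation` block is passed to [sim_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(sim_config, raw$simulation)
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) load or simulate inputs; (2) estimate the
#' background threshold from exonic vs intergenic values and filter to
#' expressed genes; (3) differential expression with signed fold-changes
#' and BH adjustment; (4) positional enrichment of the significant set
#' at each requested level; (5) coordinate control of the focus gene set
#' (default: significant genes on the most-enriched subband) in both
#' groups; (6) sample-level QC (PCA scores, hierarchical clustering of
#' samples on the significant set). All stage outputs are written as TSV
#' under `output_dir` together with a JSON manifest recording package
#' version, parameters, derived seeds and the gene/sample counts after
#' every stage; re-running with the same config reproduces all outputs
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return a `pipeline_report` (invisibly printable list): the manifest
#'   plus the in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[bandenrich] ", ...)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  files <- character(0)
  seed <- config$seed

  # ---- stage 1: inputs -------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    say("simulating ", sim$n_genes, " genes (seed ", sim$seed, ")")
    ann <- generate_annotation(sim)
    gen <- generate_expression(sim, ann)
    mat <- gen$matrix
    thr_samples <- generate_threshold_samples(
      n_exon = 5000, n_intergenic = 5000, seed = sim$seed + 2L)
    truth_file <- out("truth.json")
    jsonlite::write_json(gen$truth, truth_file, auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, truth_file)
  } else {
    say("reading expression from ", config$matrix_file)
    mat <- read_expression(config$matrix_file, config$groups_file)
    ann <- read_annotation(config$annotation_file)
    thr_samples <- NULL
    if (!is.null(config$exon_file) && !is.null(config$intergenic_file))
      thr_samples <- list(
        exon = utils::read.delim(config$exon_file, header = FALSE)[[1L]],
        intergenic = utils::read.delim(config$intergenic_file,
                                       header = FALSE)[[1L]])
  }
  say("input: ", nrow(mat$values), " genes, ", ncol(mat$values),
      " samples (A=", sum(mat$groups == "A"), ", B=",
      sum(mat$groups == "B"), ")")

  # ---- stage 2: background threshold ----------------------------------
  if (!is.null(config$threshold)) {
    thr <- structure(list(grid = config$threshold, fdr_curve = NA_real_,
                          fnr_curve = NA_real_, threshold = config$threshold,
                          n_expressed = NA_integer_),
                     class = "threshold_result")
  } else if (!is.null(thr_samples)) {
    thr <- estimate_threshold(thr_samples$exon, thr_samples$intergenic)
    files <- c(files, write_tsv(
      data.frame(fpkm = thr$grid, fdr = thr$fdr_curve, fnr = thr$fnr_curve),
      out("threshold_curves.tsv")))
  } else {
    stop("stage threshold: no exon/intergenic values and no fixed threshold",
         call. = FALSE)
  }
  expressed <- tryCatch(filter_expressed(mat, thr$threshold),
                        error = function(e)
                          stop("stage threshold: ", conditionMessage(e),
                               call. = FALSE))
  thr$n_expressed <- nrow(expressed$values)
  say("threshold ", signif(thr$threshold, 3), " FPKM: ", thr$n_expressed,
      " expressed genes")

  # ---- stage 3: differential expression -------------------------------
  tab <- de_table(expressed, config$fc_cut, config$q_cut)
  sig <- select_significant(tab)
  top <- rank_top(tab, config$top_n)
  say("differential expression: ", length(sig$genes), " significant (",
      sig$n_up, " up, ", sig$n_down, " down)")
  files <- c(files, write_tsv(as.data.frame(tab), out("de_table.tsv")))
  files <- c(files, write_tsv(
    as.data.frame(tab)[match(top, tab$gene_id), ], out("top_genes.tsv")))

  # ---- stage 4: positional enrichment ---------------------------------
  universe <- gene_ids(expressed)
  enr <- list()
  for (lv in config$levels) {
    enr[[lv]] <- tryCatch(
      enrich(sig$genes, universe, ann, level = lv,
             n_iterations = config$n_iterations, seed = seed + 101L),
      error = function(e) stop("stage enrichment (", lv, "): ",
                               conditionMessage(e), call. = FALSE))
    say("enrichment at ", lv, " level: top location ",
        enr[[lv]]$location[1L], " (p = ",
        signif(enr[[lv]]$p_empirical[1L], 3), ")")
    files <- c(files, write_tsv(as.data.frame(enr[[lv]]),
                                out(paste0("enrichment_", lv, ".tsv"))))
  }

  # ---- stage 5: coordinate control ------------------------------------
  focus <- config$focus_genes
  focus_location <- NA_character_
  if (is.null(focus) && "subband" %in% names(enr)) {
    focus_location <- enr$subband$location[1L]
    loc <- location_of(ann, "subband")
    focus <- intersect(sig$genes, names(loc)[loc == focus_location])
  }
  coord <- NULL
  if (!is.null(focus) && length(focus) >= 2) {
    say("coordinate control of ", length(focus), " focus genes",
        if (!is.na(focus_location)) paste0(" on ", focus_location))
    coord <- coordinate_control(expressed, focus, universe,
                                n_permutations = config$n_permutations,
                                seed = seed + 202L,
                                statistic = config$statistic)
    for (g in names(coord)) {
      rm_ <- coord[[g]]$r_matrix
      files <- c(files, write_tsv(
        data.frame(gene_id = rownames(rm_), rm_, check.names = FALSE),
        out(paste0("correlation_", g, ".tsv"))))
    }
    files <- c(files, write_tsv(
      data.frame(gene_id = cluster_correlation_matrix(
        coord$A$r_matrix)$order),
      out("correlation_order_A.tsv")))
  } else {
    say("coordinate control skipped (fewer than 2 focus genes)")
  }

  # ---- stage 6: sample QC ---------------------------------------------
  pca <- qc_pca(expressed)
  files <- c(files, write_tsv(pca, out("qc_pca.tsv")))
  clus <- if (length(sig$genes) >= 2)
    qc_sample_clustering(expressed, sig$genes) else NULL
  if (!is.null(clus))
    say("sample clustering on significant genes: complete separation = ",
        clus$complete_separation)

  # ---- manifest -------------------------------------------------------
  manifest <- list(
    package = "bandenrich",
    version = as.character(utils::packageVersion("bandenrich")),
    parameters = list(fc_cut = config$fc_cut, q_cut = config$q_cut,
                      n_iterations = config$n_iterations,
                      n_permutations = config$n_permutations,
                      statistic = config$statistic, levels = config$levels,
                      top_n = config$top_n),
    seeds = list(master = seed, enrichment = seed + 101L,
                 coordinate = seed + 202L,
                 simulation = if (!is.null(config$simulation))
                   config$simulation$seed),
    counts = list(
      genes_in = nrow(mat$values), samples = ncol(mat$values),
      n_expressed = thr$n_expressed, threshold = thr$threshold,
      n_significant = length(sig$genes), n_up = sig$n_up,
      n_down = sig$n_down),
    top_location = lapply(enr, function(e)
      list(location = e$location[1L], observed = e$observed[1L],
           percent = e$percent[1L], p_empirical = e$p_empirical[1L])),
    focus = list(location = focus_location, genes = focus),
    coordinate = if (!is.null(coord)) lapply(coord, function(s)
      list(mean_r = s$mean_r, mean_r2 = s$mean_r2,
           squared_mean_r = s$squared_mean_r, perm_p = s$perm_p)),
    complete_separation = if (!is.null(clus)) clus$complete_separation,
    files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  structure(list(manifest = manifest, threshold = thr, de = tab,
                 significant = sig, top_genes = top, enrichment = enr,
                 coordinate = coord, pca = pca, clustering = clus,
                 output_dir = config$output_dir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  m <- x$manifest
  cat("pipeline_report (bandenrich ", m$version, ")\n", sep = "")
  cat("  expressed genes:", m$counts$n_expressed, "of", m$counts$genes_in,
      "at threshold", signif(m$counts$threshold, 3), "FPKM\n")
  cat("  significant:", m$counts$n_significant, "(", m$counts$n_up, "up,",
      m$counts$n_down, "down )\n")
  for (lv in names(m$top_location)) {
    tl <- m$top_location[[lv]]
    cat("  top ", lv, ": ", tl$location, " (", tl$observed, " genes, ",
        tl$percent, "%, p = ", signif(tl$p_empirical, 3), ")\n", sep = "")
  }
  if (!is.null(m$coordinate))
    cat(sprintf("  coordinate control: mean_r A = %.3f (p = %.3g), B = %.3f (p = %.3g)\n",
                m$coordinate$A$mean_r, m$coordinate$A$perm_p,
                m$coordinate$B$mean_r, m$coordinate$B$perm_p))
  cat("  outputs in", x$output_dir, "\n")
  invisible(x)
}

#' Sample scores on the first two principal components
#'
#' Singular-value decomposition of the gene-centered `log2(FPKM + 1)`
#' matrix; per-sample scores on components 1 and 2 with a deterministic
#' sign convention (the largest-magnitude gene loading of each component
#' is made positive).
#'
#' @param x an [expression_matrix()] with at least 3 samples.
#' @return data.frame with `sample_id`, `group`, `pc1`, `pc2`; attribute
#'   `var_explained` holds the variance fractions.
#' @export
qc_pca <- function(x) {
  if (ncol(x$values) < 3) stop("need at least 3 samples", call. = FALSE)
  lx <- log2(x$values + 1)
  if (any(!is.finite(lx)))
    stop("degenerate matrix: non-finite values", call. = FALSE)
  xc <- lx - rowMeans(lx)
  s <- svd(xc, nu = 2, nv = 2)
  # identical samples give a zero centered matrix and all-zero scores
  scores <- sweep(s$v, 2, s$d[1:2], `*`)
  for (k in 1:2) {
    top <- which.max(abs(s$u[, k]))
    if (s$u[top, k] < 0) scores[, k] <- -scores[, k]
  }
  d2 <- s$d^2
  structure(data.frame(sample_id = colnames(x$values),
                       group = unname(x$groups),
                       pc1 = scores[, 1], pc2 = scores[, 2],
                       stringsAsFactors = FALSE),
            var_explained = d2[1:2] / sum(d2))
}

#' Hierarchical clustering of samples on a gene set
#'
#' Average-linkage clustering of samples with distance
#' `1 - Pearson r` over `log2(FPKM + 1)` of the given genes. Reports
#' whether the two phenotype groups form perfectly separated subtrees
#' (the two-cluster cut coincides with the group labels).
#'
#' @param x an [expression_matrix()].
#' @param gene_set non-empty gene ids to cluster on.
#' @return list with `hclust` and logical `complete_separation`.
#' @export
qc_sample_clustering <- function(x, gene_set) {
  if (length(gene_set) == 0) stop("gene_set is empty", call. = FALSE)
  v <- log2(x$values[gene_set, , drop = FALSE] + 1)
  if (ncol(v) < 2) stop("need at least 2 samples", call. = FALSE)
  r <- suppressWarnings(stats::cor(v))
  d <- 1 - r
  if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cut2 <- stats::cutree(hc, k = 2)
  grp <- x$groups[hc$labels]
  sep <- length(unique(cut2[grp == "A"])) == 1 &&
    length(unique(cut2[grp == "B"])) == 1 &&
    cut2[grp == "A"][1L] != cut2[grp == "B"][1L]
  list(hclust = hc, complete_separation = sep)
}
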