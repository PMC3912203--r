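test_that("annotation assignment is multinomial by weight", {
  cfg <- sim_config(n_genes = 100, seed = 3)
  one_band <- data.frame(chromosome = "5", subband = "5q31.1", weight = 1)
  ann <- generate_annotation(cfg, one_band)
  expect_equal(nrow(ann), 100)
  expect_true(all(ann$subband == "5q31.1"))

  # two equal-weight bands: counts within 3 binomial SDs of n/2
  cfg2 <- sim_config(n_genes = 10000, seed = 11)
  two <- data.frame(chromosome = c("1", "2"),
                    subband = c("1p36.1", "2q31.1"), weight = c(1, 1))
  ann2 <- generate_annotation(cfg2, two)
  counts <- table(ann2$subband)
  expect_equal(sum(counts), 10000)
  expect_true(all(abs(counts - 5000) < 3 * sqrt(10000 * 0.25)))

  expect_error(generate_annotation(cfg, data.frame()), "empty")
  expect_error(
    generate_annotation(cfg, data.frame(chromosome = "1",
                                        subband = "1p36.1", weight = -1)),
    "positive")
})

test_that("generators are bit-reproducible given the seed", {
  cfg <- sim_config(n_genes = 300, seed = 99)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  g1 <- generate_expression(cfg, a1)
  g2 <- generate_expression(cfg, a2)
  expect_identical(g1$matrix$values, g2$matrix$values)
  expect_identical(g1$truth, g2$truth)
  t1 <- generate_threshold_samples(50, 50, seed = 5)
  t2 <- generate_threshold_samples(50, 50, seed = 5)
  expect_identical(t1, t2)
})

test_that("expression grand mean follows the log-normal mean formula", {
  cfg <- sim_config(n_genes = 10000, de_fraction = 0, module_genes = 0,
                    seed = 21)
  gen <- generate_expression(cfg, generate_annotation(cfg))
  expected <- exp(cfg$log_fpkm_mean + (cfg$log_fpkm_sd^2 + cfg$noise_sd^2) / 2)
  expect_lt(abs(mean(gen$matrix$values) - expected) / expected, 0.10)
  # the defaults target a grand mean near 32 FPKM
  expect_lt(abs(expected - 32.2) / 32.2, 0.01)
})

test_that("with no planted DE all group fold-changes are near 1", {
  cfg <- sim_config(n_genes = 2000, de_fraction = 0, module_genes = 0,
                    noise_sd = 0.1, seed = 4)
  gen <- generate_expression(cfg, generate_annotation(cfg))
  expect_equal(nrow(gen$truth$de_genes), 0)
  m <- gen$matrix
  fc <- rowMeans(m$values[, m$groups == "B"]) /
    rowMeans(m$values[, m$groups == "A"])
  expect_lt(max(abs(fc - 1)), 0.25)
  expect_lt(abs(mean(fc) - 1), 0.01)
})

test_that("planted fold-changes are recovered as noise vanishes", {
  cfg <- sim_config(n_genes = 500, de_fraction = 0.1, noise_sd = 0.004,
                    module_genes = 0, seed = 8)
  gen <- generate_expression(cfg, generate_annotation(cfg))
  m <- gen$matrix
  tr <- gen$truth$de_genes
  ratio <- rowMeans(m$values[tr$gene_id, m$groups == "B", drop = FALSE]) /
    rowMeans(m$values[tr$gene_id, m$groups == "A", drop = FALSE])
  target <- ifelse(tr$direction == "up", tr$fold_change, 1 / tr$fold_change)
  expect_true(all(abs(ratio / target - 1) < 0.01))
  # asymmetric up/down split follows de_up_fraction
  expect_equal(sum(tr$direction == "up"),
               round(cfg$de_up_fraction * nrow(tr)))
})

test_that("planted truth is consistent with the generated data", {
  cfg <- sim_config(n_genes = 400, seed = 13)
  ann <- generate_annotation(cfg)
  gen <- generate_expression(cfg, ann)
  gid <- gene_ids(gen$matrix)
  expect_true(all(gen$truth$de_genes$gene_id %in% gid))
  expect_true(all(gen$truth$module_genes %in% gid))
  expect_equal(length(gen$truth$location_assignment), length(gid))
  expect_false(anyNA(gen$truth$location_assignment))
  # DE genes are over-represented on the enriched subband
  on_band <- names(gen$truth$location_assignment)[
    gen$truth$location_assignment == cfg$enriched_location]
  frac_de <- mean(gen$truth$de_genes$gene_id %in% on_band)
  frac_all <- length(on_band) / length(gid)
  expect_gt(frac_de, frac_all)
})

test_that("module correlation is stronger in group A than B across seeds", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 120, de_fraction = 0, module_genes = 13,
                      module_correlation_a = 0.9, module_correlation_b = 0,
                      seed = 1000 + s)
    gen <- generate_expression(cfg, generate_annotation(cfg))
    mr <- vapply(c("A", "B"), function(g) {
      r <- pairwise_correlation(gen$matrix, gen$truth$module_genes, g)
      mean(r[upper.tri(r)])
    }, 0)
    hits <- hits + (mr["A"] > mr["B"])
  }
  expect_gte(hits, 18L)
})

test_that("threshold sample generator honours its degenerate settings", {
  s <- generate_threshold_samples(30, 30, intergenic_zero_prob = 1, seed = 2)
  expect_true(all(s$intergenic == 0))
  expect_true(all(s$exon > 0))
  expect_error(generate_threshold_samples(0, 10), "positive")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(de_fraction = 1.2), "fractions")
  expect_error(sim_config(de_fold_range = c(0.5, 2)), "fold_range")
  expect_error(sim_config(module_correlation_a = 1), "correlations")
  cfg <- sim_config(n_genes = 10, module_genes = 20)
  expect_error(generate_expression(cfg, generate_annotation(cfg)),
               "module_genes")
})
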