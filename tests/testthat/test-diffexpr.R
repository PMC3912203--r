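# literal step-up definition: q_(i) = min_{j>=i} p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

test_that("signed fold-change reproduces reported two-group arithmetic", {
  # strongly up-regulated gene: 32.6 -> 182.6 FPKM
  expect_equal(round(signed_fold_change(32.6, 182.6), 1), 5.6)
  expect_equal(round(absolute_difference(32.6, 182.6), 1), 150.0)
  # down-regulated genes use the negative-reciprocal convention
  expect_equal(round(signed_fold_change(358.2, 236.4), 1), -1.5)
  expect_equal(round(absolute_difference(358.2, 236.4), 1), 121.8)
  expect_equal(round(signed_fold_change(207.6, 119.7), 1), -1.7)
  # moderate up-regulation
  expect_equal(round(signed_fold_change(34.1, 104.3), 1), 3.1)
  expect_equal(round(absolute_difference(34.1, 104.3), 1), 70.2)
})

test_that("signed fold-change edge cases and antisymmetry", {
  expect_equal(signed_fold_change(7, 7), 1)
  expect_equal(absolute_difference(5, 5), 0)
  expect_true(is.na(signed_fold_change(0, 0)))
  set.seed(12)
  a <- runif(200, 0.1, 100)
  b <- runif(200, 0.1, 100)
  keep <- abs(signed_fold_change(a, b)) > 1
  expect_equal(signed_fold_change(a, b)[keep],
               -signed_fold_change(b, a)[keep])
})

test_that("per-gene Welch test matches stats::t.test on log2(FPKM+1)", {
  x <- tiny_matrix(n_genes = 25, n_a = 6, n_b = 5, seed = 5)
  p <- de_test(x)
  lx <- log2(x$values + 1)
  for (g in rownames(lx)) {
    ref <- t.test(lx[g, x$groups == "B"], lx[g, x$groups == "A"])$p.value
    expect_equal(unname(p[g]), ref, tolerance = 1e-12)
  }
})

test_that("degenerate and extreme genes get sensible p-values", {
  v <- rbind(flat = rep(3, 9),
             huge = c(rep(1, 5), rep(1000, 4)))
  colnames(v) <- paste0("s", 1:9)
  x <- expression_matrix(v, setNames(rep(c("A", "B"), c(5, 4)),
                                     colnames(v)))
  p <- de_test(x)
  expect_equal(unname(p["flat"]), 1)
  expect_lt(unname(p["huge"]), 1e-6)
})

test_that("null p-values are approximately uniform", {
  cfg <- sim_config(n_genes = 1000, de_fraction = 0, module_genes = 0,
                    seed = 17)
  gen <- generate_expression(cfg, generate_annotation(cfg))
  p <- de_test(gen$matrix)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH step-up agrees with hand computation and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    q <- bh_adjust(p)
    expect_true(all(q >= p))                      # q >= p per gene
    expect_true(all(diff(q[order(p)]) >= -1e-15)) # monotone in sorted order
  }
})

test_that("significance requires |fc| strictly above the cutoff", {
  tab <- fake_de_table(c("edge", "up", "weak_q"),
                       mean_a = c(10, 10, 10),
                       mean_b = c(15, 30, 40),
                       q = c(0.01, 0.04, 0.2))
  s <- select_significant(tab)
  expect_false("edge" %in% s$genes)  # fc exactly 1.5 is not significant
  expect_true("up" %in% s$genes)
  expect_false("weak_q" %in% s$genes)
  expect_equal(s$n_up, 1)
  expect_equal(s$n_down, 0)
})

test_that("planted DE genes at high fold and low noise are fully recovered", {
  cfg <- sim_config(n_genes = 400, de_fraction = 0.05, noise_sd = 0.1,
                    de_fold_range = c(4, 6), module_genes = 0, seed = 19)
  gen <- generate_expression(cfg, generate_annotation(cfg))
  tab <- de_table(gen$matrix)
  expect_setequal(select_significant(tab)$genes, gen$truth$de_genes$gene_id)
})

test_that("top-gene ranking sorts by absolute difference then gene id", {
  tab <- fake_de_table(c("mif_like", "mgst1_like"),
                       mean_a = c(32.6, 358.2), mean_b = c(182.6, 236.4),
                       q = c(0.001, 0.001))
  expect_equal(rank_top(tab, 2), c("mif_like", "mgst1_like"))
  expect_equal(rank_top(tab, 0), character(0))
  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    tab <- fake_de_table(sprintf("g%02d", sample(n)),
                         mean_a = rep(10, n),
                         mean_b = round(runif(n, 20, 40)),
                         q = rep(0.01, n))
    got <- rank_top(tab, n)
    ord <- tab[order(-tab$abs_diff, tab$gene_id), "gene_id"]
    expect_equal(got, ord)
  }
})
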