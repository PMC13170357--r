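# Gene-level statistics: filters, ratios, tests, FDR, hits, dispersion.

test_that("one-sample Wilcoxon worked example: all-positive n=5 gives W=15, p=0.0625", {
  out <- wilcoxon_one_sample(c(1.2, 0.8, 1.5, 0.9, 1.1))
  expect_equal(out$statistic, 15)
  expect_equal(out$p_value, 0.0625)
})

test_that("Wilcoxon handles symmetric, degenerate and tiny inputs per contract", {
  sym <- wilcoxon_one_sample(c(-1, 1, -2, 2))
  expect_equal(sym$p_value, 1, tolerance = 0.15) # W at the null median
  deg <- wilcoxon_one_sample(c(0, 0, 0))
  expect_equal(deg$p_value, 1)
  expect_equal(deg$flag, "degenerate")
  tiny <- wilcoxon_one_sample(c(0.5, -0.2))
  expect_true(is.na(tiny$p_value))
  expect_equal(tiny$flag, "untestable")
})

test_that("Wilcoxon agrees with sign-flip enumeration for all n <= 10 instances", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    x <- round(stats::rnorm(n), 2)
    x <- x[x != 0]
    if (length(x) < 3 || any(duplicated(abs(x)))) next
    got <- wilcoxon_one_sample(x)
    expect_equal(got$p_value, oracle_signed_rank_p(x), tolerance = 1e-10)
  }
})

test_that("Mann-Whitney worked example: {1,2,3} vs {4,5,6} gives U=0, p=0.1", {
  out <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.1)
})

test_that("Mann-Whitney is symmetric, null on identical lists, and matches enumeration", {
  a <- c(1.4, 2.2, 0.7, 3.1)
  b <- c(1.9, 0.4, 2.8)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_value, 1, tolerance = 0.01)
  set.seed(102)
  for (i in 1:40) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    v <- round(stats::rnorm(nx + ny), 2)
    if (any(duplicated(v))) next
    got <- mann_whitney(v[1:nx], v[(nx + 1):(nx + ny)])
    expect_equal(got$p_value, oracle_mann_whitney_p(v[1:nx], v[(nx + 1):(nx + ny)]),
      tolerance = 1e-10
    )
  }
})

test_that("BH adjustment: worked example, order preservation, and elementwise bound", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(103)
  for (i in 1:20) {
    p <- stats::runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # permutation invariance up to order preservation
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("dispersion: SD uses n-1, CV% = 100*sd/|mean|, undefined at mean 0", {
  expect_equal(dispersion(c(1, 1, 1)), list(sd = 0, cv_percent = 0, cv_defined = TRUE))
  d <- dispersion(c(0, 2))
  expect_equal(d$sd, sqrt(2))
  expect_equal(d$cv_percent, 141.42, tolerance = 1e-4)
  d0 <- dispersion(c(-1, 1))
  expect_false(d0$cv_defined)
  expect_true(is.na(d0$cv_percent))
})

test_that("baseline-normalized ratios follow the worked arithmetic", {
  # one gene, one barcode; 37C baseline 8, 50C values {16, 8, 4}
  mat <- matrix(c(8, 8, 8, 16, 8, 4), nrow = 1,
    dimnames = list("B1", c("37_1", "37_2", "37_3", "50_1", "50_2", "50_3"))
  )
  filtered <- tibble::tibble(
    barcode = "B1", gene_id = "g1",
    `37_1` = 8, `37_2` = 8, `37_3` = 8, `50_1` = 16, `50_2` = 8, `50_3` = 4
  )
  meta <- tibble::tibble(
    sample_id = colnames(mat), temperature = rep(c(37, 50), each = 3),
    replicate = rep(1:3, 2), batch = "b1"
  )
  fc <- gene_log2fc(filtered, meta, "g1")
  expect_equal(fc$baseline_37, 8)
  expect_equal(sort(fc$log2_ratios), c(-1, 0, 1))
  expect_equal(mean(fc$log2_ratios), 0)
  # scale invariance: doubling all normalized abundances changes nothing
  f2 <- filtered
  for (s in meta$sample_id) f2[[s]] <- f2[[s]] * 2
  expect_equal(gene_log2fc(f2, meta, "g1")$log2_ratios, fc$log2_ratios)
})

test_that("gene and barcode filters apply the read-count and multi-feature rules", {
  # gene gLow: max raw count 4 anywhere -> removed; gene gOK: one 5 -> kept
  mat <- matrix(
    c(
      4, 4, 4, 4, # B1 (gLow)
      4, 4, 5, 4, # B2 (gOK)
      9, 9, 9, 9, # B3 (gMulti, multi-feature)
      7, 7, 7, 7 # B4 (gInter, intergenic)
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("B", 1:4), c("37_1", "37_2", "50_1", "50_2"))
  )
  cts <- manual_counts(mat, c(37, 37, 50, 50), c(1L, 2L, 1L, 2L))
  pool <- tibble::tibble(
    barcode = paste0("B", 1:4),
    chromosome = "chr1", position = c(10L, 20L, 30L, 40L), strand = "+",
    classification = "single", read_support = 5L,
    gene_id = c("gLow", "gOK", "gA;gB", "intergenic"),
    multi_feature = c(FALSE, FALSE, TRUE, FALSE), batch = "b1"
  )
  out <- filter_barcodes_and_genes(cts, pool, min_reads = 5)
  expect_equal(out$barcode, "B2")
  expect_equal(out$gene_id, "gOK")
})

test_that("hit calling applies both thresholds and the barcode cap", {
  g <- tiny_genome()
  tr <- simulate_gene_pool_truth(g, 5, seed = 51)
  # inflate one gene past the 15-barcode cap by reassigning three donors
  pool <- truth_pool(tr)
  g16 <- pool$gene_id[1]
  donors <- setdiff(unique(pool$gene_id), g16)[1:3]
  pool$gene_id[pool$gene_id %in% donors] <- g16
  tr$gene_effects <- stats::setNames(3, g16)
  cts <- simulate_barseq_counts(tr, abundance_noise = 0.05, seed = 52)
  fit <- gene_fitness(cts, pool)
  expect_true(g16 %in% fit$excluded$gene_id)
  expect_false(g16 %in% tidy(fit)$gene_id)
  res <- tidy(fit)
  expect_true(all(res$is_hit ==
    (abs(res$mean_log2fc) >= 1 & res$fdr < 0.05)))
  expect_true(all(res$fdr >= res$p_value, na.rm = TRUE))
  expect_true(all(res$direction[res$mean_log2fc > 0] == "favors-50"))
})

test_that("planted positive effects are detected and favor 50C", {
  g <- tiny_genome()
  tr <- simulate_gene_pool_truth(g, 5, seed = 53)
  tr <- plant_gene_effects(tr, 2, 2, min_barcodes = 5, seed = 54)
  cts <- simulate_barseq_counts(tr, abundance_noise = 0.1, seed = 55)
  fit <- gene_fitness(cts, truth_pool(tr))
  res <- tidy(fit)
  planted <- res[res$gene_id %in% names(tr$gene_effects), ]
  expect_true(all(planted$is_hit))
  expect_true(all(planted$direction == "favors-50"))
  # in this tiny pool the planted barcodes are a sizeable weight fraction, so
  # total-count renormalization shifts the estimate down by log2(1 + 3q);
  # check recovery against that compositional expectation
  q <- sum(tr$insertions$baseline_abundance[
    tr$insertions$gene_id %in% names(tr$gene_effects)
  ]) / sum(tr$insertions$baseline_abundance)
  expected <- 2 - log2(1 + 3 * q)
  expect_true(all(abs(planted$mean_log2fc - expected) < 0.5))
  # unplanted genes are overwhelmingly quiet
  expect_lt(mean(res$is_hit[!res$gene_id %in% names(tr$gene_effects)]), 0.05)
})

test_that("volcano table has one sorted row per tested gene", {
  g <- tiny_genome()
  tr <- simulate_gene_pool_truth(g, 4, seed = 56)
  cts <- simulate_barseq_counts(tr, seed = 57)
  fit <- gene_fitness(cts, truth_pool(tr))
  v <- volcano_table(fit)
  expect_equal(nrow(v), nrow(tidy(fit)[!is.na(tidy(fit)$fdr), ]))
  expect_equal(v$neg_log10_fdr[1], max(v$neg_log10_fdr))
  expect_equal(v$neg_log10_fdr, -log10(tidy(fit)$fdr[!is.na(tidy(fit)$fdr)]))
})

test_that("hit thresholds can be re-applied to an external results table", {
  tab <- tibble::tibble(
    mean_log2fc = c(1.98, 1.95, -1.45, 0.9, -0.98),
    fdr = c(1.12e-5, 5.84e-2, 0.0184, 0.001, 0.0184)
  )
  out <- hit_calls_from_table(tab)
  expect_equal(out$n_genes, 5L)
  expect_equal(out$n_hits, 2L) # |lfc|>=1 & fdr<0.05 only
  expect_equal(out$hits_favor_50, 1L)
  expect_equal(out$hits_favor_37, 1L)
})

test_that("fitness results are deterministic for fixed inputs", {
  g <- tiny_genome()
  tr <- simulate_gene_pool_truth(g, 3, seed = 58)
  cts <- simulate_barseq_counts(tr, seed = 59)
  f1 <- gene_fitness(cts, truth_pool(tr))
  f2 <- gene_fitness(cts, truth_pool(tr))
  expect_identical(tidy(f1), tidy(f2))
})
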