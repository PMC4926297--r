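noise_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

test_that("mRNA-mRNA null is seed-deterministic with symmetric percentiles on noise", {
  expr <- noise_expr(300, 100, 1)
  n1 <- mrna_mrna_null(expr, set_size = 100, seed = 7)
  n2 <- mrna_mrna_null(expr, set_size = 100, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_equal(n1$n_draws, 100^2)
  expect_equal(n1$p95, unname(quantile(n1$values, 0.95)))
  # exchangeable noise: upper and lower cutoffs are symmetric
  expect_lt(abs(n1$p95 + n1$p05), 0.02)
  expect_error(mrna_mrna_null(expr, set_size = 200), "set_size")
})

test_that("size-matched gene-set null returns add-one extremes", {
  universe <- sprintf("g%03d", 1:60)
  stat <- function(genes) length(genes)  # constant statistic
  below <- geneset_size_matched_null(universe, character(0), 10,
                                     observed = 100, statistic = stat,
                                     n_iter = 50, seed = 1)
  expect_equal(below$p, 1 / 51)
  above <- geneset_size_matched_null(universe, character(0), 10,
                                     observed = 0, statistic = stat,
                                     n_iter = 50, seed = 1)
  expect_equal(above$p, 1)
  expect_error(geneset_size_matched_null(universe, universe, 10, 1, stat),
               "smaller")
})

test_that("random-set enrichment p is small for a planted co-expressed block", {
  set.seed(3)
  expr <- noise_expr(200, 80, 3)
  shared <- rnorm(80)
  block <- sprintf("g%04d", 1:12)
  expr[block, ] <- expr[block, ] * 0.3 + rep(shared, each = 12)
  # statistic: mean pairwise correlation within the set
  stat <- function(genes) {
    cm <- cor(t(expr[genes, ]))
    mean(cm[upper.tri(cm)])
  }
  res <- geneset_size_matched_null(rownames(expr), excluded = block,
                                   set_size = length(block),
                                   observed = stat(block), statistic = stat,
                                   n_iter = 200, seed = 5)
  expect_equal(res$p, 1 / 201)
})

test_that("correlation-count tables respect cutoffs and exclude self-pairs", {
  expr <- noise_expr(60, 50, 8)
  null <- mrna_mrna_null(expr, set_size = 20, seed = 2)
  metabolic <- rownames(expr)[1:10]
  drivers <- rownames(expr)[8:20]  # overlaps the metabolic set
  counts <- correlation_count_table(metabolic, drivers, expr, null)
  overlap <- intersect(metabolic, drivers)
  expect_true(all(counts$n_drivers_tested[counts$gene_id %in% overlap] ==
                    length(drivers) - 1))
  expect_true(all(counts$correlated_count <= counts$n_drivers_tested))
  # unreachable cutoffs give zero counts
  null0 <- null; null0$p95 <- 1; null0$p05 <- -1
  counts0 <- correlation_count_table(metabolic, drivers, expr, null0)
  expect_true(all(counts0$correlated_count == 0))
  expect_true(all(counts0$anticorrelated_count == 0))
})

test_that("cell-wise enrichment p-values hit the add-one extremes and are reproducible", {
  set.seed(4)
  expr <- noise_expr(80, 60, 4)
  null <- mrna_mrna_null(expr, set_size = 25, seed = 3)
  metabolic <- rownames(expr)[1:5]
  drivers <- rownames(expr)[41:50]
  counts <- correlation_count_table(metabolic, drivers, expr, null)
  # observed count 0 can never beat the null: p = 1 for zero-count cells
  p1 <- count_table_enrichment_p(counts, drivers, expr, null,
                                 n_iter = 100, seed = 6)
  expect_true(all(p1$p_enriched[p1$correlated_count == 0] == 1))
  p2 <- count_table_enrichment_p(counts, drivers, expr, null,
                                 n_iter = 100, seed = 6)
  expect_identical(p1$p_enriched, p2$p_enriched)
  # a gene correlated with every driver beats all noise draws
  expr2 <- expr
  shared <- rnorm(60)
  expr2["g0001", ] <- shared + rnorm(60, 0, 0.05)
  for (d in drivers) expr2[d, ] <- shared + rnorm(60, 0, 0.05)
  counts2 <- correlation_count_table("g0001", drivers, expr2, null)
  expect_equal(counts2$correlated_count, length(drivers))
  p3 <- count_table_enrichment_p(counts2, drivers, expr2, null,
                                 n_iter = 100, seed = 6)
  expect_equal(p3$p_enriched, 1 / 101)
})

test_that("hypergeometric overlap matches brute-force tail sums", {
  universe <- sprintf("u%03d", 1:100)
  a <- universe[1:10]
  b <- c(universe[6:10], universe[90:94])  # overlap 5
  res <- hypergeometric_overlap(a, b, universe)
  expect_equal(res$overlap, 5)
  # frozen brute-force enumeration over the support (choose() arithmetic)
  expect_equal(res$p_enriched, 6.716277482651e-04, tolerance = 1e-12)
  # disjoint halves of a 20-gene universe: overlap 0
  u20 <- sprintf("v%02d", 1:20)
  res0 <- hypergeometric_overlap(u20[1:10], u20[11:20], u20)
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p_enriched, 1)  # P(X >= 0) covers the whole support
  expect_equal(res0$p_depleted, 5.412544112235e-06, tolerance = 1e-12)
  expect_error(hypergeometric_overlap(c(a, "zzz"), b, universe), "subsets")
})

test_that("permutation overlap null converges to the exact hypergeometric tail", {
  universe <- sprintf("u%03d", 1:80)
  reference <- universe[1:20]
  obs <- 2
  exact <- phyper(obs, 20, 60, 10, lower.tail = TRUE)
  perm <- permutation_overlap_null(reference, character(0), universe,
                                   set_size = 10, observed_overlap = obs,
                                   side = "low", n_iter = 20000, seed = 2)
  expect_equal(perm$p, exact, tolerance = 0.01)
  # low-side extreme when the null is strictly positive
  all_ref <- permutation_overlap_null(universe[1:79], "u080", universe,
                                      set_size = 10, observed_overlap = 0,
                                      side = "low", n_iter = 1000, seed = 3)
  expect_equal(all_ref$p, 1 / 1001)
  # observed at the null median sits near 0.5
  med <- permutation_overlap_null(reference, character(0), universe,
                                  set_size = 10,
                                  observed_overlap = qhyper(0.5, 20, 60, 10),
                                  side = "low", n_iter = 5000, seed = 4)
  expect_gt(med$p, 0.4)
})

test_that("mutation-frequency gate keeps genes above the cohort threshold", {
  samples <- sprintf("s%02d", 1:40)
  muts <- data.frame(
    gene_id = c(rep("freq", 3), rep("rare", 2), rep("freq", 0)),
    sample_id = c(samples[1:3], samples[1:2]),
    variant_class = "missense")
  kept <- mutation_frequency_filter(c("freq", "rare", "absent"), muts,
                                    samples, min_freq = 0.05)
  expect_identical(kept, "freq")   # 3/40 = 7.5% > 5%; 2/40 = 5% fails strictly
})
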