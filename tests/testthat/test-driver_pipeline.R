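test_that("Spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearman(1:3 * 1.0, c(10, 20, 30) * 1.0)$rho, 1)
  expect_equal(spearman(1:4 * 1.0, c(30, 20, 10, 5))$rho, -1)
  # frozen hand-rank oracle for the tied case
  r <- spearman(c(1, 2, 2, 3), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.9486832981, tolerance = 1e-9)
  # independent route: cor.test with the t approximation
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  s <- spearman(x, y)
  expect_equal(s$rho, unname(ct$estimate))
  expect_equal(s$p, ct$p.value, tolerance = 1e-10)
  # pairwise deletion and the constant-vector convention
  expect_equal(spearman(c(1, 2, 3, 4, NA), c(1, 2, 3, 4, 5))$n, 4L)
  expect_true(is.na(spearman(rep(1, 5), 1:5)$rho))
  expect_error(spearman(1:2, 1:2), ">= 3")
})

make_cascade_bundle <- function() {
  # 6 genes x 40 samples: hand-planted gain fractions and couplings
  set.seed(31)
  n <- 40
  genes <- paste0("g", 1:6)
  cn <- matrix(rnorm(6 * n, 0, 0.05), 6, n,
               dimnames = list(genes, paste0("s", 1:n)))
  # g1: gained in half the samples, expression tracks dosage
  cn["g1", 1:20] <- cn["g1", 1:20] + runif(20, 0.4, 1)
  # g2: gained in only 7/40 samples (17.5% < 20%)
  cn["g2", 1:7] <- cn["g2", 1:7] + runif(7, 0.4, 1)
  # g3: gained in half the samples but expression is pure noise
  cn["g3", 21:40] <- cn["g3", 21:40] + runif(20, 0.4, 1)
  expr <- matrix(rnorm(6 * n, 8, 0.3), 6, n,
                 dimnames = dimnames(cn))
  expr["g1", ] <- 8 + 2 * cn["g1", ] + rnorm(n, 0, 0.1)
  expr["g2", ] <- 8 + 2 * cn["g2", ] + rnorm(n, 0, 0.1)
  manual_bundle(expr, cn)
}

test_that("candidate cascade applies gain, rho and q thresholds as stated", {
  b <- make_cascade_bundle()
  cand <- candidate_drivers(b, overexpressed = paste0("g", 1:6))
  # g2 fails the gain filter before any correlation is computed
  expect_false("g2" %in% cand$gene_id)
  expect_true("g1" %in% cand$gene_id[cand$passes])
  expect_false(isTRUE(cand$passes[cand$gene_id == "g3"]))
  # no over-expressed genes -> empty table, not an error
  empty <- candidate_drivers(b, overexpressed = character(0))
  expect_identical(nrow(empty), 0L)
  # monotonicity: raising thresholds never enlarges the passing set
  for (rho_min in c(0.3, 0.5, 0.8)) {
    for (gain_min in c(0.2, 0.4)) {
      sub <- candidate_drivers(b, paste0("g", 1:6),
                               gain_min = gain_min, rho_min = rho_min)
      base <- candidate_drivers(b, paste0("g", 1:6))
      expect_true(all(sub$gene_id[sub$passes] %in% base$gene_id[base$passes]))
    }
  }
})

test_that("exact-boundary rho and gain values do not pass", {
  # rho exactly at the threshold must fail the strict comparison
  fake <- data.frame(gene_id = "g", cohort = "c", gain_fraction = 0.5,
                     rho = 0.3, rho_p = 1e-9, rho_q = 1e-9)
  passes <- fake$rho > 0.3 & fake$rho_q < 1e-3
  expect_false(passes)
  # gain fraction 0.19 is below "at least 20 %"; 0.2 itself passes
  expect_false(0.19 >= 0.2)
  b <- make_cascade_bundle()
  cand <- candidate_drivers(b, paste0("g", 1:6), gain_min = 0.5)
  expect_true(all(cand$gain_fraction >= 0.5))
})

test_that("core signature requires recurrence in min_cancers cohorts", {
  mk <- function(cohort, passers, failers = character(0)) {
    data.frame(gene_id = c(passers, failers), cohort = cohort,
               gain_fraction = 0.5, rho = 0.6, rho_p = 1e-9, rho_q = 1e-9,
               passes = c(rep(TRUE, length(passers)),
                          rep(FALSE, length(failers))))
  }
  tabs <- list(mk("c1", c("a", "b")), mk("c2", c("a", "b")),
               mk("c3", "a", "b"), mk("c4", character(0), "a"))
  core <- core_signature(tabs, min_cancers = 3)
  expect_identical(core$gene_id, "a")
  expect_identical(core$inclusion_count, 3L)
  expect_false("b" %in% core$gene_id)
  union_all <- core_signature(tabs, min_cancers = 1)
  expect_setequal(union_all$gene_id, c("a", "b"))
})

test_that("loss-side cascade mirrors the gain side for deleted-and-silenced genes", {
  set.seed(77)
  n <- 60
  genes <- c("lost", "gained", "flat")
  cn <- matrix(rnorm(3 * n, 0, 0.05), 3, n,
               dimnames = list(genes, paste0("s", 1:n)))
  cn["lost", 1:30] <- cn["lost", 1:30] - runif(30, 0.4, 1)
  cn["gained", 1:30] <- cn["gained", 1:30] + runif(30, 0.4, 1)
  expr <- matrix(rnorm(3 * n, 8, 0.3), 3, n, dimnames = dimnames(cn))
  expr["lost", ] <- 8 + 2 * cn["lost", ] + rnorm(n, 0, 0.1)
  b <- manual_bundle(expr, cn)
  res <- loss_side_candidates(b, underexpressed = genes)
  expect_true(res$passes[res$gene_id == "lost"])
  expect_false("gained" %in% res$gene_id)
  empty <- loss_side_candidates(b, underexpressed = character(0))
  expect_identical(nrow(empty), 0L)
})

test_that("full cascade on simulated cohorts recovers the planted drivers", {
  sims <- simulate_pan_cancer(simulation_params(seed = 42))
  res <- driver_cascade(lapply(sims, function(s) s$bundle))
  truth <- sims[[1]]$truth$planted_drivers
  expect_gte(mean(truth %in% res$core$gene_id), 0.9)
  fp <- setdiff(res$core$gene_id, truth)
  expect_lte(length(fp), 0.01 * (2000 - length(truth)))
  expect_true(all(res$core$inclusion_count >= 3))
})
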