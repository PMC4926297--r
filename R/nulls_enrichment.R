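## Permutation-null constructions and overlap tests: random-gene-set
## enrichment, mRNA-mRNA null percentiles, correlation-count tables against
## known-driver lists, and hypergeometric overlaps.
##
## All empirical p-values use the add-one (permutation-inclusive) estimator
## (1 + #{null at least as extreme}) / (1 + n_iter), so they are always in
## (0, 1]; every operation is a pure function of its seed.

#' Null distribution of mRNA-mRNA correlations
#'
#' Samples two disjoint sets of `set_size` genes and computes all
#' `set_size^2` cross-pair Spearman correlations (with the default 1000 x
#' 1000 design this is one million correlations). The 95th and 5th empirical
#' percentiles of this distribution serve as correlation cutoffs downstream.
#'
#' @param expr Gene x sample expression matrix with at least `2 * set_size`
#'   genes.
#' @param set_size Genes per set (default 1000).
#' @param seed Integer seed.
#' @return List of class `null_distribution`: `values` (numeric vector of
#'   length set_size^2), `p95`, `p05`, `n_draws`, `seed`.
#' @export
mrna_mrna_null <- function(expr, set_size = 1000L, seed = 1L) {
  if (nrow(expr) < 2L * set_size) {
    stop("need at least ", 2L * set_size, " genes; reduce set_size for ",
         "smaller matrices")
  }
  set.seed(seed)
  picked <- sample.int(nrow(expr), 2L * set_size)
  a <- picked[seq_len(set_size)]
  b <- picked[set_size + seq_len(set_size)]
  ra <- rank_rows(expr[a, , drop = FALSE])
  rb <- rank_rows(expr[b, , drop = FALSE])
  values <- as.vector(cor(t(ra), t(rb)))
  structure(list(values = values,
                 p95 = unname(quantile(values, 0.95, type = 7)),
                 p05 = unname(quantile(values, 0.05, type = 7)),
                 n_draws = length(values), seed = seed),
            class = "null_distribution")
}

## rank each row (mid-ranks for ties)
rank_rows <- function(m) {
  t(apply(m, 1L, rank))
}

#' Size-matched random-gene-set enrichment probability
#'
#' Draws `n_iter` gene sets of size `set_size` from `universe \ excluded`,
#' evaluates `statistic` on each, and returns the add-one empirical
#' probability that a random set attains a statistic at least as large as
#' `observed`.
#'
#' @param universe Character vector: the gene universe to draw from.
#' @param excluded Genes never drawn (e.g. the metabolic genome when the
#'   observed set is metabolic).
#' @param set_size Size of each random set.
#' @param observed The observed statistic value.
#' @param statistic Function: character vector of gene ids -> single number.
#' @param n_iter Number of random sets (default 10000).
#' @param seed Integer seed.
#' @return List with `p`, `null_values`, `observed`.
#' @export
geneset_size_matched_null <- function(universe, excluded, set_size, observed,
                                      statistic, n_iter = 10000L, seed = 1L) {
  pool <- setdiff(universe, excluded)
  if (length(pool) < set_size) stop("universe minus exclusions smaller than set_size")
  set.seed(seed)
  null_values <- vapply(seq_len(n_iter), function(i) {
    statistic(sample(pool, set_size))
  }, numeric(1L))
  list(p = (1 + sum(null_values >= observed)) / (1 + n_iter),
       null_values = null_values, observed = observed)
}

#' Correlation-count table against a driver list
#'
#' For each metabolic gene, counts how many genes of the driver list its
#' expression profile correlates with beyond the null cutoffs: `rho >
#' null$p95` (correlated) and `rho < null$p05` (anti-correlated). Self-pairs
#' (a metabolic gene also present in the driver list) are excluded.
#'
#' @param metabolic Character vector of metabolic gene ids.
#' @param drivers Character vector of driver gene ids.
#' @param expr Gene x sample expression matrix containing both sets.
#' @param null A `null_distribution` from [mrna_mrna_null()].
#' @return data.frame gene_id, correlated_count, anticorrelated_count,
#'   n_drivers_tested.
#' @export
correlation_count_table <- function(metabolic, drivers, expr, null) {
  metabolic <- intersect(metabolic, rownames(expr))
  drivers <- intersect(drivers, rownames(expr))
  if (length(metabolic) == 0L || length(drivers) == 0L) {
    stop("metabolic and driver sets must be present in the matrix")
  }
  rho <- cross_spearman(expr[metabolic, , drop = FALSE],
                        expr[drivers, , drop = FALSE])
  self <- outer(metabolic, drivers, "==")
  rho[self] <- NA_real_
  data.frame(
    gene_id = metabolic,
    correlated_count = rowSums(rho > null$p95, na.rm = TRUE),
    anticorrelated_count = rowSums(rho < null$p05, na.rm = TRUE),
    n_drivers_tested = rowSums(!is.na(rho)),
    stringsAsFactors = FALSE)
}

## Spearman correlations of every row of `a` against every row of `b`.
cross_spearman <- function(a, b) {
  cor(t(rank_rows(a)), t(rank_rows(b)))
}

#' Empirical enrichment p-values for a correlation-count table
#'
#' For each metabolic gene, the add-one probability that a random gene set
#' (size-matched to the driver list, drawn from `universe` minus the
#' metabolic gene itself) yields a correlated count at least as large as the
#' observed one. One shared collection of `n_iter` random sets is used for
#' the whole table.
#'
#' @param counts data.frame from [correlation_count_table()].
#' @param drivers The driver list that produced `counts`.
#' @param expr Gene x sample expression matrix.
#' @param null The `null_distribution` used for the cutoffs.
#' @param universe Genes to draw random sets from (defaults to all genes in
#'   `expr`).
#' @param n_iter Number of shared random sets (default 10000).
#' @param seed Integer seed.
#' @return `counts` with an extra `p_enriched` column.
#' @export
count_table_enrichment_p <- function(counts, drivers, expr, null,
                                     universe = rownames(expr),
                                     n_iter = 10000L, seed = 1L) {
  metabolic <- counts$gene_id
  drivers <- intersect(drivers, rownames(expr))
  k <- length(drivers)
  pool <- intersect(universe, rownames(expr))
  set.seed(seed)
  draw_sets <- replicate(n_iter, sample(pool, k), simplify = FALSE)
  ## correlations of each metabolic gene against the whole pool, once
  rho <- cross_spearman(expr[metabolic, , drop = FALSE],
                        expr[pool, , drop = FALSE])
  hit <- rho > null$p95
  hit[outer(metabolic, pool, "==")] <- NA
  pool_index <- setNames(seq_along(pool), pool)
  p <- vapply(seq_along(metabolic), function(i) {
    null_counts <- vapply(draw_sets, function(s) {
      sum(hit[i, pool_index[s]], na.rm = TRUE)
    }, numeric(1L))
    (1 + sum(null_counts >= counts$correlated_count[i])) / (1 + n_iter)
  }, numeric(1L))
  counts$p_enriched <- p
  counts
}

#' Exact hypergeometric overlap test
#'
#' Exact upper-tail `P(X >= overlap)` and lower-tail `P(X <= overlap)`
#' probabilities for the overlap of two gene sets drawn from a common
#' universe.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector: the common gene universe.
#' @return List with `overlap`, `p_enriched`, `p_depleted`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  m <- length(set_b)
  n <- length(universe) - m
  d <- length(set_a)
  list(overlap = k,
       p_enriched = phyper(k - 1, m, n, d, lower.tail = FALSE),
       p_depleted = phyper(k, m, n, d, lower.tail = TRUE))
}

#' Permutation null for a set-overlap count
#'
#' Draws `n_iter` random gene sets of size `set_size` from `universe \
#' excluded_pool`, counts their overlap with `reference`, and returns the
#' add-one empirical probability of the requested tail at
#' `observed_overlap`. Converges to the exact hypergeometric tail when
#' `excluded_pool` is empty.
#'
#' @param reference Character vector: the fixed set overlaps are counted
#'   against.
#' @param excluded_pool Genes never drawn.
#' @param universe The gene universe.
#' @param set_size Size of each random set.
#' @param observed_overlap The observed overlap count.
#' @param side `"low"` for P(overlap <= observed), `"high"` for
#'   P(overlap >= observed).
#' @param n_iter Number of random sets (default 100000).
#' @param seed Integer seed.
#' @return List with `p` and `null_overlaps`.
#' @export
permutation_overlap_null <- function(reference, excluded_pool, universe,
                                     set_size, observed_overlap,
                                     side = c("low", "high"),
                                     n_iter = 100000L, seed = 1L) {
  side <- match.arg(side)
  pool <- setdiff(universe, excluded_pool)
  if (length(pool) < set_size) stop("universe minus exclusions smaller than set_size")
  set.seed(seed)
  in_ref <- pool %in% reference
  null_overlaps <- vapply(seq_len(n_iter), function(i) {
    sum(in_ref[sample.int(length(pool), set_size)])
  }, numeric(1L))
  p <- if (side == "low") {
    (1 + sum(null_overlaps <= observed_overlap)) / (1 + n_iter)
  } else {
    (1 + sum(null_overlaps >= observed_overlap)) / (1 + n_iter)
  }
  list(p = p, null_overlaps = null_overlaps)
}

#' Filter a driver list by cohort mutation frequency
#'
#' Restricts a gene list to genes somatically mutated in more than
#' `min_freq` of the cohort's samples — the gate used to derive
#' cancer-specific driver lists from a global catalogue.
#'
#' @param genes Candidate gene list.
#' @param mutations Mutation data.frame (gene_id, sample_id, variant_class).
#' @param samples All sample ids of the cohort (the frequency denominator).
#' @param min_freq Frequency threshold (exclusive), default 0.05.
#' @return The genes whose mutation frequency exceeds `min_freq`.
#' @export
mutation_frequency_filter <- function(genes, mutations, samples,
                                      min_freq = 0.05) {
  mut <- unique(mutations[mutations$gene_id %in% genes &
                            mutations$sample_id %in% samples,
                          c("gene_id", "sample_id")])
  freq <- table(factor(mut$gene_id, levels = genes)) / length(samples)
  genes[as.vector(freq) > min_freq]
}
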