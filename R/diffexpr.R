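## Tumour-vs-normal and mutant-vs-wild-type differential expression.
##
## Tests are Welch (unequal-variance) t-tests on log2 abundance; multiple
## testing is controlled with Benjamini-Hochberg. Fold changes are mean
## differences on the log2 scale.

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test between two groups of log2 values, returning the
#' statistic, p-value and the log2 fold change `mean(a) - mean(b)`. If both
#' groups are constant with equal means the test is degenerate and returns
#' `t = 0, p = 1`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Named list with `t_stat`, `p`, `log2_fc`, `df`.
#' @export
welch_t <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 values")
  m1 <- mean(group_a); m2 <- mean(group_b)
  v1 <- var(group_a); v2 <- var(group_b)
  se2 <- v1 / n1 + v2 / n2
  fc <- m1 - m2
  if (se2 == 0) {
    if (fc == 0) return(list(t_stat = 0, p = 1, log2_fc = 0, df = n1 + n2 - 2))
    return(list(t_stat = sign(fc) * Inf, p = 0, log2_fc = fc,
                df = n1 + n2 - 2))
  }
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t_stat <- fc / sqrt(se2)
  list(t_stat = t_stat, p = 2 * pt(-abs(t_stat), df), log2_fc = fc, df = df)
}

## Row-wise Welch test of two matrices sharing gene rows; returns a DeResult
## data.frame. Vectorised because cohort-scale DE is on thousands of genes.
welch_t_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  stopifnot(n1 >= 2L, n2 >= 2L, nrow(a) == nrow(b))
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  fc <- m1 - m2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t_stat <- fc / sqrt(se2)
  p <- 2 * pt(-abs(t_stat), df)
  deg <- se2 == 0
  t_stat[deg] <- ifelse(fc[deg] == 0, 0, sign(fc[deg]) * Inf)
  p[deg] <- ifelse(fc[deg] == 0, 1, 0)
  data.frame(gene_id = rownames(a), log2_fc = unname(fc),
             t_stat = unname(t_stat), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (clipped at 1), in the input order. Thin wrapper
#' over `stats::p.adjust(method = "BH")` with input validation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Tumour-versus-normal differential expression table
#'
#' Row-wise Welch t-tests of tumour against normal samples on the shared
#' genes, with BH adjustment across genes.
#'
#' @param tumour_expr,normal_expr Gene x sample log2 expression matrices with
#'   identical gene rows.
#' @return data.frame with gene_id, log2_fc (tumour - normal), t_stat, p, q.
#' @export
de_table <- function(tumour_expr, normal_expr) {
  common <- intersect(rownames(tumour_expr), rownames(normal_expr))
  if (length(common) == 0L) stop("no shared genes between tumour and normal")
  de <- welch_t_rows(tumour_expr[common, , drop = FALSE],
                     normal_expr[common, , drop = FALSE])
  de$q <- bh_adjust(de$p)
  de
}

#' Select over-expressed genes
#'
#' Genes with `log2_fc > fc_min` and, when `use_q` is set, `q < q_max`
#' (strict inequalities on both). Cohorts without a usable q (e.g. when
#' normal samples come from a different platform) are handled with
#' `use_q = FALSE`, i.e. a fold-change-only rule.
#'
#' @param de DeResult data.frame from [de_table()].
#' @param fc_min Log2 fold-change threshold (default 0.5).
#' @param q_max q-value threshold (default 0.05).
#' @param use_q Whether to apply the q filter.
#' @return Character vector of selected gene ids.
#' @export
select_overexpressed <- function(de, fc_min = 0.5, q_max = 0.05, use_q = TRUE) {
  keep <- de$log2_fc > fc_min
  if (use_q) keep <- keep & de$q < q_max
  de$gene_id[keep]
}

#' Select under-expressed genes (loss-side mirror)
#'
#' @inheritParams select_overexpressed
#' @return Gene ids with `log2_fc < -fc_min` (and `q < q_max` if `use_q`).
#' @export
select_underexpressed <- function(de, fc_min = 0.5, q_max = 0.05, use_q = TRUE) {
  keep <- de$log2_fc < -fc_min
  if (use_q) keep <- keep & de$q < q_max
  de$gene_id[keep]
}

#' Top decile of over-expressed metabolic genes
#'
#' Restricts the DE table to metabolic genes, applies
#' [select_overexpressed()], ranks the passers by descending log2 fold
#' change and keeps the top `ceiling(decile * |metabolic|)`. By default the
#' decile denominator is the whole metabolic gene universe (set
#' `denominator = "passers"` to use only the significant genes instead).
#' Ties at the cutoff are broken by smaller q, then lexicographic gene id.
#'
#' @param de DeResult data.frame.
#' @param metabolic Character vector: the metabolic gene universe.
#' @param use_q Passed to [select_overexpressed()].
#' @param decile Fraction kept (default 0.10).
#' @param denominator `"universe"` (default) or `"passers"`.
#' @param fc_min,q_max Selection thresholds.
#' @return Character vector of gene ids, at most the decile size.
#' @export
top_decile_overexpressed <- function(de, metabolic, use_q = TRUE,
                                     decile = 0.10,
                                     denominator = c("universe", "passers"),
                                     fc_min = 0.5, q_max = 0.05) {
  denominator <- match.arg(denominator)
  de <- de[de$gene_id %in% metabolic, , drop = FALSE]
  passers <- select_overexpressed(de, fc_min = fc_min, q_max = q_max,
                                  use_q = use_q)
  base_n <- if (denominator == "universe") length(metabolic) else length(passers)
  k <- min(ceiling(decile * base_n), length(passers))
  if (k <= 0L) return(character(0L))
  sub <- de[match(passers, de$gene_id), , drop = FALSE]
  ord <- order(-sub$log2_fc, sub$q, sub$gene_id)
  sub$gene_id[ord][seq_len(k)]
}

#' Mutant-versus-wild-type expression stratification
#'
#' For each target gene, Welch t-test of expression between carriers and
#' non-carriers of a somatic mutation in `driver`, BH-adjusted across
#' targets. A target is flagged significant when `|log2_fc| > 1` and
#' `q < 0.1`.
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param mutations Mutation data.frame (gene_id, sample_id, variant_class).
#' @param driver Gene whose mutation status defines the strata.
#' @param targets Gene ids to test.
#' @return data.frame gene_id, log2_fc (mutant - wild-type), t_stat, p, q,
#'   significant.
#' @export
mutation_stratified_de <- function(expr, mutations, driver, targets) {
  mut_samples <- unique(mutations$sample_id[mutations$gene_id == driver])
  mut <- colnames(expr) %in% mut_samples
  if (sum(mut) < 2L || sum(!mut) < 2L) {
    stop("driver ", driver, " has a stratum with fewer than 2 samples")
  }
  targets <- intersect(targets, rownames(expr))
  de <- welch_t_rows(expr[targets, mut, drop = FALSE],
                     expr[targets, !mut, drop = FALSE])
  de$q <- bh_adjust(de$p)
  de$significant <- abs(de$log2_fc) > 1 & de$q < 0.1
  de
}
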