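## Per-sample hypoxia scoring and signature-vs-background association tests.
##
## The score is the mean, over signature genes, of the within-cohort
## z-scored expression of each gene — a location/scale-free summary that is
## monotone-equivalent to the common signature summary scores. Genes with
## zero variance carry no information and are skipped. A median-of-ranks
## alternative is available for robustness checks.

#' Per-sample hypoxia signature score
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param signature Character vector of signature gene ids (at least one
#'   must be present in `expr`).
#' @param method `"mean_z"` (default): mean of within-cohort z-scored
#'   signature-gene expression; `"median_rank"`: median of within-gene
#'   sample ranks scaled to \[0, 1\].
#' @return Named numeric vector, one score per sample.
#' @export
hypoxia_score <- function(expr, signature, method = c("mean_z", "median_rank")) {
  method <- match.arg(method)
  sig <- intersect(signature, rownames(expr))
  if (length(sig) == 0L) stop("no signature genes present in the matrix")
  sub <- expr[sig, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  sub <- sub[sds > 0, , drop = FALSE]
  if (nrow(sub) == 0L) stop("all signature genes have zero variance")
  if (method == "mean_z") {
    z <- (sub - rowMeans(sub)) / apply(sub, 1L, sd)
    colMeans(z)
  } else {
    ranks <- t(apply(sub, 1L, rank)) / ncol(sub)
    apply(ranks, 2L, median)
  }
}

#' Per-gene correlations with the hypoxia score
#'
#' Spearman correlation of each gene's profile (expression or copy-number
#' log2 ratio) against the per-sample hypoxia score. Genes that are
#' themselves part of the scoring signature are always removed from the
#' tested set (in addition to any caller-supplied exclusions) to avoid
#' self-correlation.
#'
#' @param mat Gene x sample matrix (expression or cn_log2).
#' @param scores Named score vector from [hypoxia_score()].
#' @param genes Gene ids to test.
#' @param signature The scoring signature (always excluded).
#' @param exclude Additional gene ids to exclude.
#' @return Named numeric vector of Spearman rho, one per tested gene.
#' @export
gene_hypoxia_correlations <- function(mat, scores, genes, signature,
                                      exclude = character(0L)) {
  test <- setdiff(intersect(genes, rownames(mat)), c(signature, exclude))
  if (length(test) == 0L) stop("no genes left to test after exclusions")
  samples <- intersect(colnames(mat), names(scores))
  vapply(test, function(g) {
    spearman(mat[g, samples], scores[samples])$rho
  }, numeric(1L))
}

#' One-sided signature-versus-background comparison
#'
#' Wilcoxon rank-sum test of whether the signature genes' correlations are
#' stochastically greater than the background genes' correlations. The exact
#' distribution is used when both groups have at most 50 values and there
#' are no ties; otherwise the normal approximation with continuity
#' correction.
#'
#' @param sig_rhos,other_rhos Non-empty numeric vectors.
#' @return One-sided p-value.
#' @export
signature_vs_other_test <- function(sig_rhos, other_rhos) {
  if (length(sig_rhos) == 0L || length(other_rhos) == 0L) {
    stop("both correlation sets must be non-empty")
  }
  exact <- length(sig_rhos) <= 50L && length(other_rhos) <= 50L &&
    !anyDuplicated(c(sig_rhos, other_rhos))
  wilcox.test(sig_rhos, other_rhos, alternative = "greater",
              exact = exact, correct = TRUE)$p.value
}

#' Association between hypoxia and copy-number gain burden
#'
#' Spearman correlation between the hypoxia score and the per-sample gained
#' fraction of a gene set, plus a one-sided Wilcoxon test comparing the
#' gained fractions of samples above versus at-or-below the median hypoxia
#' score. A constant gained fraction leaves rho undefined and p = 1.
#'
#' @param scores Named hypoxia score vector.
#' @param per_sample_gained Named per-sample gained-fraction vector (see
#'   [per_sample_gained_fraction()]).
#' @return List with `rho` and `p` (one-sided Wilcoxon).
#' @export
hypoxia_scna_association <- function(scores, per_sample_gained) {
  samples <- intersect(names(scores), names(per_sample_gained))
  if (length(samples) < 4L) stop("need >= 4 shared samples")
  g <- per_sample_gained[samples]
  s <- scores[samples]
  if (sd(g) == 0) return(list(rho = NA_real_, p = 1))
  rho <- spearman(s, g)$rho
  hi <- s > median(s)
  p <- wilcox.test(g[hi], g[!hi], alternative = "greater",
                   exact = FALSE, correct = TRUE)$p.value
  list(rho = rho, p = p)
}
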