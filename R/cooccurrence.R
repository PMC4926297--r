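## Pairwise amplification co-occurrence testing and cytoband proximity
## clustering.
##
## The two-sided Fisher p-value follows the "probability mass <= observed"
## convention: over the margin-fixed hypergeometric support, the
## probabilities of all tables no more probable than the observed one are
## summed (with a tiny relative tolerance for floating-point ties, as in
## stats::fisher.test). The odds ratio reported is the sample odds ratio
## (ad)/(bc) with the usual 0/Inf conventions for zero cells, not the
## conditional maximum-likelihood estimate.

#' Build a 2x2 amplification co-occurrence table
#'
#' Counts, over pairwise-complete samples, how often both genes are
#' amplified, only one is, or neither is. "Amplified" means call >= 1 when
#' `merged` (gain and amplification treated as one category) and call == 2
#' otherwise.
#'
#' @param calls_a,calls_b Equal-length integer SCNA call vectors.
#' @param merged Treat gains and amplifications as one category.
#' @return 2x2 integer matrix: rows = gene a amplified yes/no, columns =
#'   gene b amplified yes/no.
#' @export
build_2x2 <- function(calls_a, calls_b, merged = TRUE) {
  if (length(calls_a) != length(calls_b)) stop("call vectors differ in length")
  ok <- !is.na(calls_a) & !is.na(calls_b)
  thr <- if (merged) 1L else 2L
  a <- calls_a[ok] >= thr
  b <- calls_b[ok] >= thr
  matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(a_amplified = c("yes", "no"),
                         b_amplified = c("yes", "no")))
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional exact test: with margins fixed, the two-sided p-value sums
#' the hypergeometric probabilities of every table whose probability does
#' not exceed the observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` (sample OR) and `p` (two-sided).
#' @export
fisher_exact <- function(table) {
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  or <- if (b == 0 || c_ == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  m <- a + b          # row-1 total
  n <- c_ + d         # row-2 total
  k <- a + c_         # column-1 total
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(p, 1))
}

#' Pairwise co-occurrence tests over a candidate gene set
#'
#' Builds the 2x2 table and Fisher test for every unordered pair from
#' `genes` (optionally against a second `anchors` set instead of all
#' within-set pairs).
#'
#' @param calls Gene x sample SCNA call matrix.
#' @param genes Candidate gene ids.
#' @param anchors Optional second gene set; if supplied, only
#'   candidate-anchor pairs are tested.
#' @param merged Passed to [build_2x2()].
#' @param bh Add a BH-adjusted q column over the tested pairs.
#' @return data.frame gene_a, gene_b, n_both, n_only_a, n_only_b, n_neither,
#'   odds_ratio, p (and q when `bh`).
#' @export
cooccurrence_tests <- function(calls, genes, anchors = NULL, merged = TRUE,
                               bh = FALSE) {
  genes <- intersect(genes, rownames(calls))
  if (is.null(anchors)) {
    if (length(genes) < 2L) stop("need >= 2 genes")
    pairs <- t(utils::combn(genes, 2L))
  } else {
    anchors <- intersect(anchors, rownames(calls))
    pairs <- as.matrix(expand.grid(gene_a = genes, gene_b = anchors,
                                   stringsAsFactors = FALSE))
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    tab <- build_2x2(calls[pairs[i, 1L], ], calls[pairs[i, 2L], ],
                     merged = merged)
    ft <- fisher_exact(tab)
    data.frame(gene_a = pairs[i, 1L], gene_b = pairs[i, 2L],
               n_both = tab[1L, 1L], n_only_a = tab[1L, 2L],
               n_only_b = tab[2L, 1L], n_neither = tab[2L, 2L],
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (bh) out$q <- bh_adjust(out$p)
  out
}

## parse a cytoband label like "p03" or "q12.1" into arm and major band index
parse_band <- function(cytoband) {
  arm <- substr(cytoband, 1L, 1L)
  num <- suppressWarnings(as.numeric(sub("^[pq]", "", cytoband)))
  list(arm = arm, band = floor(num))
}

#' Cluster co-occurring genes on proximal cytobands
#'
#' Groups candidate and anchor genes that (a) lie on the same chromosome
#' arm with major band indices differing by at most one ("proximal bands")
#' and (b) show significant pairwise amplification co-occurrence
#' (`p < alpha`). Clusters are the connected components (of size >= 2) of
#' the resulting gene graph. Genes without annotation are dropped with a
#' warning.
#'
#' @param candidates,anchors Gene id vectors (the union is clustered).
#' @param ann Annotation data.frame with gene_id, chromosome, cytoband.
#' @param results Pairwise results from [cooccurrence_tests()].
#' @param alpha Significance threshold on the pairwise Fisher p.
#' @return List of clusters; each is a list with `genes` (character vector)
#'   and `min_p` (smallest pairwise p inside the cluster).
#' @export
band_proximity_clusters <- function(candidates, anchors, ann, results,
                                    alpha = 0.05) {
  genes <- unique(c(candidates, anchors))
  known <- genes %in% ann$gene_id
  if (any(!known)) {
    warning("dropping genes without annotation: ",
            paste(genes[!known], collapse = ", "))
    genes <- genes[known]
  }
  idx <- match(genes, ann$gene_id)
  chrom <- ann$chromosome[idx]
  band <- parse_band(ann$cytoband[idx])
  sig <- results[results$p < alpha, , drop = FALSE]
  ## adjacency: proximal bands + significant co-occurrence
  n <- length(genes)
  adj <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  pmat <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(nrow(sig))) {
    ga <- sig$gene_a[i]; gb <- sig$gene_b[i]
    if (!(ga %in% genes) || !(gb %in% genes)) next
    ia <- match(ga, genes); ib <- match(gb, genes)
    proximal <- chrom[ia] == chrom[ib] && band$arm[ia] == band$arm[ib] &&
      abs(band$band[ia] - band$band[ib]) <= 1
    if (proximal) {
      adj[ia, ib] <- adj[ib, ia] <- TRUE
      pmat[ia, ib] <- pmat[ib, ia] <- sig$p[i]
    }
  }
  ## connected components by BFS
  seen <- rep(FALSE, n)
  clusters <- list()
  for (s in seq_len(n)) {
    if (seen[s] || !any(adj[s, ])) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0L) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    clusters[[length(clusters) + 1L]] <- list(
      genes = sort(genes[comp]),
      min_p = min(pmat[comp, comp], na.rm = TRUE))
  }
  clusters
}
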