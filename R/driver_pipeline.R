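## The candidate-driver cascade: over-expression, recurrent gain and
## DNA-mRNA dosage correlation per cohort, then cross-cancer core-signature
## assembly; plus the mirrored loss-side analysis.
##
## A gene passes within a cohort when it is over-expressed, gained or
## amplified in at least `gain_min` of samples, and its expression correlates
## with its copy-number log2 ratio at Spearman rho > rho_min with BH q <
## q_max. The q adjustment universe is the set of genes actually tested in
## that cohort (those surviving the over-expression and gain filters).

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected Spearman correlation (Pearson correlation of mid-ranks) with
#' a two-sided p-value from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}. Missing pairs are deleted
#' pairwise. A constant vector leaves rho undefined (`NA` result, not an
#' error).
#'
#' @param x,y Numeric vectors of equal length with >= 3 complete pairs.
#' @return Named list with `rho`, `p`, `n` (complete pairs used).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) stop("need >= 3 complete pairs")
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  p <- spearman_p(rho, n)
  list(rho = rho, p = p, n = n)
}

spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t_stat), n - 2)
}

## Spearman of each row of `a` against the matching row of `b`; pairwise NA
## deletion per row. Returns data.frame(gene_id, rho, p, n).
spearman_rows <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  out <- vapply(seq_len(nrow(a)), function(i) {
    s <- spearman(a[i, ], b[i, ])
    c(s$rho, s$p, s$n)
  }, numeric(3L))
  data.frame(gene_id = rownames(a), rho = out[1L, ], p = out[2L, ],
             n = as.integer(out[3L, ]), stringsAsFactors = FALSE)
}

#' Per-cohort candidate metabolic drivers
#'
#' Runs the gain-side cascade within one cohort: restrict to the supplied
#' over-expressed genes, require a gained fraction of at least `gain_min`,
#' correlate expression with the copy-number log2 ratio across tumour
#' samples, BH-adjust the correlation p-values over the genes tested, and
#' flag genes with `rho > rho_min` and `q < q_max` (strict) as passing.
#'
#' @param cohort A harmonised `cohort_bundle` with `scna_calls`.
#' @param overexpressed Character vector of over-expressed gene ids.
#' @param gain_min Minimum gained fraction (inclusive), default 0.2.
#' @param rho_min Spearman threshold (exclusive), default 0.3.
#' @param q_max q-value threshold (exclusive), default 1e-3.
#' @return data.frame with gene_id, cohort, gain_fraction, rho, rho_p, rho_q,
#'   passes. Empty (zero rows) when nothing survives the gain filter.
#' @export
candidate_drivers <- function(cohort, overexpressed, gain_min = 0.2,
                              rho_min = 0.3, q_max = 1e-3) {
  if (is.null(cohort$scna_calls)) stop("cohort has no SCNA calls; run add_scna_calls()")
  fr <- altered_fractions(cohort$scna_calls)
  tested <- fr$gene_id[fr$gene_id %in% overexpressed &
                         !is.na(fr$gained_fraction) &
                         fr$gained_fraction >= gain_min]
  if (length(tested) == 0L) {
    return(empty_candidates())
  }
  cors <- spearman_rows(cohort$tumour_expr[tested, , drop = FALSE],
                        cohort$cn_log2[tested, , drop = FALSE])
  ok <- !is.na(cors$p)
  q <- rep(NA_real_, nrow(cors))
  q[ok] <- bh_adjust(cors$p[ok])
  data.frame(
    gene_id = tested,
    cohort = cohort$name,
    gain_fraction = fr$gained_fraction[match(tested, fr$gene_id)],
    rho = cors$rho,
    rho_p = cors$p,
    rho_q = q,
    passes = !is.na(cors$rho) & cors$rho > rho_min & !is.na(q) & q < q_max,
    stringsAsFactors = FALSE
  )
}

empty_candidates <- function() {
  data.frame(gene_id = character(0L), cohort = character(0L),
             gain_fraction = numeric(0L), rho = numeric(0L),
             rho_p = numeric(0L), rho_q = numeric(0L),
             passes = logical(0L), stringsAsFactors = FALSE)
}

#' Loss-side candidate analysis
#'
#' Mirror of [candidate_drivers()] for under-expressed genes with recurrent
#' loss: requires `loss_fraction >= loss_min` and the same positive
#' (dosage-concordant) correlation thresholds.
#'
#' @param cohort A harmonised `cohort_bundle` with `scna_calls`.
#' @param underexpressed Character vector of under-expressed gene ids.
#' @param loss_min Minimum lost fraction (inclusive), default 0.2.
#' @inheritParams candidate_drivers
#' @return Same shape as [candidate_drivers()], with `loss_fraction` instead
#'   of `gain_fraction`.
#' @export
loss_side_candidates <- function(cohort, underexpressed, loss_min = 0.2,
                                 rho_min = 0.3, q_max = 1e-3) {
  if (is.null(cohort$scna_calls)) stop("cohort has no SCNA calls; run add_scna_calls()")
  fr <- altered_fractions(cohort$scna_calls)
  tested <- fr$gene_id[fr$gene_id %in% underexpressed &
                         !is.na(fr$loss_fraction) &
                         fr$loss_fraction >= loss_min]
  if (length(tested) == 0L) {
    out <- empty_candidates()
    names(out)[names(out) == "gain_fraction"] <- "loss_fraction"
    return(out)
  }
  cors <- spearman_rows(cohort$tumour_expr[tested, , drop = FALSE],
                        cohort$cn_log2[tested, , drop = FALSE])
  ok <- !is.na(cors$p)
  q <- rep(NA_real_, nrow(cors))
  q[ok] <- bh_adjust(cors$p[ok])
  data.frame(
    gene_id = tested,
    cohort = cohort$name,
    loss_fraction = fr$loss_fraction[match(tested, fr$gene_id)],
    rho = cors$rho,
    rho_p = cors$p,
    rho_q = q,
    passes = !is.na(cors$rho) & cors$rho > rho_min & !is.na(q) & q < q_max,
    stringsAsFactors = FALSE
  )
}

#' Cross-cancer core signature
#'
#' Genes whose `passes` flag is `TRUE` in at least `min_cancers` of the
#' supplied per-cohort candidate tables, with their inclusion counts.
#'
#' @param candidates List of data.frames from [candidate_drivers()] (one per
#'   cohort).
#' @param min_cancers Minimum number of cohorts (default 3).
#' @return data.frame gene_id, inclusion_count, sorted by decreasing count
#'   then gene id.
#' @export
core_signature <- function(candidates, min_cancers = 3L) {
  all_pass <- unlist(lapply(candidates, function(d) d$gene_id[d$passes]))
  if (length(all_pass) == 0L) {
    return(data.frame(gene_id = character(0L), inclusion_count = integer(0L),
                      stringsAsFactors = FALSE))
  }
  counts <- table(all_pass)
  keep <- counts[counts >= min_cancers]
  out <- data.frame(gene_id = names(keep),
                    inclusion_count = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(-out$inclusion_count, out$gene_id), , drop = FALSE]
}

#' Run the full gain-side cascade over a list of cohorts
#'
#' Convenience wrapper: per cohort, tumour-vs-normal DE (q filter used only
#' when normals are present), over-expression selection, the candidate
#' cascade, then the cross-cancer core signature.
#'
#' @param cohorts List of harmonised `cohort_bundle`s with SCNA calls.
#' @param min_cancers Minimum number of cohorts for the core signature.
#' @param fc_min,q_max_de Over-expression thresholds.
#' @param gain_min,rho_min,q_max_rho Cascade thresholds.
#' @return List with `per_cohort` (candidate tables), `overexpressed`
#'   (per-cohort gene sets) and `core` (the core-signature data.frame).
#' @export
driver_cascade <- function(cohorts, min_cancers = 3L, fc_min = 0.5,
                           q_max_de = 0.05, gain_min = 0.2, rho_min = 0.3,
                           q_max_rho = 1e-3) {
  per_cohort <- list()
  overexpressed <- list()
  for (cohort in cohorts) {
    if (is.null(cohort$normal_expr)) {
      stop("cohort ", cohort$name, " has no normal samples; supply an ",
           "over-expressed set directly via candidate_drivers()")
    }
    de <- de_table(cohort$tumour_expr, cohort$normal_expr)
    over <- select_overexpressed(de, fc_min = fc_min, q_max = q_max_de,
                                 use_q = TRUE)
    overexpressed[[cohort$name]] <- over
    per_cohort[[cohort$name]] <- candidate_drivers(
      cohort, over, gain_min = gain_min, rho_min = rho_min, q_max = q_max_rho)
  }
  list(per_cohort = per_cohort, overexpressed = overexpressed,
       core = core_signature(per_cohort, min_cancers = min_cancers))
}
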