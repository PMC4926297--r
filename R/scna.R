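## Discretisation of copy-number log2 ratios into SCNA calls and
## altered-fraction summaries.

#' Call discrete SCNA states from log2 ratios
#'
#' Maps a log2 ratio t to a five-state call:
#' \deqn{t > 1 \to 2;\ 0.2 \le t \le 1 \to 1;\ -0.2 < t < 0.2 \to 0;\
#'       -1 \le t \le -0.2 \to -1;\ t < -1 \to -2.}
#' The gain-side boundaries 0.2 and 1 belong to the single-gain state and the
#' loss-side boundaries -0.2 and -1 to the single-loss state (inclusive
#' inequalities on both sides). `NA` input gives an `NA` call; non-finite
#' input is an error.
#'
#' @param t Numeric scalar, vector or matrix of log2 ratios.
#' @return Integer calls in \{-2, -1, 0, 1, 2\}, same shape as `t`.
#' @export
call_scna <- function(t) {
  if (any(is.nan(t) | is.infinite(t))) stop("non-finite log2 ratio")
  call <- ifelse(t > 1, 2L,
          ifelse(t >= 0.2, 1L,
          ifelse(t > -0.2, 0L,
          ifelse(t >= -1, -1L, -2L))))
  if (is.matrix(t)) {
    call <- matrix(as.integer(call), nrow = nrow(t), dimnames = dimnames(t))
  } else {
    call <- as.integer(call)
    names(call) <- names(t)
  }
  call
}

#' Merge gains and amplifications into one category
#'
#' Recodes call 2 to 1, leaving all other states untouched — the convention
#' used for datasets whose copy-number caller does not distinguish gain from
#' amplification reliably. Idempotent.
#'
#' @param calls SCNA call matrix or vector.
#' @return The recoded calls.
#' @export
merge_gain_amp <- function(calls) {
  calls[!is.na(calls) & calls == 2L] <- 1L
  calls
}

#' Per-gene gained and lost fractions
#'
#' For each gene, the fraction of samples with call 1 or 2 (gained) and with
#' call -1 or -2 (lost), computed over non-missing calls so that segment gaps
#' do not deflate the estimate. A gene with no non-missing call gets `NA`
#' fractions.
#'
#' @param calls Gene x sample SCNA call matrix.
#' @return data.frame with columns gene_id, gained_fraction, loss_fraction.
#' @export
altered_fractions <- function(calls) {
  n_obs <- rowSums(!is.na(calls))
  gained <- rowSums(calls >= 1L, na.rm = TRUE) / n_obs
  lost <- rowSums(calls <= -1L, na.rm = TRUE) / n_obs
  gained[n_obs == 0L] <- NA_real_
  lost[n_obs == 0L] <- NA_real_
  data.frame(gene_id = rownames(calls), gained_fraction = unname(gained),
             loss_fraction = unname(lost), stringsAsFactors = FALSE)
}

#' Mean altered fraction over a gene set
#'
#' Unweighted mean of the per-gene gained and lost fractions over the set —
#' an overall genomic-instability summary for the set.
#'
#' @param calls Gene x sample SCNA call matrix.
#' @param genes Character vector of gene ids (non-empty, present in `calls`).
#' @return Named numeric vector `c(mean_gained, mean_loss)`.
#' @export
geneset_instability <- function(calls, genes) {
  if (length(genes) == 0L) stop("empty gene set")
  missing <- setdiff(genes, rownames(calls))
  if (length(missing) > 0L) {
    stop("genes absent from call matrix: ", paste(missing, collapse = ", "))
  }
  fr <- altered_fractions(calls[genes, , drop = FALSE])
  c(mean_gained = mean(fr$gained_fraction, na.rm = TRUE),
    mean_loss = mean(fr$loss_fraction, na.rm = TRUE))
}

#' Per-sample fraction of gained genes in a set
#'
#' For each sample, the fraction of genes in the set carrying call >= 1 —
#' the per-patient summary needed to relate copy-number gain burden to a
#' per-sample covariate such as the hypoxia score.
#'
#' @param calls Gene x sample SCNA call matrix.
#' @param genes Character vector of gene ids (non-empty).
#' @return Named numeric vector, one value per sample.
#' @export
per_sample_gained_fraction <- function(calls, genes) {
  if (length(genes) == 0L) stop("empty gene set")
  sub <- calls[intersect(genes, rownames(calls)), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no genes from the set present in call matrix")
  colSums(sub >= 1L, na.rm = TRUE) / colSums(!is.na(sub))
}
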