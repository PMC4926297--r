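# Shared fixture builders. Everything is generated in code; no data files.

# tiny expression matrix with named genes/samples
tiny_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# write a gene x sample TSV the way the package expects it
write_tsv_matrix <- function(mat, path) {
  write_expression(mat, path)
  path
}

# a small fully-specified cohort bundle with hand-set layers
manual_bundle <- function(tumour, cn, normal = NULL,
                          signature = character(0L)) {
  genes <- rownames(tumour)
  n <- ncol(tumour)
  ann <- data.frame(gene_id = genes, chromosome = "chr1",
                    start = seq_along(genes) * 1000L,
                    end = seq_along(genes) * 1000L + 500L,
                    cytoband = "p01",
                    is_metabolic = TRUE, stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = colnames(tumour),
                         time = rep(1, n), event = rep(TRUE, n),
                         age = rep(60, n), stage = rep(1L, n),
                         subtype = NA_character_, stringsAsFactors = FALSE)
  muts <- data.frame(gene_id = character(0L), sample_id = character(0L),
                     variant_class = character(0L), stringsAsFactors = FALSE)
  b <- cohort_bundle("test", tumour_expr = tumour, cn_log2 = cn,
                     mutations = muts, clinical = clinical, annotation = ann,
                     hypoxia_signature = signature, normal_expr = normal)
  add_scna_calls(b)
}

# simulation parameters with every planted effect switched off
null_sim_params <- function(seed, ...) {
  simulation_params(overexpression_shift = 0, driver_coupling = 0,
                    hypoxia_effect = 0, hypoxia_gain_slope = 0,
                    prognostic_beta = 0, seed = seed, ...)
}

# brute-force BH step-up: q_i = min_{j >= i} p_(j) * n / j (independent oracle)
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * n / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# brute-force SCNA interval lookup (independent oracle)
scna_bruteforce <- function(t) {
  vapply(t, function(x) {
    if (is.na(x)) return(NA_integer_)
    if (x > 1) 2L
    else if (x >= 0.2 && x <= 1) 1L
    else if (x > -0.2 && x < 0.2) 0L
    else if (x >= -1 && x <= -0.2) -1L
    else -2L
  }, integer(1L))
}

# brute-force two-sided Fisher p by enumeration with choose() arithmetic
fisher_bruteforce <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  pobs <- pr[supp == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# brute-force per-base segment average for genes (independent oracle)
segment_per_base_oracle <- function(segs, ann, sample_id) {
  vapply(seq_len(nrow(ann)), function(i) {
    bases <- ann$start[i]:ann$end[i]
    vals <- rep(NA_real_, length(bases))
    s <- segs[segs$sample == sample_id &
                segs$chromosome == ann$chromosome[i], , drop = FALSE]
    for (j in seq_len(nrow(s))) {
      hit <- bases >= s$start[j] & bases <= s$end[j]
      vals[hit] <- s$log2ratio[j]
    }
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1L))
}

# brute-force Harrell concordance over all ordered pairs (independent oracle)
concordance_bruteforce <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- event[i] && (time[i] < time[j] ||
                                 (time[i] == time[j] && !event[j]))
    if (!comparable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}
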