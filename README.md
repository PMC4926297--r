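# metadriver

Integrative discovery of **candidate metabolic driver genes** from matched
tumour expression and DNA copy-number profiles, across multiple cancer
cohorts, in R.

Changes in mRNA abundance can come either from altered transcriptional
regulation or from genomic aberration. A gene whose tumour over-expression
is *explained by* recurrent somatic copy-number gain — i.e. whose mRNA level
tracks its DNA dosage — is a candidate driver rather than a passenger of
transcriptional noise. `metadriver` implements that reasoning as a tested,
reusable pipeline for gene-level multi-cohort data:

1. **SCNA calling.** Copy-number log2 ratios *t* are discretised into five
   states: `2` if *t* > 1, `1` if 0.2 ≤ *t* ≤ 1, `0` if −0.2 < *t* < 0.2,
   `−1` if −1 ≤ *t* ≤ −0.2, `−2` if *t* < −1. Per-gene gained/lost fractions
   and per-sample gain burdens summarise the call matrix.
2. **Differential expression.** Welch *t*-tests of tumour vs normal on the
   log2 scale with Benjamini–Hochberg correction; over-expression means
   log2 FC > 0.5 and *q* < 0.05 (the *q* filter can be dropped for cohorts
   whose normals come from another platform).
3. **The driver cascade.** Within each cohort, a candidate must be
   over-expressed, gained/amplified in ≥ 20 % of samples, and show a
   Spearman correlation between expression and copy-number log2 ratio of
   ρ > 0.3 with BH *q* < 10⁻³. Genes passing in ≥ 3 cohorts form the
   cross-cancer **core signature**.
4. **Hypoxia association.** A per-sample hypoxia score (mean of z-scored
   signature-gene expression) is correlated with candidate-gene expression
   and copy-number gain burden; signature-vs-background contrasts use
   one-sided Wilcoxon rank-sum tests.
5. **Permutation nulls and overlaps.** Size-matched random-gene-set nulls,
   million-pair mRNA–mRNA correlation nulls with 95th/5th-percentile
   cutoffs, correlation-count tables against driver catalogues, and exact
   hypergeometric overlap tests. All empirical *p*-values use the add-one
   estimator.
6. **Co-occurrence.** Pairwise 2×2 Fisher exact tests of amplification
   co-occurrence and proximity clustering on cytobands.
7. **Prognosis.** Median-dichotomised univariate Cox/log-rank screening
   (*P* < 0.1), LASSO-penalised Cox models with ten-fold cross-validation,
   and repeated random train/validation splits evaluated by Harrell's
   concordance index with per-gene inclusion frequencies.

A fully seeded synthetic-cohort generator (`simulate_pan_cancer()`) plants
known drivers, a latent hypoxia axis, hypoxia-coupled gain probabilities and
prognostic genes, so every stage of the pipeline can be validated against
ground truth.

## Worked example

```r
library(metadriver)

# three synthetic cohorts: 200 tumours + 50 normals each, 2000 genes,
# 20 planted dosage-driven drivers (gain fraction 0.5, target rho 0.6)
sims    <- simulate_pan_cancer(simulation_params(seed = 7))
bundles <- lapply(sims, function(s) s$bundle)

res <- driver_cascade(bundles, min_cancers = 3)
nrow(res$core)                                   # 20
truth <- sims[[1]]$truth$planted_drivers
mean(truth %in% res$core$gene_id)                # 1  (all planted drivers found)
head(res$per_cohort[[1]][res$per_cohort[[1]]$passes, c("gene_id", "gain_fraction", "rho")], 3)
#   gene_id gain_fraction       rho
# 1   g0034         0.495 0.6606135
# 2   g0079         0.515 0.6104958
# 3   g0122         0.505 0.5306158

# hypoxia: score tumours, then ask whether candidate drivers track the score
b  <- bundles[[1]]
sc <- hypoxia_score(b$tumour_expr, b$hypoxia_signature)
spearman(sc, sims[[1]]$truth$latent_hypoxia)$rho  # 0.823 (latent axis recovered)
```

The numbers above are what the code prints for `seed = 7`: the cascade
recovers all 20 planted drivers with no false positives among the 1980
unplanted genes, per-gene DNA–mRNA correlations sit near the generator's
target of 0.6, and the hypoxia score reconstructs the latent per-sample
hypoxia axis.

A command-line interface mirroring the pipeline stages
(`simulate`, `call-scna`, `diffexpr`, `drivers`, `hypoxia`, `nulls`,
`cooccur`, `survival`) lives at
`system.file("cli", "metadriver.R", package = "metadriver")`.

## File formats

Expression and copy-number matrices are TSV with a `gene_id` first column;
segments are SEG-style TSV (`sample, chromosome, start, end, log2ratio`,
1-based inclusive coordinates); mutations are a minimal MAF-like TSV;
clinical tables carry `sample_id, time_years, event, age, stage, subtype`;
annotation is BED-like TSV plus `cytoband` and `is_metabolic`; gene lists
are one id per line. See the vignette for details and conventions.
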