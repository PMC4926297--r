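---
title: "Methods: driver discovery, hypoxia association and prognostic modelling in metadriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: driver discovery, hypoxia association and prognostic modelling in metadriver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadriver)
```

## The problem and the model

Tumour transcriptomes are shaped both by transcriptional regulation and by
somatic copy-number alteration (SCNA). When a gene is recurrently gained or
amplified across a cohort *and* its mRNA abundance rises with its DNA dosage,
the over-expression has a genomic explanation and the gene becomes a
candidate driver. `metadriver` operationalises this as a per-cohort cascade
of three filters and a cross-cohort recurrence rule:

* **over-expression** — Welch's unequal-variance *t*-test of tumour against
  normal log2 abundance, Benjamini–Hochberg (BH) corrected; a gene is
  over-expressed when log2 FC > 0.5 and *q* < 0.05. Both inequalities are
  strict. For cohorts whose normal samples are not comparable (different
  platform), the *q* filter can be dropped (`use_q = FALSE`) so that the
  initial sets stay a similar size across cohorts;
* **recurrent gain** — the fraction of samples with SCNA call 1 or 2 must be
  at least 0.2 (inclusive comparison, "at least 20 %");
* **dosage correlation** — Spearman's ρ between expression and copy-number
  log2 ratio across tumour samples must exceed 0.3 with BH *q* < 10⁻³
  (both strict). The BH adjustment universe is the set of genes actually
  tested in that cohort, i.e. those surviving the first two filters; the
  adjustment universe is exposed as an argument because other choices
  (all metabolic genes, pooled cohorts) are defensible;
* **recurrence** — genes passing in at least `min_cancers = 3` cohorts form
  the core signature, with per-gene inclusion counts.

The SCNA caller maps a log2 ratio *t* to
`2 (t > 1), 1 (0.2 ≤ t ≤ 1), 0 (−0.2 < t < 0.2), −1 (−1 ≤ t ≤ −0.2),
−2 (t < −1)`. The gain-side and loss-side threshold lists are mutually
consistent at every boundary, so they are implemented as one piecewise
function; the boundary values 0.2, 1, −0.2 and −1 belong to the single-gain
and single-loss states. Altered fractions are computed over non-missing
calls rather than all samples, so segment gaps do not deflate alteration
estimates. A mirrored loss-side cascade (under-expression, loss fraction,
positive dosage correlation) is provided by `loss_side_candidates()`.

## Hypoxia scoring

Hypoxia both follows from and drives genomic instability, so the package
relates candidate drivers to a per-sample hypoxia score. The score is the
**mean of within-cohort z-scored expression of the signature genes**. A
z-score mean is location- and scale-free per gene (verified by an affine
invariance test), is monotone-equivalent to the usual signature summaries,
and is exactly testable: a sample sitting at the cohort mean of every
signature gene scores 0. A median-of-ranks variant is available via
`method = "median_rank"` for robustness checks. Genes with zero variance are
skipped. The scoring formula itself is a package choice — published hypoxia
signatures specify gene lists rather than a canonical summary statistic —
and the signature gene list is always supplied by the user; the package
ships no curated list.

Association tests: per-gene Spearman correlations against the score (with
scoring-signature genes always removed from the tested set, to avoid
self-correlation), a one-sided Wilcoxon rank-sum comparison of
signature-gene correlations versus background-gene correlations (exact
distribution when both groups have ≤ 50 values and no ties, otherwise the
normal approximation with continuity correction), and a copy-number-side
test correlating the score with each sample's gained fraction over a gene
set, plus a one-sided Wilcoxon of gained fractions in above-median versus
at-or-below-median hypoxia groups. Dichotomisation at the cohort median is
used consistently everywhere in the package (ties at the median go to the
low group).

## Permutation nulls

All empirical *p*-values use the **add-one estimator**
`(1 + #{null ≥ observed}) / (1 + n_iter)`, which can never return 0 and is
the standard convention for permutation tests (at 10⁴ draws the smallest
reportable value is just under 10⁻⁴). Every null construction takes an
explicit seed and is a pure function of it.

* `mrna_mrna_null()` draws two disjoint sets of 1000 genes and takes all
  10⁶ cross-pair Spearman correlations; the 95th and 5th percentiles serve
  as "correlated"/"anti-correlated" cutoffs. The set size is configurable
  so the same construction works on small matrices.
* `geneset_size_matched_null()` evaluates an arbitrary statistic on
  size-matched random gene sets drawn from a universe minus an exclusion
  pool (e.g. random non-metabolic sets matched to a metabolic set's size).
* `correlation_count_table()` counts, per gene, how many members of a
  driver catalogue it correlates with beyond the null cutoffs, excluding
  self-pairs; `count_table_enrichment_p()` compares each observed count to
  counts obtained from random size-matched catalogues. One shared
  collection of random sets is used for a whole table — draws are
  exchangeable across cells and the shared design is much cheaper than
  per-cell redraws.
* `hypergeometric_overlap()` gives exact upper/lower tails for set
  overlaps; `permutation_overlap_null()` is its sampling analogue when the
  draw pool is restricted (e.g. non-metabolic genes only), and converges to
  the exact tail when it is not (verified to within 0.01 at 10⁵ draws).

## Co-occurrence

Amplification co-occurrence between gene pairs uses a 2×2 table over
pairwise-complete samples (both amplified / only one / neither).
"Amplified" means call = 2, or call ≥ 1 when gains and amplifications are
merged (`merge_gain_amp()`, the convention for datasets whose caller does
not separate the two states; the merge is idempotent). The two-sided Fisher
*p* follows the *probability-mass-at-most-observed* rule — summing, over the
margin-fixed hypergeometric support, the probabilities of all tables no more
probable than the observed one, with a relative tolerance of 10⁻⁷ for
floating-point ties. This convention is stated explicitly because exact-test
dialects differ; it matches `stats::fisher.test`, which serves as an
independent cross-check in the test suite, while the reported odds ratio is
the sample odds ratio (with 0/∞ conventions for zero cells), not the
conditional MLE. Band-proximity clustering groups significantly
co-occurring genes that lie on the same chromosome arm with major cytoband
indices differing by at most 1; "proximal" has no standard numeric
definition, so this rule is a documented package choice.

## Prognostic modelling

Follow-up is truncated (default 10 years; 5 for aggressive subtypes is the
caller's choice) *before* any model sees the data; times strictly beyond
the cutoff are censored at it. The univariate screen median-dichotomises
each candidate gene on the **training part only** and keeps genes with
log-rank *P* < 0.1. Screening on dichotomised groups keeps the screen
consistent with the univariate survival analyses; the penalised fit then
uses continuous expression, because an L1 path over dichotomised inputs
would be degenerate. The multivariate model is an L1-penalised Cox fit
(`glmnet`), penalty chosen to minimise the mean ten-fold cross-validated
partial-likelihood deviance, with folds stratified by event status so no
fold is event-free. Clinical covariates (age dichotomised at 50; stage as
an ordinal numeric with stage 1 as baseline) are always included
unpenalised when requested. Degenerate situations are handled explicitly:
an empty screen yields a clinical-only (or empty) model, and a single
screen survivor is fitted unpenalised.

Validation uses Harrell's concordance index: over pairs comparable under
censoring (the earlier observed time is an event; tied times count only
when the later is censored), the fraction in which the higher predicted
risk fails earlier, ties in risk counting 0.5. The implementation is exact
pair counting, verified against brute-force enumeration and against
`survival::concordance`. `repeated_split_evaluation()` re-draws the
train/validation split on every repeat (the alternative — fixed folds — is
not reproducible from published descriptions of such procedures, and
re-drawing gives the honest between-split variability), trains from
scratch, and records held-out concordance plus per-gene inclusion
frequencies; genes above a 0.2 inclusion frequency are reported as the
stable signature, and `refit_full_cohort()` turns them into a final
unpenalised model.

## The synthetic-cohort generator

`simulate_pan_cancer()` generates the study conditions every test and the
acceptance script run under. Per cohort:

1. latent hypoxia `h ~ Uniform(0, 1)` per tumour sample;
2. segmental copy number: each chromosome is cut into 3–8 contiguous
   segments per sample with baseline log2 ratios `Normal(0, 0.05)`;
   planted drivers receive a focal gain `Uniform(0.3, 1.2)` in a Bernoulli
   subset of samples with probability `driver_gain_fraction` (default
   0.5); for hypoxia-coupled drivers the per-sample probability is
   `driver_gain_fraction + hypoxia_gain_slope · (h − 1/2)`, clipped to
   [0, 1] — centred on the latent mean so the expected gained fraction
   stays at `driver_gain_fraction` while still increasing with hypoxia;
3. tumour expression = per-gene baseline (`Uniform(4, 10)` log2 units) +
   `overexpression_shift` (planted drivers, default 1.0) + `c ·`
   (within-gene standardised copy-number ratio) + `hypoxia_effect · h`
   (signature genes and hypoxia-coupled drivers, default 1.0) +
   `Normal(0, noise_sd)` with `noise_sd = 1`; normals are baseline plus
   noise;
4. sparse mutations `Bernoulli(0.01)` per gene and sample;
5. survival: event times are exponential with rate
   `baseline_hazard · exp(Σ β · centred expression)` over the planted
   prognostic genes (|β| = 0.8 with alternating signs, expression centred
   within gene so the baseline hazard of 0.1/year keeps its
   interpretation), censoring exponential at 0.05/year, age
   `Normal(58, 10)`, stage categorical (0.3, 0.4, 0.2, 0.1).

The dosage coefficient *c* is solved from the target Spearman correlation
`driver_coupling` (default 0.6) by inverting the Gaussian rank-correlation
relation ρ = (6/π)·asin(r/2) with r = c/√(c² + σ²) at the generator's noise
level σ. The inversion assumes approximately Gaussian margins; the planted
gains make the copy-number margin bimodal, so the empirical ρ deviates
slightly from the target (the test suite verifies it lands within 0.1 of
0.6 and is monotone in the requested coupling). The defaults — 3 cohorts of
200 tumours and 50 normals, 2000 genes on 10 chromosomes, 20 planted
drivers of which 10 hypoxia-coupled, a 50-gene signature, 3 prognostic
genes — are the conditions under which the pipeline is validated: the full
cascade recovers ≥ 90 % of planted drivers with ≤ 1 % false positives, and
with all effects zeroed returns an empty core signature.

The gene universe, annotation (uniformly spaced 50-kb genes on a 100-kb
grid, cytobands in blocks of 50 genes split into p and q arms) and all
planted gene sets derive from `seed` alone, so cohorts of one run share
them; per-cohort randomness derives from `seed + cancer_index`. Identical
parameters therefore give bit-identical output.

What the generator does **not** emulate: real marginal distributions of
RNA-seq abundance, batch and purity effects, subclonal or allele-specific
copy number, correlated mutational processes, non-exponential hazards, and
linkage between neighbouring genes beyond shared segments. Passing tests
demonstrate that the machinery is correct and calibrated under a known
generative model — not that the biological findings of any particular study
would replicate on real cohorts.

## Numerical conventions and tie-breaks

* BH is implemented via `stats::p.adjust` and verified against the
  step-up definition to 10⁻¹².
* Spearman correlations use mid-ranks (tie-corrected) with the
  *t*-approximation for *p*; a constant margin yields a missing ρ rather
  than an error; missing copy-number values are deleted pairwise; at least
  3 complete pairs are required.
* Probe-to-gene collapse keeps the probe with the largest standard
  deviation, ties broken by the lexicographically smallest probe id.
* The top-decile over-expression rule keeps `ceil(0.10 · |metabolic|)`
  genes after the FC/q filter, ranked by descending FC with ties broken by
  smaller *q* then gene id. The decile denominator (whole metabolic
  universe versus significant genes only) is ambiguous in common usage, so
  both are supported; the default is the whole universe.
* Median splits send ties to the low group; quartile groups assign ties
  spanning a boundary to the lower group and error when the three
  quartiles are not distinct.
* Follow-up truncation uses a strict inequality: a record observed exactly
  at the cutoff is not modified.
* SEG coordinates are 1-based inclusive on both ends; gene-level values
  are segment-length-weighted means; overlapping segments within one
  sample and chromosome are an error, not silently averaged.
* Matrices are written with 6 significant digits; write–read–write is
  byte-stable.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at deliberately
moderate scale: driver recovery over 5–10 independent simulation seeds of
the default 3 × 2000-gene design; null calibration over 10–20 seeds;
hypoxia power over 20 seeds at n = 300; survival over 100 repeated splits
of an n = 600 cohort with 50 candidate genes; the mRNA–mRNA null at reduced
set sizes on small matrices (the construction is size-agnostic). These
sizes give stable pass/fail behaviour at a few minutes of total runtime and
are the package's chosen validation design.

## Known limitations

* No curated hypoxia-signature gene list ships with the package; users
  supply their own.
* No ploidy/purity correction or GISTIC-style peak detection; the SCNA
  caller consumes whatever log2 ratios it is given.
* Count-model differential expression (dispersion estimation) is out of
  scope; the tests are *t*-tests on normalised log2 abundance.
* Pathway enrichment against curated databases is not included; the
  generic hypergeometric over-representation test can be pointed at any
  user-supplied gene sets.
* The proportional-hazards machinery performs no formal proportionality
  diagnostics; the repeated-split design measures discrimination, not
  calibration.
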