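## Seeded multi-cancer cohort simulator with planted ground truth.
##
## The generative model, per cohort:
##   1. a latent hypoxia level h_s ~ Uniform(0, 1) per tumour sample;
##   2. segmental copy number: each chromosome is cut into 3-8 contiguous
##      segments per sample with baseline log2 ratios ~ Normal(0, 0.05);
##      planted drivers additionally receive a focal gain (log2 ratio
##      ~ Uniform(0.3, 1.2)) in a Bernoulli-selected subset of samples of
##      expected size driver_gain_fraction; for hypoxia-coupled drivers the
##      per-sample gain probability is driver_gain_fraction +
##      hypoxia_gain_slope * (h_s - 1/2), clipped to [0, 1], so the expected
##      gained fraction stays at driver_gain_fraction while the gain
##      probability increases with hypoxia;
##   3. tumour expression = per-gene baseline + overexpression_shift
##      (planted drivers) + c * (within-gene standardised copy-number log2
##      ratio) + hypoxia_effect * h_s (signature genes and hypoxia-coupled
##      drivers) + Normal(0, noise_sd); the dosage coefficient c is solved
##      from the target Spearman correlation `driver_coupling` at the
##      generator's noise level; normal-tissue expression = baseline +
##      Normal(0, noise_sd);
##   4. sparse somatic mutations ~ Bernoulli(mutation_rate) per gene/sample;
##   5. survival: event time ~ Exponential with rate baseline_hazard *
##      exp(sum of prognostic betas times centred log2 expression),
##      independent censoring ~ Exponential(censor_rate); age ~ Normal(58,
##      10); stage ~ Categorical(0.3, 0.4, 0.2, 0.1).
##
## The gene universe, annotation and all planted gene sets derive from
## params$seed alone, so every cohort of a pan-cancer run shares them;
## per-cohort randomness derives from params$seed + cancer_index.

#' Simulation parameters
#'
#' Builds a validated parameter list for [simulate_cohort()] /
#' [simulate_pan_cancer()]. The defaults describe a moderately sized
#' multi-cancer design: 3 cohorts of 200 tumours + 50 normals over 2000
#' genes on 10 chromosomes, 20 planted drivers gained in half the samples
#' with a target DNA-mRNA Spearman correlation of 0.6 and a 1 log2-unit
#' over-expression shift, a 50-gene hypoxia signature with a 1 log2-unit
#' hypoxia effect, 10 hypoxia-coupled drivers, and a 3-gene prognostic
#' signal of 0.8 log-hazard per log2 unit.
#'
#' @param n_cancers Number of cohorts.
#' @param n_tumour,n_normal Samples per cohort.
#' @param n_genes,n_chromosomes Gene universe size and chromosome count.
#' @param n_planted_drivers Planted dosage-driven over-expressed genes.
#' @param driver_coupling Target DNA-mRNA Spearman rho in \[0, 1\].
#' @param driver_gain_fraction Expected gained fraction of planted drivers.
#' @param overexpression_shift Tumour-vs-normal shift (log2 units) of
#'   planted drivers.
#' @param n_signature_genes Hypoxia-signature genes.
#' @param hypoxia_effect Expression increase (log2 units) per unit latent
#'   hypoxia for signature genes and hypoxia-coupled drivers.
#' @param n_hypoxia_coupled_drivers Drivers whose gain probability rises
#'   with hypoxia (subset of the planted drivers).
#' @param hypoxia_gain_slope Increase in gain probability per unit latent
#'   hypoxia for the coupled drivers.
#' @param n_prognostic_genes,prognostic_beta Planted prognostic genes and
#'   their absolute log-hazard per log2 unit (signs alternate).
#' @param baseline_hazard,censor_rate Exponential event and censoring rates
#'   per year.
#' @param mutation_rate Per-gene per-sample somatic mutation probability.
#' @param noise_sd Expression noise standard deviation (log2 units).
#' @param metabolic_fraction Fraction of the gene universe flagged
#'   metabolic (planted drivers are always metabolic).
#' @param seed Integer seed; the whole simulation is a pure function of the
#'   parameter list.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_cancers = 3L, n_tumour = 200L,
                              n_normal = 50L, n_genes = 2000L,
                              n_chromosomes = 10L,
                              n_planted_drivers = 20L,
                              driver_coupling = 0.6,
                              driver_gain_fraction = 0.5,
                              overexpression_shift = 1.0,
                              n_signature_genes = 50L,
                              hypoxia_effect = 1.0,
                              n_hypoxia_coupled_drivers = 10L,
                              hypoxia_gain_slope = 0.5,
                              n_prognostic_genes = 3L,
                              prognostic_beta = 0.8,
                              baseline_hazard = 0.1,
                              censor_rate = 0.05,
                              mutation_rate = 0.01,
                              noise_sd = 1.0,
                              metabolic_fraction = 0.25,
                              seed = 1L) {
  p <- as.list(environment())
  if (p$n_planted_drivers + p$n_signature_genes > p$n_genes) {
    stop("n_planted_drivers + n_signature_genes must not exceed n_genes")
  }
  if (p$n_hypoxia_coupled_drivers > p$n_planted_drivers) {
    stop("hypoxia-coupled drivers must be a subset of planted drivers")
  }
  if (p$driver_coupling < 0 || p$driver_coupling > 1) {
    stop("driver_coupling must lie in [0, 1]")
  }
  if (p$driver_gain_fraction <= 0 || p$driver_gain_fraction > 1) {
    stop("driver_gain_fraction must lie in (0, 1]")
  }
  rates <- c(p$baseline_hazard, p$censor_rate, p$mutation_rate, p$noise_sd,
             p$hypoxia_gain_slope)
  if (any(rates < 0)) stop("rates and noise_sd must be >= 0")
  if (round(p$metabolic_fraction * p$n_genes) < p$n_planted_drivers) {
    stop("metabolic set too small to hold the planted drivers")
  }
  class(p) <- "simulation_params"
  p
}

## Dosage coefficient c for the target Spearman correlation rho between
## e = c*z + eps (eps ~ N(0, sd)) and z: invert the Gaussian rank-correlation
## relation rho_S = (6/pi) asin(r/2) and r = c/sqrt(c^2 + sd^2).
coupling_coefficient <- function(rho, noise_sd) {
  if (rho <= 0) return(0)
  if (rho >= 1) stop("driver_coupling must be < 1 for a finite coefficient")
  r <- 2 * sin(pi * rho / 6)
  noise_sd * r / sqrt(1 - r^2)
}

## Shared gene universe: annotation, metabolic flags and planted gene sets,
## a pure function of params$seed.
make_gene_universe <- function(params) {
  set.seed(params$seed)
  n <- params$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  per_chr <- ceiling(n / params$n_chromosomes)
  idx0 <- seq_len(n) - 1L
  chr_i <- idx0 %/% per_chr + 1L
  within <- idx0 %% per_chr
  ## genes uniformly spaced: 50 kb bodies on a 100 kb grid
  start <- within * 100000L + 1L
  end <- start + 50000L - 1L
  ## cytobands in blocks of 50 genes; first half of each chromosome is the
  ## p arm, second half the q arm
  band <- within %/% 50L
  bands_per_chr <- ceiling(per_chr / 50L)
  p_bands <- ceiling(bands_per_chr / 2)
  arm <- ifelse(band < p_bands, "p", "q")
  band_in_arm <- ifelse(band < p_bands, band + 1L, band - p_bands + 1L)
  cytoband <- sprintf("%s%02d", arm, band_in_arm)
  n_metab <- round(params$metabolic_fraction * n)
  metabolic <- sort(sample.int(n, n_metab))
  drivers <- sort(sample(metabolic, params$n_planted_drivers))
  coupled <- sort(sample(drivers, params$n_hypoxia_coupled_drivers))
  non_driver <- setdiff(seq_len(n), drivers)
  signature <- sort(sample(non_driver, params$n_signature_genes))
  free <- setdiff(non_driver, signature)
  prognostic <- sort(sample(free, params$n_prognostic_genes))
  betas <- params$prognostic_beta *
    rep_len(c(1, -1), params$n_prognostic_genes)
  list(
    annotation = data.frame(
      gene_id = genes,
      chromosome = paste0("chr", chr_i),
      start = start, end = end, cytoband = cytoband,
      is_metabolic = seq_len(n) %in% metabolic,
      stringsAsFactors = FALSE),
    baseline = runif(n, 4, 10),
    drivers = genes[drivers],
    coupled = genes[coupled],
    signature = genes[signature],
    prognostic = setNames(betas, genes[prognostic])
  )
}

#' Simulate one cohort with known ground truth
#'
#' @param params A `simulation_params` list.
#' @param cancer_index Integer cohort index (used to derive the per-cohort
#'   seed; cohorts of one pan-cancer run share their gene universe and
#'   planted sets but have independent samples).
#' @return List with elements `bundle` (a harmonised [cohort_bundle()] with
#'   SCNA calls) and `truth` (planted_drivers, hypoxia_coupled, prognostic
#'   betas, signature_genes, latent_hypoxia).
#' @export
simulate_cohort <- function(params, cancer_index = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  uni <- make_gene_universe(params)
  set.seed(params$seed + cancer_index)
  n_g <- params$n_genes
  n_t <- params$n_tumour
  n_n <- params$n_normal
  genes <- uni$annotation$gene_id
  t_ids <- sprintf("C%02d_T%04d", cancer_index, seq_len(n_t))
  n_ids <- sprintf("C%02d_N%04d", cancer_index, seq_len(n_n))

  h <- runif(n_t)

  ## segmental copy-number baseline
  cn <- matrix(0, n_g, n_t, dimnames = list(genes, t_ids))
  chr_of <- uni$annotation$chromosome
  for (chrom in unique(chr_of)) {
    rows <- which(chr_of == chrom)
    m <- length(rows)
    for (s in seq_len(n_t)) {
      k <- min(sample(3:8, 1L), m)
      cuts <- sort(sample.int(m - 1L, k - 1L))
      seg_id <- findInterval(seq_len(m), c(0L, cuts) + 1L)
      cn[rows, s] <- rnorm(k, 0, 0.05)[seg_id]
    }
  }

  ## focal gains for planted drivers
  is_coupled <- uni$drivers %in% uni$coupled
  for (i in seq_along(uni$drivers)) {
    g <- uni$drivers[i]
    p_gain <- if (is_coupled[i]) {
      pmin(pmax(params$driver_gain_fraction +
                  params$hypoxia_gain_slope * (h - 0.5), 0), 1)
    } else {
      rep(params$driver_gain_fraction, n_t)
    }
    gained <- runif(n_t) < p_gain
    cn[g, gained] <- cn[g, gained] + runif(sum(gained), 0.3, 1.2)
  }

  ## expression
  cc <- coupling_coefficient(params$driver_coupling, params$noise_sd)
  tumour <- matrix(uni$baseline, n_g, n_t, dimnames = list(genes, t_ids))
  tumour[uni$drivers, ] <- tumour[uni$drivers, ] + params$overexpression_shift
  if (cc > 0) {
    cn_sd <- apply(cn, 1L, sd)
    nz <- cn_sd > 0
    z <- (cn[nz, , drop = FALSE] - rowMeans(cn[nz, , drop = FALSE])) / cn_sd[nz]
    tumour[nz, ] <- tumour[nz, ] + cc * z
  }
  hyp_genes <- union(uni$signature, uni$coupled)
  tumour[hyp_genes, ] <- tumour[hyp_genes, ] +
    params$hypoxia_effect * matrix(h, length(hyp_genes), n_t, byrow = TRUE)
  tumour <- tumour + matrix(rnorm(n_g * n_t, 0, params$noise_sd), n_g, n_t)
  normal <- matrix(uni$baseline, n_g, n_n, dimnames = list(genes, n_ids)) +
    matrix(rnorm(n_g * n_n, 0, params$noise_sd), n_g, n_n)

  ## sparse somatic mutations
  n_mut <- rbinom(1L, n_g * n_t, params$mutation_rate)
  mut_idx <- sample.int(n_g * n_t, n_mut)
  mutations <- data.frame(
    gene_id = genes[(mut_idx - 1L) %% n_g + 1L],
    sample_id = t_ids[(mut_idx - 1L) %/% n_g + 1L],
    variant_class = sample(c("missense", "nonsense", "frameshift", "splice"),
                           n_mut, replace = TRUE),
    stringsAsFactors = FALSE)

  ## survival with planted prognostic genes on centred expression
  prog <- names(uni$prognostic)
  lp <- if (length(prog) > 0L) {
    expr_c <- tumour[prog, , drop = FALSE] -
      rowMeans(tumour[prog, , drop = FALSE])
    drop(crossprod(expr_c, uni$prognostic))
  } else rep(0, n_t)
  event_time <- rexp(n_t, params$baseline_hazard * exp(lp))
  censor_time <- if (params$censor_rate > 0) {
    rexp(n_t, params$censor_rate)
  } else rep(Inf, n_t)
  clinical <- data.frame(
    sample_id = t_ids,
    time = pmin(event_time, censor_time),
    event = event_time <= censor_time,
    age = rnorm(n_t, 58, 10),
    stage = sample(1:4, n_t, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1)),
    subtype = NA_character_,
    stringsAsFactors = FALSE)

  bundle <- cohort_bundle(
    name = sprintf("cancer%02d", cancer_index),
    tumour_expr = tumour, normal_expr = normal, cn_log2 = cn,
    mutations = mutations, clinical = clinical,
    annotation = uni$annotation, hypoxia_signature = uni$signature)
  bundle <- add_scna_calls(bundle)
  truth <- list(
    planted_drivers = uni$drivers,
    hypoxia_coupled = uni$coupled,
    prognostic = uni$prognostic,
    signature_genes = uni$signature,
    latent_hypoxia = setNames(h, t_ids))
  list(bundle = bundle, truth = truth)
}

#' Simulate a pan-cancer collection of cohorts
#'
#' Calls [simulate_cohort()] with per-cancer seeds `seed + cancer_index`;
#' all cohorts share the gene universe, annotation and planted gene sets and
#' have disjoint sample ids.
#'
#' @param params A `simulation_params` list.
#' @return List of length `n_cancers` of `list(bundle, truth)`.
#' @export
simulate_pan_cancer <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  lapply(seq_len(params$n_cancers), function(i) simulate_cohort(params, i))
}
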