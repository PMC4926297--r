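## Univariate and repeated-split multivariate prognostic modelling with
## concordance-index validation.
##
## The modelling convention: follow-up is truncated before any model is
## fitted; the univariate screen works on median-dichotomised expression
## (high = above the cohort median); the penalised multivariate fit works on
## continuous expression, with clinical covariates (age dichotomised at 50,
## ordinal stage with 1 as baseline) left unpenalised when requested.

#' Truncate follow-up at a cutoff
#'
#' Times strictly greater than `cutoff_years` are set to the cutoff and the
#' event flag is censored; a record observed exactly at the cutoff is left
#' unchanged.
#'
#' @param records data.frame with columns `time` and `event`.
#' @param cutoff_years Positive truncation horizon.
#' @return The records with truncated time/event.
#' @export
truncate_followup <- function(records, cutoff_years) {
  if (cutoff_years < 0) stop("negative truncation cutoff")
  over <- records$time > cutoff_years
  records$event[over] <- FALSE
  records$time[over] <- cutoff_years
  records
}

#' Median dichotomisation into high/low groups
#'
#' Values strictly above the median are "high"; values at or below it are
#' "low" (ties at the median go low).
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Factor with levels `low`, `high`, same length as `values`.
#' @export
median_dichotomise <- function(values) {
  m <- median(values)
  if (all(values == values[1L])) stop("constant vector cannot be dichotomised")
  labels <- ifelse(values > m, "high", "low")
  if (length(unique(labels)) < 2L) stop("median split produced a single group")
  factor(labels, levels = c("low", "high"))
}

#' Quartile grouping
#'
#' Splits values into four groups at the 25th, 50th and 75th percentiles;
#' ties spanning a boundary are assigned to the lower group (boundaries are
#' inclusive on the left: `Q1 <= p25 < Q2 <= p50 < Q3 <= p75 < Q4`).
#'
#' @param values Numeric vector.
#' @return Factor with levels `Q1`..`Q4`; errors if any group is empty.
#' @export
quartile_groups <- function(values) {
  qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7)
  if (anyDuplicated(qs)) {
    stop("too few distinct values for four non-empty quartile groups")
  }
  g <- cut(values, breaks = c(-Inf, qs, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  if (any(table(g) == 0L)) {
    stop("too few distinct values for four non-empty quartile groups")
  }
  g
}

#' Univariate Cox model on a two-group split
#'
#' Hazard ratio (high vs low), Wald 95% confidence interval and Wald
#' p-value from a proportional-hazards fit. Monotone-likelihood
#' (separation) fits are flagged rather than failing.
#'
#' @param groups Factor with levels `low`, `high`.
#' @param records data.frame with `time` and `event` aligned with `groups`.
#' @return List with `hr`, `ci95` (length-2), `wald_p`, `flagged`.
#' @export
univariate_cox <- function(groups, records) {
  if (nlevels(droplevels(groups)) != 2L) stop("need two non-empty groups")
  if (sum(records$event) == 0L) stop("no events in the data")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(records$time, records$event) ~ groups),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(coef(fit)[1L])
  se <- sqrt(fit$var[1L, 1L])
  flagged <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se)
  list(hr = exp(beta),
       ci95 = exp(beta + c(-1, 1) * 1.959963984540054 * se),
       wald_p = 2 * pnorm(-abs(beta / se)),
       flagged = flagged)
}

#' Two-group log-rank test
#'
#' @param groups Factor with two non-empty levels.
#' @param records data.frame with `time` and `event`.
#' @return Chi-square p-value.
#' @export
logrank <- function(groups, records) {
  if (nlevels(droplevels(groups)) != 2L) stop("need two non-empty groups")
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ groups)
  unname(1 - pchisq(sd$chisq, df = 1L))
}

## Build the design matrix for the penalised fit: continuous expression of
## the given genes plus (optionally) age_ge_50 and ordinal stage.
survival_design <- function(expr, clinical, genes, clinical_covariates) {
  x <- t(expr[genes, clinical$sample_id, drop = FALSE])
  if (clinical_covariates) {
    x <- cbind(x, age_ge_50 = as.numeric(clinical$age >= 50),
               stage = as.numeric(clinical$stage))
  }
  x
}

#' Train a penalised multivariate prognostic model
#'
#' Two stages on the training cohort only: (1) univariate screen — each
#' candidate gene is median-dichotomised and kept when its log-rank p-value
#' is below `preselect_alpha`; (2) an L1-penalised proportional-hazards fit
#' on the continuous expression of the survivors (plus unpenalised clinical
#' covariates when `clinical` is set), with the penalty chosen to minimise
#' the mean `n_folds`-fold cross-validated partial-likelihood deviance.
#' Folds are stratified by event status so no fold is event-free. An empty
#' screen yields a clinical-covariate-only (or empty) model rather than an
#' error.
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param clinical data.frame with sample_id, time, event, age, stage
#'   (training samples only).
#' @param gene_pool Candidate gene ids.
#' @param preselect_alpha Screen threshold (default 0.1).
#' @param n_folds Cross-validation folds (default 10).
#' @param clinical_covariates Include age_ge_50 and stage, unpenalised.
#' @param seed Integer seed (fold assignment).
#' @return List of class `prognostic_model`: `selected_features` (named
#'   coefficients of genes with non-zero coefficient), `clinical_features`,
#'   `screened_genes`, `chosen_penalty`, `cv_error_curve`, `training_ids`.
#' @export
train_multivariate <- function(expr, clinical, gene_pool,
                               preselect_alpha = 0.1, n_folds = 10L,
                               clinical_covariates = FALSE, seed = 1L) {
  gene_pool <- intersect(gene_pool, rownames(expr))
  clinical <- clinical[clinical$sample_id %in% colnames(expr), , drop = FALSE]
  if (sum(clinical$event) < n_folds) stop("need at least n_folds events")
  records <- clinical[, c("time", "event")]
  keep <- vapply(gene_pool, function(g) {
    vals <- expr[g, clinical$sample_id]
    if (all(vals == vals[1L])) return(FALSE)
    grp <- tryCatch(median_dichotomise(vals), error = function(e) NULL)
    if (is.null(grp)) return(FALSE)
    logrank(grp, records) < preselect_alpha
  }, logical(1L))
  screened <- gene_pool[keep]

  model <- list(selected_features = setNames(numeric(0L), character(0L)),
                clinical_features = setNames(numeric(0L), character(0L)),
                screened_genes = screened, chosen_penalty = NA_real_,
                cv_error_curve = NULL,
                training_ids = clinical$sample_id,
                clinical_covariates = clinical_covariates)
  class(model) <- "prognostic_model"

  n_feat <- length(screened) + if (clinical_covariates) 2L else 0L
  if (n_feat == 0L) return(model)

  y <- survival::Surv(clinical$time, clinical$event)
  x <- survival_design(expr, clinical, screened, clinical_covariates)

  if (ncol(x) < 2L || length(screened) == 0L) {
    ## glmnet needs >= 2 columns; a single survivor is fitted unpenalised
    fit <- survival::coxph(y ~ x)
    cf <- setNames(unname(coef(fit)), colnames(x))
    model$selected_features <- cf[names(cf) %in% screened]
    model$clinical_features <- cf[!(names(cf) %in% screened)]
    return(model)
  }

  set.seed(seed)
  foldid <- integer(nrow(x))
  for (ev in c(TRUE, FALSE)) {
    idx <- which(clinical$event == ev)
    if (length(idx) > 0L) {
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  }
  pf <- c(rep(1, length(screened)),
          if (clinical_covariates) rep(0, 2L))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", nfolds = n_folds,
                          foldid = foldid, penalty.factor = pf,
                          standardize = TRUE)
  cf <- as.matrix(coef(cv, s = "lambda.min"))[, 1L]
  nz <- cf[cf != 0]
  model$selected_features <- nz[names(nz) %in% screened]
  model$clinical_features <- cf[!(names(cf) %in% screened)]
  model$chosen_penalty <- cv$lambda.min
  model$cv_error_curve <- data.frame(lambda = cv$lambda, cvm = cv$cvm)
  model
}

#' Predicted risk score of a prognostic model
#'
#' Linear predictor (log relative hazard) of the model on new samples.
#'
#' @param model A `prognostic_model`.
#' @param expr Gene x sample expression matrix.
#' @param clinical Clinical data.frame for the samples to score.
#' @return Named numeric risk vector (higher = higher predicted hazard).
#' @export
predict_risk <- function(model, expr, clinical) {
  risk <- rep(0, nrow(clinical))
  names(risk) <- clinical$sample_id
  feats <- model$selected_features
  if (length(feats) > 0L) {
    risk <- risk + drop(crossprod(
      expr[names(feats), clinical$sample_id, drop = FALSE], feats))
  }
  clin <- model$clinical_features
  if (length(clin) > 0L) {
    cm <- cbind(age_ge_50 = as.numeric(clinical$age >= 50),
                stage = as.numeric(clinical$stage))
    risk <- risk + drop(cm[, names(clin), drop = FALSE] %*% clin)
  }
  risk
}

#' Harrell's concordance index
#'
#' Fraction of usable (comparable under censoring) pairs in which the
#' sample with the higher predicted risk fails earlier; ties in risk count
#' 0.5. A pair is usable when the shorter observed time belongs to an event
#' (and the times differ, or they are tied with at least one event).
#'
#' @param risk Numeric predicted risk (higher = worse).
#' @param time Observed times.
#' @param event Logical event indicators.
#' @return Concordance index in \[0, 1\].
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    if (!event[i]) next
    ## pairs (i, j) where i is an event and observed earlier than j
    later <- time > time[i] | (time == time[i] & !event)
    den <- den + sum(later)
    num <- num + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (den == 0) stop("no usable pairs for concordance")
  num / den
}

#' Concordance of a model on validation records
#'
#' @param model A `prognostic_model`.
#' @param expr Gene x sample expression matrix (validation samples).
#' @param clinical Validation clinical data.frame.
#' @return Harrell's c-index of the model's risk score.
#' @export
concordance <- function(model, expr, clinical) {
  risk <- predict_risk(model, expr, clinical)
  concordance_index(risk, clinical$time, clinical$event)
}

#' Repeated-split prognostic evaluation
#'
#' Repeats `n_repeats` times: randomly split the cohort into training and
#' held-out parts (`split` = training fraction, e.g. 0.5 for half/half or
#' 2/3 for a 2:1 split), train a penalised model on the training part, and
#' evaluate the concordance index on the held-out part (and on an external
#' cohort when given). The per-gene inclusion frequency is the fraction of
#' repeats in which the gene entered the model with a non-zero coefficient.
#'
#' @param expr Gene x sample expression matrix.
#' @param clinical Clinical data.frame for all samples in `expr`.
#' @param gene_pool Candidate gene ids.
#' @param n_repeats Number of split/train/validate repeats (default 1000).
#' @param split Training fraction (default 0.5).
#' @param external Optional list(expr, clinical) of an external validation
#'   cohort.
#' @param preselect_alpha,n_folds,clinical_covariates Passed to
#'   [train_multivariate()].
#' @param inclusion_threshold Reporting threshold on the inclusion
#'   frequency (default 0.2).
#' @param seed Integer seed.
#' @return List with `c_index` (per-repeat held-out c), `c_index_external`
#'   (or NULL), `inclusion_frequency` (named, all genes ever screened),
#'   `frequent_genes` (those above the threshold), `n_repeats`.
#' @export
repeated_split_evaluation <- function(expr, clinical, gene_pool,
                                      n_repeats = 1000L, split = 0.5,
                                      external = NULL,
                                      preselect_alpha = 0.1, n_folds = 10L,
                                      clinical_covariates = FALSE,
                                      inclusion_threshold = 0.2,
                                      seed = 1L) {
  set.seed(seed)
  n <- nrow(clinical)
  n_train <- round(split * n)
  sel_counts <- setNames(numeric(length(gene_pool)), gene_pool)
  cs <- rep(NA_real_, n_repeats)
  cs_ext <- if (!is.null(external)) rep(NA_real_, n_repeats)
  for (r in seq_len(n_repeats)) {
    idx <- sample.int(n, n_train)
    train_cl <- clinical[idx, , drop = FALSE]
    valid_cl <- clinical[-idx, , drop = FALSE]
    fit_seed <- sample.int(.Machine$integer.max, 1L)
    model <- tryCatch(
      train_multivariate(expr, train_cl, gene_pool,
                         preselect_alpha = preselect_alpha,
                         n_folds = n_folds,
                         clinical_covariates = clinical_covariates,
                         seed = fit_seed),
      error = function(e) NULL)
    if (is.null(model)) next
    sel <- names(model$selected_features)
    sel_counts[sel] <- sel_counts[sel] + 1
    cs[r] <- tryCatch(concordance(model, expr, valid_cl),
                      error = function(e) NA_real_)
    if (!is.null(external)) {
      cs_ext[r] <- tryCatch(
        concordance(model, external$expr, external$clinical),
        error = function(e) NA_real_)
    }
  }
  freq <- sel_counts / n_repeats
  list(c_index = cs,
       c_index_external = cs_ext,
       inclusion_frequency = freq,
       frequent_genes = names(freq)[freq > inclusion_threshold],
       n_repeats = n_repeats)
}

#' Refit a model on the full cohort using the frequently selected genes
#'
#' Convenience for building a final classifier after
#' [repeated_split_evaluation()]: an unpenalised proportional-hazards fit of
#' the genes whose inclusion frequency exceeded the reporting threshold.
#'
#' @param expr Gene x sample expression matrix.
#' @param clinical Full-cohort clinical data.frame.
#' @param genes The frequently selected genes.
#' @param clinical_covariates Include age_ge_50 and stage.
#' @return A `prognostic_model` with unpenalised coefficients.
#' @export
refit_full_cohort <- function(expr, clinical, genes,
                              clinical_covariates = FALSE) {
  if (length(genes) == 0L) stop("no genes to refit")
  x <- survival_design(expr, clinical, genes, clinical_covariates)
  fit <- survival::coxph(
    survival::Surv(clinical$time, clinical$event) ~ x)
  cf <- setNames(unname(coef(fit)), colnames(x))
  model <- list(selected_features = cf[names(cf) %in% genes],
                clinical_features = cf[!(names(cf) %in% genes)],
                screened_genes = genes, chosen_penalty = 0,
                cv_error_curve = NULL, training_ids = clinical$sample_id,
                clinical_covariates = clinical_covariates)
  class(model) <- "prognostic_model"
  model
}
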