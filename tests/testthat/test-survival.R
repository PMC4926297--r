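surv_records <- function(time, event) {
  data.frame(time = time, event = event)
}

test_that("follow-up truncation censors beyond the cutoff but not at it", {
  rec <- surv_records(c(12, 4, 10), c(TRUE, TRUE, TRUE))
  out <- truncate_followup(rec, 10)
  expect_equal(out$time, c(10, 4, 10))
  expect_equal(out$event, c(FALSE, TRUE, TRUE))
  expect_error(truncate_followup(rec, -1), "negative")
})

test_that("median dichotomisation sends ties at the median to the low group", {
  g <- median_dichotomise(c(1, 2, 3, 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  g2 <- median_dichotomise(c(1, 2, 2, 3))
  expect_identical(as.character(g2), c("low", "low", "low", "high"))
  expect_identical(levels(median_dichotomise(c(5, 7))), c("low", "high"))
  expect_error(median_dichotomise(rep(3, 5)), "constant")
})

test_that("quartile groups split at the three quartiles with lower-group ties", {
  g <- quartile_groups(1:8)
  expect_identical(as.vector(table(g)), rep(2L, 4))
  g100 <- quartile_groups(rnorm(100))
  expect_true(all(abs(table(g100) - 25) <= 1))
  v <- c(1, 2, 2, 2, 3, 4, 5, 6, 7)  # p25 = 2: the tied 2s all go low
  gt <- quartile_groups(v)
  expect_true(all(gt[v == 2] == "Q1"))
  expect_identical(as.vector(table(gt)), c(4L, 1L, 2L, 2L))
  expect_error(quartile_groups(c(1, 1, 1, 2)), "distinct")
})

test_that("univariate Cox estimates the hazard ratio with Wald inference", {
  set.seed(16)
  n <- 1000
  grp <- factor(rep(c("low", "high"), each = n / 2),
                levels = c("low", "high"))
  time <- c(rexp(n / 2, 0.1), rexp(n / 2, 0.2))  # true HR 2 for high
  rec <- surv_records(time, rep(TRUE, n))
  fit <- univariate_cox(grp, rec)
  expect_gt(fit$hr, 1.8); expect_lt(fit$hr, 2.2)
  expect_lt(fit$wald_p, 1e-6)
  expect_true(fit$ci95[1] < fit$hr & fit$hr < fit$ci95[2])
  # label swap inverts the hazard ratio
  swapped <- univariate_cox(factor(ifelse(grp == "high", "low", "high"),
                                   levels = c("low", "high")), rec)
  expect_equal(swapped$hr, 1 / fit$hr, tolerance = 1e-6)
  # identical survival in both groups: HR near 1
  set.seed(17)
  rec0 <- surv_records(rexp(n, 0.1), rep(TRUE, n))
  fit0 <- univariate_cox(grp, rec0)
  expect_gt(fit0$hr, 0.85); expect_lt(fit0$hr, 1.18)
  expect_error(univariate_cox(grp, surv_records(time, rep(FALSE, n))),
               "no events")
})

test_that("log-rank test is calibrated and powered", {
  set.seed(18)
  grp <- factor(rep(c("low", "high"), each = 250), levels = c("low", "high"))
  strong <- surv_records(c(rexp(250, 0.1), rexp(250, 0.4)), rep(TRUE, 500))
  expect_lt(logrank(grp, strong), 0.001)
  ps <- replicate(60, {
    logrank(grp, surv_records(rexp(500, 0.1), rep(TRUE, 500)))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_error(logrank(factor(rep("a", 10)), surv_records(1:10, rep(TRUE, 10))),
               "two")
})

test_that("concordance matches brute-force pair enumeration and survival::concordance", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    risk <- sample(rnorm(n))          # continuous risks
    time <- round(rexp(n, 0.2), 1)    # rounded times induce ties
    event <- runif(n) < 0.7
    if (!any(event)) event[1] <- TRUE
    mine <- concordance_index(risk, time, event)
    expect_equal(mine, concordance_bruteforce(risk, time, event))
    ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                                 reverse = TRUE)$concordance
    expect_equal(mine, unname(ref))
  }
  # perfect and reversed rankings without censoring
  t_obs <- c(5, 3, 8, 1, 9)
  ev <- rep(TRUE, 5)
  expect_equal(concordance_index(-t_obs, t_obs, ev), 1)
  expect_equal(concordance_index(t_obs, t_obs, ev), 0)
  expect_error(concordance_index(1:3, 1:3, rep(FALSE, 3)), "usable")
})

sim_survival_cohort <- function(seed, n_tumour = 600, beta = 0.8) {
  p <- simulation_params(n_cancers = 1, n_tumour = n_tumour, n_normal = 10,
                         n_genes = 300, n_planted_drivers = 5,
                         n_signature_genes = 10,
                         n_hypoxia_coupled_drivers = 2,
                         n_prognostic_genes = 3, prognostic_beta = beta,
                         seed = seed)
  sim <- simulate_cohort(p, 1)
  prog <- names(sim$truth$prognostic)
  noise <- setdiff(rownames(sim$bundle$tumour_expr),
                   c(prog, sim$truth$planted_drivers,
                     sim$truth$signature_genes))[1:47]
  list(bundle = sim$bundle, prog = prog, pool = c(prog, noise),
       betas = sim$truth$prognostic)
}

test_that("penalised training is deterministic and recovers planted genes", {
  sc <- sim_survival_cohort(25)
  cl <- truncate_followup(sc$bundle$clinical, 10)
  m1 <- train_multivariate(sc$bundle$tumour_expr, cl, sc$pool, seed = 2)
  m2 <- train_multivariate(sc$bundle$tumour_expr, cl, sc$pool, seed = 2)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_true(all(sc$prog %in% names(m1$selected_features)))
  # planted signs survive the fit
  expect_equal(sign(unname(m1$selected_features[sc$prog])),
               sign(unname(sc$betas)))
})

test_that("an empty univariate screen yields a clinical-only model, not an error", {
  sc <- sim_survival_cohort(26, beta = 0)
  cl <- truncate_followup(sc$bundle$clinical, 10)
  # alpha so strict nothing survives the screen
  m <- train_multivariate(sc$bundle$tumour_expr, cl, sc$pool,
                          preselect_alpha = 1e-12,
                          clinical_covariates = TRUE, seed = 3)
  expect_length(m$selected_features, 0)
  expect_setequal(names(m$clinical_features), c("age_ge_50", "stage"))
})

test_that("repeated splits give high held-out concordance with planted signal and ~0.5 without", {
  sc <- sim_survival_cohort(27)
  cl <- truncate_followup(sc$bundle$clinical, 10)
  ev <- repeated_split_evaluation(sc$bundle$tumour_expr, cl, sc$pool,
                                  n_repeats = 25, split = 0.5, seed = 4)
  expect_gte(median(ev$c_index, na.rm = TRUE), 0.65)
  expect_true(all(ev$inclusion_frequency[sc$prog] > 0.2))
  expect_lt(median(ev$inclusion_frequency[setdiff(sc$pool, sc$prog)]), 0.1)

  null_sc <- sim_survival_cohort(28, beta = 0)
  null_cl <- truncate_followup(null_sc$bundle$clinical, 10)
  ev0 <- repeated_split_evaluation(null_sc$bundle$tumour_expr, null_cl,
                                   null_sc$pool, n_repeats = 25,
                                   split = 0.5, seed = 5)
  expect_gte(median(ev0$c_index, na.rm = TRUE), 0.42)
  expect_lte(median(ev0$c_index, na.rm = TRUE), 0.58)
})

test_that("risk prediction composes gene and clinical coefficients", {
  sc <- sim_survival_cohort(29)
  cl <- truncate_followup(sc$bundle$clinical, 10)
  m <- train_multivariate(sc$bundle$tumour_expr, cl, sc$pool,
                          clinical_covariates = TRUE, seed = 6)
  risk <- predict_risk(m, sc$bundle$tumour_expr, cl)
  manual <- drop(crossprod(
    sc$bundle$tumour_expr[names(m$selected_features), cl$sample_id,
                          drop = FALSE],
    m$selected_features)) +
    as.numeric(cl$age >= 50) * m$clinical_features["age_ge_50"] +
    as.numeric(cl$stage) * m$clinical_features["stage"]
  expect_equal(unname(risk), unname(manual))
  cidx <- concordance(m, sc$bundle$tumour_expr, cl)
  expect_gt(cidx, 0.6)
})
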