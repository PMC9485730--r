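# log partial likelihood for untied data, used as a brute-force oracle
log_pl <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

test_that("univariate Cox matches a grid-search oracle on untied data", {
  time <- c(2, 5, 7, 10)
  event <- c(1, 1, 1, 0)
  x <- c(1, 0, 1, 0)
  clin <- mini_clinical(time, event)
  fit <- cox_univariate(x, clin, label = "toy")

  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, log_pl, 0, time = time, event = event, x = x)
  beta_star <- grid[which.max(ll)]
  expect_lt(abs(fit$beta - beta_star), 1e-3)
})

test_that("Cox preconditions are enforced", {
  clin <- mini_clinical(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_error(cox_univariate(rep(1, 4), clin), class = "irlnc_validation_error")
  expect_error(cox_univariate(c(1, 0, 1, 0), mini_clinical(1:4, rep(0, 4))),
               class = "irlnc_validation_error")
})

test_that("hazard-ratio arithmetic follows the exp identities", {
  hr <- hazard_ratio_from_fit(0, 1)
  expect_equal(unname(hr["hr"]), 1)
  out <- hazard_ratio_from_fit(0.7, 0.2)
  expect_equal(unname(out["hr"]), exp(0.7))
  expect_equal(unname(out["hr_lo"]), exp(0.7 - 1.959964 * 0.2))
  expect_equal(unname(out["hr_hi"]), exp(0.7 + 1.959964 * 0.2))
  expect_error(hazard_ratio_from_fit(1, 0), class = "irlnc_validation_error")
})

test_that("every emitted Cox fit satisfies the CI identities", {
  set.seed(5)
  lp <- rep(c(0, 0.8), 50)
  clin <- sim_surv(lp, seed = 5, censor_rate = 0.02)
  fit <- cox_univariate(rep(c(0, 1), 50), clin)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-12)
  expect_equal(fit$hr_lo, exp(fit$beta - 1.959964 * fit$se), tolerance = 1e-12)
  expect_equal(fit$hr_hi, exp(fit$beta + 1.959964 * fit$se), tolerance = 1e-12)
  expect_true(fit$hr_lo <= fit$hr && fit$hr <= fit$hr_hi)
})

test_that("Cox estimates are invariant to time scaling and predictor shifts", {
  set.seed(8)
  x <- rbinom(120, 1, 0.5)
  clin <- sim_surv(0.6 * x, seed = 8, censor_rate = 0.02)
  f1 <- cox_univariate(x, clin)
  clin2 <- clin; clin2$os_time <- clin$os_time * 7.3
  f2 <- cox_univariate(x, clin2)
  f3 <- cox_univariate(x + 100, clin)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$beta, f3$beta, tolerance = 1e-6)
})

test_that("multivariate Cox with one predictor equals the univariate fit", {
  set.seed(3)
  x <- rbinom(80, 1, 0.5)
  clin <- sim_surv(0.5 * x, seed = 3, censor_rate = 0.03)
  uni <- cox_univariate(x, clin, label = "p1")
  multi <- cox_multivariate(matrix(x, dimnames = list(NULL, "p1")), clin)
  expect_equal(uni$beta, multi$beta, tolerance = 1e-10)
  expect_equal(uni$se, multi$se, tolerance = 1e-10)
})

test_that("collinear predictors raise a singular-information error naming them", {
  set.seed(4)
  x <- rbinom(60, 1, 0.5)
  clin <- sim_surv(0.5 * x, seed = 4, censor_rate = 0.02)
  design <- cbind(p1 = x, p2 = x)
  expect_error(cox_multivariate(design, clin), "collinear.*p2")
})

test_that("risk scores are the coefficient-weighted indicator sums", {
  model <- published_risk_model()
  genes <- unique(unlist(strsplit(model$pairs, "|", fixed = TRUE)))
  # expression where the first gene of each published pair is always higher:
  # all three indicators are 1 in every sample
  expr <- matrix(0, length(genes), 4,
                 dimnames = list(genes, paste0("S", 1:4)))
  expr["LINC01121", ] <- 9; expr["ADAMTS9-AS2", ] <- 9; expr["MIR124-2HG", ] <- 8
  expr["FAM167A-AS1", ] <- 1; expr["MGC12916", ] <- 1
  pm <- encode_pairs(expr, genes)
  scores <- risk_score(model, pm)
  expect_equal(unname(scores), rep(0.687 + 0.863 + 0.419, 4))
  expect_equal(unname(scores), rep(1.969, 4))

  # all indicators 0 -> score 0
  expr0 <- expr
  expr0["FAM167A-AS1", ] <- 99; expr0["MGC12916", ] <- 99
  expect_equal(unname(risk_score(model, encode_pairs(expr0, genes))), rep(0, 4))

  # additivity: sub-model scores sum to the full score
  m1 <- risk_model(model$pairs[1], model$coefs[1])
  m2 <- risk_model(model$pairs[2:3], model$coefs[2:3])
  expect_equal(risk_score(m1, pm) + risk_score(m2, pm), scores)

  expect_error(risk_score(risk_model("NOPE|NADA", 1), pm),
               class = "irlnc_key_error")
})

test_that("risk_score reconciles flipped pair orientation via complements", {
  expr <- rand_expr(2, 20, seed = 15, genes = c("AAA", "BBB"))
  pm <- encode_pairs(expr, c("AAA", "BBB"))
  fwd <- risk_score(risk_model("AAA|BBB", 1), pm)
  rev <- risk_score(risk_model("BBB|AAA", 1), pm)
  expect_equal(unname(fwd + rev), rep(1, 20))
})

test_that("median stratification splits strictly above the cutoff", {
  s <- c(A = 0, B = 0, C = 1, D = 1)
  out <- stratify(s)
  expect_equal(out$cutoff[1], 0.5)
  expect_identical(sum(out$group == "high"), 2L)

  # heavily tied discrete scores give unequal groups
  s2 <- c(0, 1, 1, 2, 2)
  out2 <- stratify(s2)  # median 1; only the two 2s exceed it
  expect_identical(sum(out2$group == "high"), 2L)
  expect_identical(sum(out2$group == "low"), 3L)

  # rank-preserving transforms leave median groups unchanged
  out3 <- stratify(exp(s2))
  expect_identical(out3$group, out2$group)

  expect_error(stratify(rep(1, 5)), class = "irlnc_validation_error")
  expect_error(stratify(numeric(0)), class = "irlnc_validation_error")
})

test_that("KM curves match hand product-limit arithmetic on 6 subjects", {
  # one group: times 1,2,2,4 events; censored at 3 and 5
  clin <- mini_clinical(c(1, 2, 2, 3, 4, 5), c(1, 1, 1, 0, 1, 0))
  assign <- data.frame(sample = clin$sample,
                       riskscore = c(1, 1, 1, 2, 2, 2),
                       group = rep(c("low", "high"), each = 3))
  km <- km_logrank(assign, clin)
  one <- survival::survfit(survival::Surv(clin$os_time, clin$os_event) ~ 1)
  # hand product-limit: S(1)=5/6; S(2)=5/6*(1-2/5)=1/2; S(4)=1/2*(1-1/2)=1/4
  expect_equal(summary(one, times = c(1, 2, 4))$surv,
               c(5 / 6, 1 / 2, 1 / 4), tolerance = 1e-12)
})

test_that("log-rank is near zero for identical groups and flags separation", {
  base <- mini_clinical(c(2, 4, 6, 8, 10, 12), c(1, 1, 0, 1, 1, 0),
                        samples = paste0("A", 1:6))
  dup <- base
  dup$sample <- paste0("B", 1:6)
  clin <- rbind(base, dup)
  assign <- data.frame(sample = clin$sample, riskscore = rep(c(0, 1), each = 6),
                       group = rep(c("low", "high"), each = 6))
  km <- km_logrank(assign, clin)
  expect_lt(km$chisq, 1e-10)
  expect_gt(km$p, 0.99)

  expect_error(
    km_logrank(data.frame(sample = clin$sample, group = "high"), clin),
    class = "irlnc_validation_error")
})

test_that("KM equals empirical survival when nothing is censored", {
  set.seed(20)
  clin <- sim_surv(rnorm(40, 0, 0.3), seed = 20)  # no censoring
  fit <- survival::survfit(survival::Surv(clin$os_time, clin$os_event) ~ 1)
  emp <- vapply(fit$time, function(t) mean(clin$os_time > t), 0)
  expect_equal(fit$surv, emp, tolerance = 1e-12)
})

test_that("time-dependent ROC equals Mann-Whitney AUC without censoring", {
  for (s in 1:5) {
    set.seed(s)
    scores <- rnorm(60)
    clin <- sim_surv(scores, seed = s)  # uncensored
    h <- median(clin$os_time)
    roc <- time_roc(scores, clin, h)
    labels <- as.integer(clin$os_time <= h)
    expect_equal(roc$auc, mw_auc(scores, labels), tolerance = 1e-9)
  }
})

test_that("time-ROC AUC is invariant under monotone score transforms", {
  set.seed(33)
  scores <- rnorm(80)
  clin <- sim_surv(scores, seed = 33, censor_rate = 0.03)
  h <- median(clin$os_time)
  a1 <- time_roc(scores, clin, h)$auc
  a2 <- time_roc(2 * scores + 5, clin, h)$auc
  a3 <- time_roc(exp(scores), clin, h)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("time-ROC discriminates planted effects and validates inputs", {
  set.seed(44)
  scores <- rnorm(400)
  clin_strong <- sim_surv(1.5 * scores, seed = 44, censor_rate = 0.02)
  clin_weak <- sim_surv(0.5 * scores, seed = 44, censor_rate = 0.02)
  h <- 10
  auc_strong <- time_roc(scores, clin_strong, h)$auc
  auc_weak <- time_roc(scores, clin_weak, h)$auc
  expect_gt(auc_weak, 0.5)
  expect_gt(auc_strong, auc_weak)

  expect_error(time_roc(scores, clin_strong, 1e6),
               class = "irlnc_validation_error")
  none <- mini_clinical(c(5, 6, 7), c(0, 0, 1))
  expect_error(time_roc(c(1, 2, 3), none, 4), class = "irlnc_validation_error")
})

test_that("LASSO path is monotone, seeded, and selects a strong planted pair", {
  cfg <- sim_config(n_samples_survival = 400L, n_immune_genes = 2L,
                    n_lncRNAs = 8L, n_linked_lnc = 0L, n_de_lnc = 0L,
                    pair_betas = c("LNC0001|LNC0002" = 1.0), seed = 17L)
  surv <- generate_survival_cohort(cfg)
  pm <- pair_ratio_filter(encode_pairs(surv$expr, paste0("LNC000", 1:8)), 0, 1)
  sel1 <- lasso_cox_select(pm, surv$clinical, seed = 2L)
  sel2 <- lasso_cox_select(pm, surv$clinical, seed = 2L)
  expect_identical(sel1$selected, sel2$selected)
  expect_identical(sel1$lambda_min, sel2$lambda_min)
  expect_true("LNC0001|LNC0002" %in% sel1$selected)
  # nonzero count nonincreasing in lambda
  ord <- order(sel1$path$lambda)
  expect_true(all(diff(sel1$path$nonzero[ord]) <= 0))
})

test_that("clinical Cox separates confounded univariate and adjusted fits", {
  set.seed(160)  # distinct from the survival-draw seed below
  n <- 500
  x1 <- rbinom(n, 1, 0.5)                    # true risk factor
  age <- 55 + 8 * x1 + rnorm(n, 0, 4)        # confounded with x1
  clin <- sim_surv(1.2 * x1, seed = 60, censor_rate = 0.02)
  clin$age <- age
  rs <- setNames(as.numeric(x1), clin$sample)
  out <- cox_clinical(clin, rs, age_cut = 55)
  uni_age <- out$univariate[grepl("^age", out$univariate$variable), ]
  multi_age <- out$multivariate[grepl("^age", out$multivariate$variable), ]
  expect_gt(uni_age$beta, multi_age$beta + 0.2)
  expect_gt(uni_age$beta, 0.5)   # picks up the confounded effect
  expect_lt(abs(multi_age$beta), 0.5)  # shrinks once adjusted

  clin$sex <- "Female"
  expect_error(cox_clinical(clin, rs), class = "irlnc_validation_error")
})

test_that("riskscore coefficient is recovered on proportional-hazards data", {
  set.seed(61)
  n <- 2000
  rs <- rnorm(n)
  clin <- sim_surv(0.8 * rs, seed = 61, censor_rate = 0.02)
  out <- cox_clinical(clin, setNames(rs, clin$sample))
  beta <- out$univariate$beta[out$univariate$variable == "riskscore"]
  expect_lt(abs(beta - 0.8), 0.1)
})
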