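## z for 95% CIs, fixed so printed hazard-ratio arithmetic reproduces to 3 dp
.z95 <- 1.959964

#' Hazard ratio and 95% confidence bounds from a Cox coefficient
#'
#' @param beta log hazard ratio.
#' @param se its standard error (> 0).
#' @return named numeric `c(hr, hr_lo, hr_hi)` with `hr = exp(beta)` and
#'   bounds `exp(beta -/+ 1.959964 * se)`.
#' @export
hazard_ratio_from_fit <- function(beta, se) {
  if (any(se <= 0)) stop_validation("se must be positive")
  c(hr = exp(beta), hr_lo = exp(beta - .z95 * se), hr_hi = exp(beta + .z95 * se))
}

cox_fit_table <- function(fit, labels = NULL) {
  sm <- summary(fit)
  beta <- sm$coefficients[, "coef"]
  se <- sm$coefficients[, "se(coef)"]
  data.frame(variable = labels %||% rownames(sm$coefficients),
             beta = unname(beta),
             se = unname(se),
             hr = unname(exp(beta)),
             hr_lo = unname(exp(beta - .z95 * se)),
             hr_hi = unname(exp(beta + .z95 * se)),
             p = unname(sm$coefficients[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

surv_object <- function(clin) {
  check_clinical_table(clin)
  if (sum(clin$os_event) < 1L) stop_validation("no events in survival data")
  survival::Surv(clin$os_time, clin$os_event)
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximum partial likelihood with Efron handling of tied event times (the
#' better approximation for the heavily tied 0/1 pair indicators), via
#' \pkg{survival}. Wald statistics and 95% bounds follow
#' [hazard_ratio_from_fit()].
#'
#' @param x numeric predictor (e.g. a pair indicator row), one value per
#'   sample; must not be constant.
#' @param clin clinical table with `os_time`/`os_event` aligned to `x`.
#' @param label variable name for the output row.
#' @param ties tie-handling method (`"efron"` default, `"breslow"` available).
#' @return one-row data.frame: `variable`, `beta`, `se`, `hr`, `hr_lo`,
#'   `hr_hi`, `p`.
#' @export
cox_univariate <- function(x, clin, label = "x", ties = "efron") {
  if (length(unique(x)) < 2L) {
    stop_validation("degenerate predictor: '", label, "' is constant")
  }
  y <- surv_object(clin)
  if (sum(clin$os_event) < 2L) stop_validation("need at least 2 events")
  fit <- survival::coxph(y ~ x, ties = ties)
  cox_fit_table(fit, labels = label)
}

pair_design <- function(pm) {
  x <- t(pm$indicators)
  colnames(x) <- pm$pairs$label
  x
}

#' Multivariate Cox fit on pair indicators
#'
#' Joint Cox fit of several pair indicators (or any numeric design matrix).
#' Collinear predictors are rejected with an error naming the offending
#' columns rather than silently dropped.
#'
#' @param pm a `pair_matrix`, or a numeric samples x variables matrix.
#' @param clin clinical table aligned to the samples.
#' @param ties tie-handling method (default Efron).
#' @return data.frame of per-variable Wald fits (schema of [cox_univariate()]).
#' @export
cox_multivariate <- function(pm, clin, ties = "efron") {
  x <- if (inherits(pm, "pair_matrix")) pair_design(pm) else as.matrix(pm)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1L) {
    dep_cols <- qrx$pivot[seq.int(qrx$rank + 1L, ncol(x) + 1L)] - 1L
    stop_validation("singular information: collinear predictor(s): ",
                    paste(colnames(x)[dep_cols], collapse = ", "))
  }
  y <- surv_object(clin)
  fit <- survival::coxph(y ~ x, ties = ties)
  cox_fit_table(fit, labels = colnames(x))
}

#' LASSO-penalized Cox selection of pairs
#'
#' L1-penalized Cox partial likelihood over glmnet's log-spaced lambda grid,
#' with the penalty chosen by `n_folds`-fold cross-validated partial-likelihood
#' deviance at `lambda.min`. Fold assignment is seeded, so selection is
#' reproducible. Used to narrow the univariate-significant pairs before the
#' final multivariate fit.
#'
#' @param pm a `pair_matrix` (>= 2 pairs).
#' @param clin clinical table aligned to the samples; needs at least `n_folds`
#'   events.
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `selected` (labels of nonzero-coefficient pairs at
#'   `lambda.min`; empty with a warning if the penalty kills everything),
#'   `coefs` (their coefficients), `lambda_min`, `path` (data.frame of lambda
#'   vs number of nonzero coefficients) and `cvfit` (the `cv.glmnet` object).
#' @export
lasso_cox_select <- function(pm, clin, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(pm, "pair_matrix"))
  x <- pair_design(pm)
  if (ncol(x) < 2L) stop_validation("LASSO selection needs at least 2 pairs")
  check_clinical_table(clin)
  if (sum(clin$os_event) < n_folds) {
    stop_validation("need at least n_folds events for cross-validation")
  }
  y <- survival::Surv(clin$os_time, clin$os_event)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, "folds"))
  foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
  cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[, 1L]
  selected <- names(cf)[cf != 0]
  if (!length(selected)) warning("LASSO selected no pairs at lambda.min")
  path <- data.frame(lambda = cvfit$glmnet.fit$lambda,
                     nonzero = cvfit$glmnet.fit$df)
  list(selected = selected, coefs = cf[cf != 0], lambda_min = cvfit$lambda.min,
       path = path, cvfit = cvfit)
}

#' Construct a risk model from pairs and coefficients
#'
#' @param pairs character vector of pair labels (display orientation allowed,
#'   e.g. `"LINC01121|FAM167A-AS1"`).
#' @param coefs numeric coefficients, one per pair.
#' @return object of class `risk_model`.
#' @export
risk_model <- function(pairs, coefs) {
  if (length(pairs) != length(coefs)) {
    stop_validation("pairs and coefs must have the same length")
  }
  structure(list(pairs = as.character(pairs), coefs = as.numeric(coefs)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model: riskscore =",
      paste(sprintf("%.3f x %s", x$coefs, x$pairs), collapse = " + "), "\n")
  invisible(x)
}

#' Per-sample risk score of a pair model
#'
#' `riskscore = sum_i coef_i * indicator_i`. Model pair labels are reconciled
#' with the pair matrix through canonical orientation: a model pair stored in
#' the opposite orientation uses the complementary indicator (1 - x).
#'
#' @param model a [risk_model()].
#' @param pm a `pair_matrix` containing every model pair.
#' @return named numeric vector of risk scores per sample.
#' @export
risk_score <- function(model, pm) {
  stopifnot(inherits(model, "risk_model"), inherits(pm, "pair_matrix"))
  score <- numeric(length(pm$samples))
  for (i in seq_along(model$pairs)) {
    g <- strsplit(model$pairs[i], "|", fixed = TRUE)[[1L]]
    canon <- canonical_pair(g[1L], g[2L])
    lab <- pair_label(canon$gene_a, canon$gene_b)
    row <- match(lab, pm$pairs$label)
    if (is.na(row)) stop_key("model pair not found in pair matrix: ", model$pairs[i])
    ind <- pm$indicators[row, ]
    if (canon$flipped) ind <- 1 - ind
    score <- score + model$coefs[i] * ind
  }
  stats::setNames(score, pm$samples)
}

#' Serialize a risk model (with its cutoff) to JSON
#'
#' @param model a [risk_model()].
#' @param path output path.
#' @param cutoff,cutoff_rule optional stratification cutoff and its rule.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path, cutoff = NULL, cutoff_rule = NULL) {
  stopifnot(inherits(model, "risk_model"))
  obj <- list(pairs = model$pairs, coefs = model$coefs)
  if (!is.null(cutoff)) obj$cutoff <- cutoff
  if (!is.null(cutoff_rule)) obj$cutoff_rule <- cutoff_rule
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stratify samples into high- and low-risk groups
#'
#' Cutoff by the median risk score (default) or by the Youden-optimal point of
#' the time-dependent ROC at a horizon. Assignment is strict: a sample is
#' high-risk only when its score exceeds the cutoff, so with heavily tied
#' discrete pair scores the two groups are generally unequal.
#'
#' @param scores named numeric risk scores.
#' @param rule `"median"` or `"roc_optimal"`.
#' @param clin,horizon survival data and horizon, required for
#'   `"roc_optimal"`.
#' @return data.frame with `sample`, `riskscore`, `group` (`high`/`low`),
#'   `cutoff`, `cutoff_rule`.
#' @export
stratify <- function(scores, rule = c("median", "roc_optimal"),
                     clin = NULL, horizon = NULL) {
  rule <- match.arg(rule)
  if (!length(scores)) stop_validation("scores must be nonempty")
  if (length(unique(scores)) < 2L) {
    stop_validation("degenerate stratification: all risk scores identical")
  }
  cutoff <- if (rule == "median") stats::median(scores) else {
    if (is.null(clin) || is.null(horizon)) {
      stop_validation("roc_optimal rule requires clin and horizon")
    }
    time_roc(scores, clin, horizon)$cutoff_star
  }
  data.frame(sample = names(scores) %||% seq_along(scores),
             riskscore = unname(scores),
             group = ifelse(scores > cutoff, "high", "low"),
             cutoff = cutoff,
             cutoff_rule = rule,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' Product-limit estimates per group and the two-group log-rank statistic
#' (1 df), via \pkg{survival}.
#'
#' @param assign data.frame from [stratify()] (columns `sample`, `group`).
#' @param clin clinical table covering the same samples.
#' @return list with `curves` (data.frame `group`, `time`, `surv`, `n_risk`,
#'   `n_event`), `chisq`, `p` and the `survfit` object.
#' @export
km_logrank <- function(assign, clin) {
  check_clinical_table(clin)
  m <- match(assign$sample, clin$sample)
  if (anyNA(m)) stop_key("samples in assignment missing from clinical table")
  grp <- factor(assign$group)
  if (nlevels(grp) < 2L) stop_validation("need at least two groups for log-rank")
  time <- clin$os_time[m]
  event <- clin$os_event[m]
  if (sum(event) < 1L) stop_validation("no events")
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  curves <- data.frame(
    group = rep(sub("^grp=", "", names(fit$strata)), fit$strata),
    time = fit$time, surv = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event)
  list(curves = curves, chisq = unname(sd$chisq), p = p, fit = fit)
}

#' Univariate and multivariate Cox analysis of clinical factors plus riskscore
#'
#' Expands categorical covariates to indicator contrasts against stated
#' reference levels (Female, No, T1, N0, Stage I, Poorly), dichotomizes age at
#' `age_cut` (cohort median by default), and fits each factor alone
#' (univariate) and all together with the risk score (multivariate), reusing
#' the Cox machinery above.
#'
#' @param clin clinical table.
#' @param riskscore named numeric risk scores covering `clin$sample`.
#' @param age_cut age dichotomization threshold; default the cohort median.
#' @return list with `univariate` and `multivariate` fit tables.
#' @export
cox_clinical <- function(clin, riskscore, age_cut = NULL) {
  check_clinical_table(clin)
  rs <- riskscore[match(clin$sample, names(riskscore))]
  if (anyNA(rs)) stop_key("risk scores missing for some clinical samples")
  refs <- c(sex = "Female", tobacco = "No", alcohol = "No", t_stage = "T1",
            n_stage = "N0", tnm_stage = "Stage I", grade = "Poorly")
  blocks <- list()  # one contrast matrix per covariate
  for (v in names(refs)) {
    if (!v %in% names(clin)) next
    f <- clin[[v]]
    lv <- if (v %in% names(.stage_vocab)) {
      intersect(.stage_vocab[[v]], unique(f))
    } else unique(f[!is.na(f)])
    if (length(lv) < 2L) {
      stop_validation("degenerate predictor: '", v, "' is constant")
    }
    if (!refs[[v]] %in% lv) {
      stop_validation("empty reference level '", refs[[v]], "' for ", v)
    }
    lv <- c(refs[[v]], setdiff(lv, refs[[v]]))
    contr <- vapply(lv[-1L], function(l) as.numeric(f == l),
                    numeric(nrow(clin)))
    colnames(contr) <- paste0(v, ":", lv[-1L], " vs ", refs[[v]])
    blocks[[v]] <- contr
  }
  if ("age" %in% names(clin)) {
    cut <- age_cut %||% stats::median(clin$age, na.rm = TRUE)
    blocks[["age"]] <- matrix(as.numeric(clin$age > cut),
                              dimnames = list(NULL, sprintf("age>%g", cut)))
  }
  blocks[["riskscore"]] <- matrix(unname(rs), dimnames = list(NULL, "riskscore"))

  uni <- do.call(rbind, lapply(blocks, function(b) {
    const <- apply(b, 2L, function(col) length(unique(col)) < 2L)
    if (any(const)) {
      stop_validation("degenerate predictor: '", colnames(b)[const][1L],
                      "' is constant")
    }
    cox_multivariate(b, clin)  # joint over one covariate's contrasts
  }))
  rownames(uni) <- NULL
  multi <- cox_multivariate(do.call(cbind, blocks), clin)
  list(univariate = uni, multivariate = multi)
}
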