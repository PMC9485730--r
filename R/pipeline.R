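#' Pipeline configuration
#'
#' Paths to the input files and every analysis threshold, with defaults equal
#' to the stated screening/design thresholds: correlation screen `|rho| >= 0.4`
#' at `p <= 1e-4`, differential-expression raw-p gate 0.05 with the mean +/- 2
#' SD fold-change gate, pair-ratio open interval (0.2, 0.8), reverse immune
#' extraction at `|rho| >= 0.4`, `p < 0.05`, 10-fold LASSO CV, median-split
#' stratification and 1/2/3-year ROC horizons (in months).
#'
#' @param discovery_expr,discovery_labels,survival_expr,clinical,immune_list
#'   input file paths (see [simulate_cohorts()] for the expected formats).
#' @param gmt optional GMT path for over-representation (skipped if `NULL`).
#' @param rho_min,p_max_cor correlation-screen thresholds.
#' @param p_max_de raw p ceiling for differential-expression calls.
#' @param pair_lo,pair_hi pair-ratio filter bounds (strict).
#' @param p_max_cox univariate/multivariate significance threshold.
#' @param rho_min_rev,p_max_rev reverse immune-gene extraction thresholds.
#' @param n_folds LASSO cross-validation folds.
#' @param cutoff_rule `"median"` or `"roc_optimal"`.
#' @param horizons ROC horizons, ascending, same units as `os_time`.
#' @param cor_method correlation method for both screens.
#' @param seed integer seed (drives LASSO fold assignment).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(discovery_expr, discovery_labels, survival_expr,
                            clinical, immune_list, gmt = NULL,
                            rho_min = 0.4, p_max_cor = 1e-4,
                            p_max_de = 0.05,
                            pair_lo = 0.2, pair_hi = 0.8,
                            p_max_cox = 0.05,
                            rho_min_rev = 0.4, p_max_rev = 0.05,
                            n_folds = 10L,
                            cutoff_rule = c("median", "roc_optimal"),
                            horizons = c(12, 24, 36),
                            cor_method = c("spearman", "pearson"),
                            seed = 1L) {
  if (any(diff(horizons) <= 0) || any(horizons <= 0)) {
    stop_validation("horizons must be positive and ascending")
  }
  for (thr in c(rho_min, p_max_cor, p_max_de, p_max_cox, rho_min_rev, p_max_rev)) {
    if (thr < 0 || thr > 1) stop_validation("thresholds must lie in [0, 1]")
  }
  structure(list(discovery_expr = discovery_expr,
                 discovery_labels = discovery_labels,
                 survival_expr = survival_expr,
                 clinical = clinical,
                 immune_list = immune_list, gmt = gmt,
                 rho_min = rho_min, p_max_cor = p_max_cor,
                 p_max_de = p_max_de,
                 pair_lo = pair_lo, pair_hi = pair_hi,
                 p_max_cox = p_max_cox,
                 rho_min_rev = rho_min_rev, p_max_rev = p_max_rev,
                 n_folds = as.integer(n_folds),
                 cutoff_rule = match.arg(cutoff_rule),
                 horizons = horizons,
                 cor_method = match.arg(cor_method),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full ir-lncRNA pair analysis end to end
#'
#' Executes, in order: correlation screen for ir-lncRNAs in the discovery
#' cohort; moderated-t differential expression with the fold-change gate; pair
#' encoding of the differential ir-lncRNAs in both cohorts; pair-ratio
#' filtering; cross-cohort pair intersection; univariate Cox per pair; LASSO
#' narrowing; multivariate Cox; risk-score construction and stratification;
#' Kaplan-Meier / log-rank comparison; time-dependent ROC at each horizon;
#' clinical Cox models; rank-sum comparison of risk score across clinical
#' factors; reverse extraction of immune genes linked to the model lncRNAs;
#' their differential expression; and hypergeometric over-representation
#' against the supplied gene sets. Every intermediate table is written to
#' `outdir` (when given) together with a plain-text summary of the stage
#' counts; written outputs are deterministic given the config (including its
#' seed).
#'
#' @param cfg a [pipeline_config()].
#' @param outdir optional output directory for the report bundle.
#' @param quiet suppress console progress messages.
#' @return a report list: `counts` (named stage counts), `de` (classified DE
#'   table), `model` (`risk_model`), `fits` (univariate/LASSO/multivariate),
#'   `assignment`, `km`, `roc` (one per horizon), `clinical_cox`,
#'   `riskscore_tests`, `reverse_immune`, `immune_de`, `ora`, `summary`
#'   (character lines).
#' @export
run_pipeline <- function(cfg, outdir = NULL, quiet = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  counts <- list()

  inp <- run_stage("read_inputs", {
    list(dexpr = read_expression_tsv(cfg$discovery_expr),
         labels = utils::read.delim(cfg$discovery_labels,
                                    stringsAsFactors = FALSE),
         sexpr = read_expression_tsv(cfg$survival_expr),
         clin = read_clinical_tsv(cfg$clinical),
         immune = read_symbol_list(cfg$immune_list),
         sets = if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL)
  })
  groups <- factor(inp$labels$group[match(colnames(inp$dexpr), inp$labels$sample)],
                   levels = c("non-responder", "responder"))
  if (anyNA(groups)) stop("pipeline stage 'read_inputs' failed: unlabeled samples")
  lnc_genes <- setdiff(rownames(inp$dexpr), inp$immune)
  immune_genes <- intersect(inp$immune, rownames(inp$dexpr))

  scr <- run_stage("screen", screen_ir_lncRNAs(
    inp$dexpr, immune_genes, lnc_genes,
    rho_min = cfg$rho_min, p_max = cfg$p_max_cor, method = cfg$cor_method))
  counts$ir_lncRNAs_screened <- length(scr$ir_lnc)
  say("screened ir-lncRNAs: ", counts$ir_lncRNAs_screened)

  de <- run_stage("dea", {
    de <- moderated_t_test(inp$dexpr[scr$ir_lnc, , drop = FALSE], groups)
    classify_de(de, fc_gate(de), p_max = cfg$p_max_de)
  })
  de_genes <- de$gene[de$change != "NotSig"]
  counts$de_ir_lncRNAs <- length(de_genes)
  counts$de_up <- sum(de$change == "Up")
  counts$de_down <- sum(de$change == "Down")
  say("differential ir-lncRNAs: ", counts$de_ir_lncRNAs,
      " (", counts$de_up, " up, ", counts$de_down, " down)")
  if (length(de_genes) < 2L) {
    stop("pipeline stage 'dea' failed: fewer than 2 differential ir-lncRNAs")
  }

  pm_disc <- run_stage("pair_encode", encode_pairs(inp$dexpr, de_genes))
  counts$pairs_built <- nrow(pm_disc$indicators)
  pm_disc_f <- run_stage("pair_filter",
                         pair_ratio_filter(pm_disc, cfg$pair_lo, cfg$pair_hi))
  counts$pairs_filtered <- nrow(pm_disc_f$indicators)

  surv_genes <- intersect(de_genes, rownames(inp$sexpr))
  pm_surv <- run_stage("pair_encode_survival", {
    pair_ratio_filter(encode_pairs(inp$sexpr, surv_genes),
                      cfg$pair_lo, cfg$pair_hi)
  })
  inter <- run_stage("pair_intersect", intersect_pairs(pm_disc_f, pm_surv))
  counts$pairs_intersected <- length(inter$pairs)
  say("pairs built/filtered/intersected: ", counts$pairs_built, "/",
      counts$pairs_filtered, "/", counts$pairs_intersected)
  pm <- inter$b  # survival-cohort view drives the Cox models
  clin <- inp$clin[match(pm$samples, inp$clin$sample), ]

  uni <- run_stage("cox_univariate", {
    do.call(rbind, lapply(seq_len(nrow(pm$indicators)), function(i) {
      x <- pm$indicators[i, ]
      if (length(unique(x)) < 2L) return(NULL)
      cox_univariate(x, clin, label = pm$pairs$label[i])
    }))
  })
  sig_pairs <- uni$variable[uni$p < cfg$p_max_cox]
  counts$pairs_univariate_significant <- length(sig_pairs)
  say("univariate-significant pairs: ", counts$pairs_univariate_significant)
  if (!length(sig_pairs)) {
    stop("pipeline stage 'cox_univariate' failed: no significant pairs")
  }

  pm_sig <- subset_pair_matrix(pm, match(sig_pairs, pm$pairs$label))
  lasso <- if (length(sig_pairs) >= 2L) {
    run_stage("lasso", lasso_cox_select(pm_sig, clin, n_folds = cfg$n_folds,
                                        seed = cfg$seed))
  } else list(selected = sig_pairs, path = NULL)
  selected <- if (length(lasso$selected)) lasso$selected else sig_pairs
  counts$pairs_lasso_selected <- length(selected)

  pm_sel <- subset_pair_matrix(pm, match(selected, pm$pairs$label))
  multi <- run_stage("cox_multivariate", cox_multivariate(pm_sel, clin))
  final <- multi[multi$p < cfg$p_max_cox, , drop = FALSE]
  if (!nrow(final)) {
    warning("no multivariate-significant pairs; keeping all LASSO-selected pairs")
    final <- multi
  }
  counts$pairs_in_model <- nrow(final)
  say("model pairs: ", counts$pairs_in_model)
  model <- risk_model(final$variable, final$beta)

  pm_model <- subset_pair_matrix(pm, match(final$variable, pm$pairs$label))
  scores <- risk_score(model, pm_model)
  assign <- run_stage("stratify", {
    if (cfg$cutoff_rule == "roc_optimal") {
      stratify(scores, "roc_optimal", clin = clin, horizon = cfg$horizons[1L])
    } else stratify(scores, "median")
  })
  counts$high_risk <- sum(assign$group == "high")
  counts$low_risk <- sum(assign$group == "low")
  km <- run_stage("km_logrank", km_logrank(assign, clin))
  roc <- run_stage("time_roc", lapply(cfg$horizons, function(h) {
    time_roc(scores, clin, h)
  }))
  names(roc) <- paste0("horizon_", cfg$horizons)

  ccox <- run_stage("cox_clinical", cox_clinical(clin, scores))
  rtests <- run_stage("riskscore_by_clinical", {
    feats <- intersect(c("sex", "tobacco", "alcohol", "t_stage", "n_stage",
                         "tnm_stage", "grade"), names(clin))
    feats <- feats[vapply(feats, function(f) {
      length(unique(stats::na.omit(clin[[f]]))) >= 2L
    }, logical(1L))]
    riskscore_by_clinical(assign, clin, feats)
  })

  model_lnc <- unique(unlist(strsplit(final$variable, "|", fixed = TRUE)))
  rev_imm <- run_stage("reverse_immune", reverse_immune_genes(
    inp$dexpr, model_lnc, immune_genes,
    rho_min = cfg$rho_min_rev, p_max = cfg$p_max_rev, method = cfg$cor_method))
  counts$reverse_immune_genes <- length(rev_imm)
  imm_de <- if (length(rev_imm)) {
    run_stage("immune_dea", immune_gene_dea(inp$dexpr, groups, rev_imm,
                                            p_max = cfg$p_max_de))
  } else NULL
  counts$immune_de_significant <- if (is.null(imm_de)) 0L else {
    sum(imm_de$change != "NotSig")
  }

  ora <- NULL
  if (!is.null(inp$sets) && !is.null(imm_de) && counts$immune_de_significant > 0L) {
    ora <- run_stage("ora", ora_hypergeometric(
      imm_de$gene[imm_de$change != "NotSig"], rev_imm, inp$sets))
  }

  summary_lines <- c(
    sprintf("ir-lncRNAs screened: %d", counts$ir_lncRNAs_screened),
    sprintf("differential ir-lncRNAs: %d (%d up, %d down)",
            counts$de_ir_lncRNAs, counts$de_up, counts$de_down),
    sprintf("pairs built: %d", counts$pairs_built),
    sprintf("pairs after ratio filter (%g, %g): %d",
            cfg$pair_lo, cfg$pair_hi, counts$pairs_filtered),
    sprintf("pairs after cross-cohort intersection: %d",
            counts$pairs_intersected),
    sprintf("univariate-significant pairs (p < %g): %d",
            cfg$p_max_cox, counts$pairs_univariate_significant),
    sprintf("LASSO-selected pairs: %d", counts$pairs_lasso_selected),
    sprintf("pairs in final model: %d", counts$pairs_in_model),
    sprintf("risk groups (cutoff %s = %.4f): %d high / %d low",
            cfg$cutoff_rule, assign$cutoff[1L], counts$high_risk,
            counts$low_risk),
    sprintf("log-rank chi-square %.3f, p = %.4g", km$chisq, km$p),
    sprintf("time-ROC AUC at %s: %s",
            paste(cfg$horizons, collapse = "/"),
            paste(sprintf("%.3f", vapply(roc, `[[`, 0, "auc")), collapse = "/")),
    sprintf("reverse-extracted immune genes: %d", counts$reverse_immune_genes),
    sprintf("differential immune genes: %d", counts$immune_de_significant),
    sprintf("seed: %d", cfg$seed)
  )

  report <- list(counts = counts, de = de, model = model,
                 fits = list(univariate = uni, lasso = lasso$path,
                             multivariate = multi, final = final),
                 assignment = assign, km = km, roc = roc,
                 clinical_cox = ccox, riskscore_tests = rtests,
                 reverse_immune = rev_imm, immune_de = imm_de, ora = ora,
                 summary = summary_lines)
  if (!is.null(outdir)) write_report_bundle(report, cfg, outdir,
                                            pm_disc_f = pm_disc_f, pm = pm)
  report
}

write_report_bundle <- function(report, cfg, outdir, pm_disc_f, pm) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_de_tsv(report$de, file.path(outdir, "ir_lncRNA_de.tsv"))
  write_pair_matrix(pm_disc_f, file.path(outdir, "pairs_discovery.tsv"))
  write_pair_matrix(pm, file.path(outdir, "pairs_survival.tsv"))
  w(report$fits$univariate, "cox_univariate.tsv")
  w(report$fits$multivariate, "cox_multivariate.tsv")
  write_risk_model(report$model, file.path(outdir, "risk_model.json"),
                   cutoff = report$assignment$cutoff[1L],
                   cutoff_rule = cfg$cutoff_rule)
  w(report$assignment, "risk_assignment.tsv")
  w(report$km$curves, "km_curves.tsv")
  for (nm in names(report$roc)) {
    w(report$roc[[nm]]$curve, paste0("roc_", nm, ".tsv"))
  }
  w(report$clinical_cox$univariate, "clinical_cox_univariate.tsv")
  w(report$clinical_cox$multivariate, "clinical_cox_multivariate.tsv")
  w(report$riskscore_tests, "riskscore_by_clinical.tsv")
  if (!is.null(report$immune_de)) {
    write_de_tsv(report$immune_de, file.path(outdir, "immune_gene_de.tsv"))
  }
  if (!is.null(report$ora)) w(report$ora, "enrichment.tsv")
  writeLines(report$summary, file.path(outdir, "summary.txt"))
  invisible(outdir)
}
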