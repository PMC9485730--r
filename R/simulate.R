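#' Simulation configuration for synthetic cohorts
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate the
#' study conditions the pipeline was designed for: a 28-sample two-group
#' discovery cohort (17 radioresistant non-responders, 11 responders), a
#' 179-sample survival cohort, 137 immune genes, 700 lncRNAs of which 681 are
#' truly correlated (rho 0.85) with an immune gene and 26 carry a group effect
#' of 1.5 log2 units, and three planted proportional-hazards pair effects with
#' the magnitudes of the published 3-pair risk model.
#'
#' @param n_samples_discovery discovery cohort size (default 28).
#' @param n_nonresponder number of non-responder (radioresistant) samples
#'   (default 17); responders make up the remainder.
#' @param n_samples_survival survival cohort size (default 179).
#' @param n_immune_genes number of immune genes (default 137).
#' @param n_lncRNAs number of lncRNAs (default 700).
#' @param n_linked_lnc lncRNAs given a true correlation `rho_true` with an
#'   immune gene (default 681).
#' @param rho_true true signal correlation of linked lncRNAs, in (-1, 1).
#' @param n_de_lnc lncRNAs with a true between-group mean shift (default 26);
#'   these are always among the linked ones.
#' @param de_effect size of the group shift on the log2 scale (default 1.5,
#'   alternating sign across the affected lncRNAs).
#' @param pair_betas named numeric vector of true Cox log-hazard ratios for
#'   pair indicators; names are `"A|B"` labels over genes in the panel. The
#'   default pairs combine differential lncRNAs shifted in the same direction,
#'   so their relative order (and hence the pair ratio) is informative in both
#'   cohorts rather than saturated by the group shift.
#' @param baseline_hazard exponential baseline event rate per month (> 0).
#' @param censor_rate exponential censoring rate per month (> 0); the default
#'   pairing of 0.012 with 0.03 yields roughly half the cohort with events.
#' @param noise_sd standard deviation of measurement noise added on top of the
#'   unit-variance biological signal (> 0).
#' @param seed integer seed; one seed drives independent sub-streams for
#'   expression, survival, censoring and clinical draws, so enlarging the gene
#'   panel does not perturb the survival draws.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples_discovery = 28L,
                       n_nonresponder = 17L,
                       n_samples_survival = 179L,
                       n_immune_genes = 137L,
                       n_lncRNAs = 700L,
                       n_linked_lnc = 681L,
                       rho_true = 0.85,
                       n_de_lnc = 26L,
                       de_effect = 1.5,
                       pair_betas = c("LNC0001|LNC0003" = 0.687,
                                      "LNC0002|LNC0004" = 0.863,
                                      "LNC0005|LNC0007" = 0.419),
                       baseline_hazard = 0.012,
                       censor_rate = 0.03,
                       noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_samples_discovery = as.integer(n_samples_discovery),
              n_nonresponder = as.integer(n_nonresponder),
              n_samples_survival = as.integer(n_samples_survival),
              n_immune_genes = as.integer(n_immune_genes),
              n_lncRNAs = as.integer(n_lncRNAs),
              n_linked_lnc = as.integer(n_linked_lnc),
              rho_true = rho_true,
              n_de_lnc = as.integer(n_de_lnc),
              de_effect = de_effect,
              pair_betas = pair_betas,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  counts <- c("n_samples_discovery", "n_samples_survival", "n_immune_genes",
              "n_lncRNAs", "n_nonresponder")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) {
      stop_validation(nm, " must be a positive integer")
    }
  }
  if (cfg$n_nonresponder >= cfg$n_samples_discovery) {
    stop_validation("n_nonresponder must be smaller than n_samples_discovery")
  }
  if (cfg$n_linked_lnc < 0L || cfg$n_linked_lnc > cfg$n_lncRNAs) {
    stop_validation("n_linked_lnc must be between 0 and n_lncRNAs")
  }
  if (cfg$n_de_lnc < 0L || cfg$n_de_lnc > cfg$n_lncRNAs) {
    stop_validation("n_de_lnc must be between 0 and n_lncRNAs")
  }
  if (abs(cfg$rho_true) >= 1) stop_validation("rho_true must lie in (-1, 1)")
  if (cfg$baseline_hazard <= 0 || cfg$censor_rate <= 0) {
    stop_validation("baseline_hazard and censor_rate must be positive")
  }
  if (cfg$noise_sd <= 0) stop_validation("noise_sd must be positive")
  if (length(cfg$pair_betas) && is.null(names(cfg$pair_betas))) {
    stop_validation("pair_betas must be a named vector of 'A|B' labels")
  }
  structure(cfg, class = "sim_config")
}

gene_panel <- function(cfg) {
  list(immune = sprintf("IMM%04d", seq_len(cfg$n_immune_genes)),
       lnc = sprintf("LNC%04d", seq_len(cfg$n_lncRNAs)))
}

## Signal + noise expression draw shared by both cohorts. Linked lncRNA j gets
## signal rho * z(partner immune gene) + sqrt(1-rho^2) * white noise, so its
## signal correlation with the partner is exactly rho_true; measurement noise
## (noise_sd) attenuates the observed correlation toward 0 and vanishing noise
## recovers rho_true.
draw_expression <- function(cfg, n, mean_seed_offset = 0L) {
  panel <- gene_panel(cfg)
  n_imm <- cfg$n_immune_genes
  n_lnc <- cfg$n_lncRNAs

  mu_imm <- stats::runif(n_imm, 4, 8)
  mu_lnc <- stats::runif(n_lnc, 4, 6)
  # genes carrying planted pair effects share a mean so their indicator is
  # informative (pair ratio near 0.5) rather than degenerate
  pair_genes <- if (length(cfg$pair_betas)) {
    unique(unlist(strsplit(names(cfg$pair_betas), "|", fixed = TRUE)))
  } else character(0)
  mu_lnc[match(intersect(pair_genes, panel$lnc), panel$lnc)] <- 5

  z_imm <- matrix(stats::rnorm(n_imm * n), n_imm, n)
  z_lnc <- matrix(stats::rnorm(n_lnc * n), n_lnc, n)
  if (cfg$n_linked_lnc > 0L) {
    idx <- seq_len(cfg$n_linked_lnc)
    partner <- ((idx - 1L) %% n_imm) + 1L
    rho <- cfg$rho_true
    z_lnc[idx, ] <- rho * z_imm[partner, , drop = FALSE] +
      sqrt(1 - rho^2) * z_lnc[idx, , drop = FALSE]
  }
  sig <- rbind(z_imm, z_lnc)
  expr <- sig + c(mu_imm, mu_lnc) +
    matrix(stats::rnorm(length(sig), sd = cfg$noise_sd), nrow(sig), n)
  rownames(expr) <- c(panel$immune, panel$lnc)
  expr
}

#' Generate the two-group discovery cohort
#'
#' Emulates a pretreatment expression cohort split into radioresistant
#' non-responders and responders: `n_linked_lnc` lncRNAs are correlated
#' (`rho_true`) with immune genes, and `n_de_lnc` of them additionally carry a
#' between-group mean shift of `de_effect` log2 units (alternating sign), the
#' structure the screening and differential-expression stages assume. Each
#' shifted lncRNA's immune partner carries the same group shift (co-regulated
#' pair), so planted differential lncRNAs remain immune-related across groups;
#' with `n_de_lnc <= n_immune_genes` the shifted partners are distinct.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (genes x samples log2 matrix) and `groups`
#'   (factor, levels `non-responder`, `responder`, named by sample).
#' @export
generate_discovery_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples_discovery
  samples <- sprintf("D%02d", seq_len(n))
  groups <- factor(rep(c("non-responder", "responder"),
                       c(cfg$n_nonresponder, n - cfg$n_nonresponder)),
                   levels = c("non-responder", "responder"))
  names(groups) <- samples

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, "expression"))
  expr <- draw_expression(cfg, n)
  colnames(expr) <- samples

  if (cfg$n_de_lnc > 0L) {
    idx <- seq_len(cfg$n_de_lnc)
    lnc_rows <- cfg$n_immune_genes + idx
    signs <- rep_len(c(1, -1), cfg$n_de_lnc)
    shift <- outer(signs * cfg$de_effect, as.numeric(groups == "non-responder"))
    expr[lnc_rows, ] <- expr[lnc_rows, ] + shift
    # the linked immune partner is co-regulated and carries the same group
    # effect; without this the shift would dilute the planted correlation and
    # a DE lncRNA could fail its own immune-relatedness screen
    partner_rows <- ((idx - 1L) %% cfg$n_immune_genes) + 1L
    expr[partner_rows, ] <- expr[partner_rows, ] + shift
  }
  check_expression_matrix(expr)
  list(expr = expr, groups = groups)
}

#' Generate the survival validation cohort
#'
#' Draws an expression matrix over the same gene panel (no group structure),
#' derives the 0/1 indicators of the planted pairs, and generates event times
#' from an exponential proportional-hazards model with linear predictor
#' `sum(beta_i * indicator_i)`, with independent exponential censoring.
#' Clinical covariates (sex, age, tobacco, alcohol, T/N/TNM stage, grade) are
#' drawn independently of expression, with margins matching the published
#' cohort description.
#'
#' @param cfg a [sim_config()]. Every gene named in `cfg$pair_betas` must be in
#'   the panel.
#' @return list with `expr` (genes x samples) and `clinical` (data.frame with
#'   `sample`, `os_time` in months, `os_event`, and covariates).
#' @export
generate_survival_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- gene_panel(cfg)
  pair_genes <- if (length(cfg$pair_betas)) {
    unlist(strsplit(names(cfg$pair_betas), "|", fixed = TRUE))
  } else character(0)
  unknown <- setdiff(pair_genes, c(panel$immune, panel$lnc))
  if (length(unknown)) {
    stop_key("pair_betas reference unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  n <- cfg$n_samples_survival
  samples <- sprintf("S%03d", seq_len(n))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, "survival"))
  expr <- draw_expression(cfg, n)
  colnames(expr) <- samples

  lp <- numeric(n)
  for (lab in names(cfg$pair_betas)) {
    g <- strsplit(lab, "|", fixed = TRUE)[[1L]]
    ind <- as.numeric(expr[g[1L], ] > expr[g[2L], ])
    lp <- lp + cfg$pair_betas[[lab]] * ind
  }
  event_time <- stats::rexp(n) / (cfg$baseline_hazard * exp(lp))

  set.seed(sub_seed(cfg$seed, "censor"))
  censor_time <- stats::rexp(n, rate = cfg$censor_rate)
  os_time <- pmin(event_time, censor_time)
  os_event <- as.integer(event_time <= censor_time)

  set.seed(sub_seed(cfg$seed, "clinical"))
  counts <- table2_fixture()
  draw_level <- function(item) {
    sub <- counts[counts$item == item, ]
    sample(sub$level, n, replace = TRUE, prob = sub$count)
  }
  age <- round(pmin(pmax(stats::rnorm(n, 58, 9), 36), 82), 1)
  clinical <- data.frame(
    sample = samples,
    os_time = os_time,
    os_event = os_event,
    sex = draw_level("sex"),
    age = age,
    tobacco = draw_level("tobacco"),
    alcohol = draw_level("alcohol"),
    t_stage = draw_level("t_stage"),
    n_stage = draw_level("n_stage"),
    tnm_stage = draw_level("tnm_stage"),
    grade = draw_level("grade"),
    stringsAsFactors = FALSE
  )
  check_clinical_table(clinical)
  list(expr = expr, clinical = clinical)
}

#' Write synthetic cohorts and companion inputs to a directory
#'
#' Materializes everything [run_pipeline()] consumes: discovery and survival
#' expression TSVs, group labels, the clinical table, the immune-gene symbol
#' list, and a small example GMT built from the immune panel.
#'
#' @param cfg a [sim_config()].
#' @param outdir writable output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
simulate_cohorts <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop_format("cannot create output directory: ", outdir)
  disc <- generate_discovery_cohort(cfg)
  surv <- generate_survival_cohort(cfg)
  panel <- gene_panel(cfg)

  paths <- c(
    discovery_expr = file.path(outdir, "discovery_expression.tsv"),
    discovery_labels = file.path(outdir, "discovery_labels.tsv"),
    survival_expr = file.path(outdir, "survival_expression.tsv"),
    clinical = file.path(outdir, "survival_clinical.tsv"),
    immune_list = file.path(outdir, "immune_genes.txt"),
    gmt = file.path(outdir, "example_sets.gmt")
  )
  write_expression_tsv(disc$expr, paths[["discovery_expr"]])
  utils::write.table(
    data.frame(sample = names(disc$groups), group = as.character(disc$groups)),
    paths[["discovery_labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_tsv(surv$expr, paths[["survival_expr"]])
  write_clinical_tsv(surv$clinical, paths[["clinical"]])
  writeLines(panel$immune, paths[["immune_list"]])
  gmt <- c(paste(c("immune_set_A", "first third of immune panel",
                   panel$immune[seq_len(ceiling(cfg$n_immune_genes / 3))]),
                 collapse = "\t"),
           paste(c("immune_set_B", "last third of immune panel",
                   panel$immune[seq.int(floor(2 * cfg$n_immune_genes / 3) + 1L,
                                        cfg$n_immune_genes)]),
                 collapse = "\t"))
  writeLines(gmt, paths[["gmt"]])
  invisible(paths)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
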