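# small deterministic builders shared across test files

# genes x samples matrix of N(mu, 1) log2-like values
rand_expr <- function(n_genes, n_samples, seed = 1, mu = 6,
                      genes = sprintf("G%03d", seq_len(n_genes)),
                      samples = sprintf("S%02d", seq_len(n_samples))) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = mu), n_genes, n_samples,
              dimnames = list(genes, samples))
  m
}

# clinical table with given times/events and no covariates
mini_clinical <- function(time, event, samples = sprintf("S%02d", seq_along(time))) {
  data.frame(sample = samples, os_time = time, os_event = event,
             stringsAsFactors = FALSE)
}

# exponential survival data driven by a linear predictor, uncensored by default
sim_surv <- function(lp, seed = 1, base_rate = 0.05, censor_rate = NULL) {
  set.seed(seed)
  n <- length(lp)
  t_event <- rexp(n) / (base_rate * exp(lp))
  if (is.null(censor_rate)) {
    mini_clinical(t_event, rep(1L, n))
  } else {
    cens <- rexp(n, censor_rate)
    mini_clinical(pmin(t_event, cens), as.integer(t_event <= cens))
  }
}

# tie-corrected Mann-Whitney AUC of scores for binary labels (1 = case)
mw_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  cmp <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small sim_config used by pipeline-level tests: strong, low-noise effects and
# a sparse differential fraction (like the study's 26/681) so every pipeline
# stage has signal to work with, at a fraction of the full size
pipeline_test_config <- function(seed = 7L, ...) {
  sim_config(n_lncRNAs = 200L, n_linked_lnc = 190L, n_de_lnc = 12L,
             n_immune_genes = 40L, de_effect = 3, noise_sd = 0.3,
             rho_true = 0.9, seed = seed, ...)
}
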