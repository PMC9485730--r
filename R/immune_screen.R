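## correlation of every immune gene with every lncRNA, plus a t-approximation
## p-value on n-2 df (same approximation for Pearson and Spearman rho)
correlate_genes <- function(expr, rows_a, rows_b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  check_expression_matrix(expr)
  missing_g <- setdiff(c(rows_a, rows_b), rownames(expr))
  if (length(missing_g)) {
    stop_key("genes absent from expression matrix: ",
             paste(utils::head(missing_g, 5L), collapse = ", "))
  }
  n <- ncol(expr)
  if (n < 3L) stop_validation("need at least 3 samples for correlation screening")
  sds <- apply(expr[c(rows_a, rows_b), , drop = FALSE], 1L, stats::sd)
  flat <- names(sds)[sds == 0]
  if (length(flat)) {
    warning("zero-variance gene(s) excluded from correlation screen: ",
            paste(utils::head(flat, 5L), collapse = ", "))
    rows_a <- setdiff(rows_a, flat)
    rows_b <- setdiff(rows_b, flat)
  }
  if (!length(rows_a) || !length(rows_b)) {
    return(data.frame(immune_gene = character(), lncRNA = character(),
                      rho = numeric(), p = numeric()))
  }
  r <- stats::cor(t(expr[rows_a, , drop = FALSE]),
                  t(expr[rows_b, , drop = FALSE]), method = method)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  data.frame(immune_gene = rep(rows_a, times = length(rows_b)),
             lncRNA = rep(rows_b, each = length(rows_a)),
             rho = as.vector(r), p = as.vector(p),
             stringsAsFactors = FALSE)
}

#' Screen immune-related lncRNAs by correlation with immune genes
#'
#' A lncRNA is called immune-related (ir-lncRNA) when it correlates with at
#' least one immune gene at `|rho| >= rho_min` and `p <= p_max` (defaults 0.4
#' and 1e-4, the screening thresholds the pipeline was designed around).
#' Spearman correlation is the default; p-values use the t approximation on
#' n-2 degrees of freedom. Zero-variance genes are excluded with a warning.
#'
#' @param expr expression matrix (genes x samples, log2).
#' @param immune_genes,lnc_genes disjoint character vectors of symbols present
#'   in `expr`.
#' @param rho_min minimum absolute correlation (default 0.4).
#' @param p_max maximum correlation p-value (default 1e-4).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `ir_lnc` (character vector of retained lncRNAs, in
#'   `lnc_genes` order) and `records` (data.frame of all qualifying
#'   immune-gene/lncRNA correlation records).
#' @export
screen_ir_lncRNAs <- function(expr, immune_genes, lnc_genes,
                              rho_min = 0.4, p_max = 1e-4,
                              method = c("spearman", "pearson")) {
  if (length(intersect(immune_genes, lnc_genes))) {
    stop_validation("immune_genes and lnc_genes must be disjoint")
  }
  rec <- correlate_genes(expr, immune_genes, lnc_genes, method = match.arg(method))
  keep <- abs(rec$rho) >= rho_min & rec$p <= p_max
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL
  list(ir_lnc = intersect(lnc_genes, unique(records$lncRNA)), records = records)
}

#' Reverse extraction of immune genes linked to model lncRNAs
#'
#' After model construction, immune genes correlated with at least one of the
#' model's lncRNAs are extracted at looser thresholds (default `|rho| >= 0.4`,
#' `p < 0.05`) for downstream differential expression and enrichment.
#'
#' @inheritParams screen_ir_lncRNAs
#' @param model_lncRNAs nonempty character vector of the model's lncRNAs.
#' @return character vector of retained immune genes (in `immune_genes` order).
#' @export
reverse_immune_genes <- function(expr, model_lncRNAs, immune_genes,
                                 rho_min = 0.4, p_max = 0.05,
                                 method = c("spearman", "pearson")) {
  if (!length(model_lncRNAs)) stop_validation("model_lncRNAs must be nonempty")
  rec <- correlate_genes(expr, immune_genes, model_lncRNAs,
                         method = match.arg(method))
  keep <- abs(rec$rho) >= rho_min & rec$p <= p_max
  intersect(immune_genes, unique(rec$immune_gene[keep]))
}

## Newton solve of trigamma(x) = y, vectorized (monotone decreasing trigamma)
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Estimate empirical-Bayes variance-moderation hyperparameters
#'
#' Fits the scaled-F prior of the moderated t-test by method of moments on the
#' log sample variances: with per-gene variances `s2` on `d` residual degrees
#' of freedom assumed distributed `s0^2 * F(d, d0)`, the prior degrees of
#' freedom `d0` solve a trigamma equation in the excess variance of
#' `log(s2)`, and `s0^2` follows from its mean. When the observed spread of
#' log-variances is no larger than expected under a common variance, `d0` is
#' infinite and `s0^2` is the (geometric-mean-based) common variance.
#'
#' @param s2 per-gene sample variances (> 0).
#' @param d residual degrees of freedom of each variance (scalar).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0_sq` (prior
#'   variance).
#' @export
fit_variance_prior <- function(s2, d) {
  if (any(s2 <= 0)) s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per-gene two-sample comparison on the log2 scale with the per-gene pooled
#' variance shrunk toward a prior: the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)` and the moderated t is referred to a
#' t-distribution on `d0 + d` degrees of freedom. `logFC` is
#' `mean(group1) - mean(group2)` where group1 is the first factor level;
#' `AveExpr` is the grand mean; `adj_p` is Benjamini-Hochberg. With `d0 = 0`
#' the statistic is exactly the ordinary pooled-variance t.
#'
#' @param expr expression matrix (genes x samples, log2).
#' @param groups factor (or coercible) of length `ncol(expr)` with exactly two
#'   levels, each with at least 2 samples.
#' @param moderation `"auto"` (default) to estimate `d0`/`s0_sq` from the data
#'   by [fit_variance_prior()], or a list with elements `d0` and `s0_sq`.
#' @return data.frame with columns `gene`, `logFC`, `AveExpr`, `t`, `p`,
#'   `adj_p`, `change` (initialized `"NotSig"`; see [classify_de()]).
#' @export
moderated_t_test <- function(expr, groups, moderation = "auto") {
  check_expression_matrix(expr)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L || length(groups) != ncol(expr)) {
    stop_validation("groups must be a two-level factor matching the samples")
  }
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (min(n1, n2) < 2L) stop_validation("each group needs at least 2 samples")

  x1 <- expr[, groups == levels(groups)[1L], drop = FALSE]
  x2 <- expr[, groups == levels(groups)[2L], drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var)
  v2 <- apply(x2, 1L, stats::var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d

  if (identical(moderation, "auto")) {
    moderation <- fit_variance_prior(s2, d)
  }
  d0 <- moderation$d0
  s0_sq <- moderation$s0_sq
  if (is.null(d0) || is.null(s0_sq) || d0 < 0 || (is.finite(d0) && d0 > 0 && s0_sq <= 0)) {
    stop_validation("moderation must provide d0 >= 0 and s0_sq > 0")
  }
  s_tilde2 <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 1, 0)
  tstat[se == 0 & m1 == m2] <- 0

  data.frame(gene = rownames(expr),
             logFC = unname(m1 - m2),
             AveExpr = unname(rowMeans(expr)),
             t = unname(tstat),
             p = unname(p),
             adj_p = unname(stats::p.adjust(p, method = "BH")),
             change = "NotSig",
             stringsAsFactors = FALSE)
}

#' Fold-change gate from the logFC distribution
#'
#' The differential-expression call uses a data-driven fold-change gate: a gene
#' is extreme when its log2 fold change falls outside mean(logFC) +/- 2 *
#' sd(logFC) computed over all tested genes.
#'
#' @param de data.frame with a `logFC` column (>= 2 rows).
#' @return numeric `c(lo, hi)`.
#' @export
fc_gate <- function(de) {
  lfc <- de$logFC
  if (length(lfc) < 2L) stop_validation("fc_gate needs at least 2 genes")
  c(lo = mean(lfc) - 2 * stats::sd(lfc), hi = mean(lfc) + 2 * stats::sd(lfc))
}

#' Classify differential-expression calls
#'
#' `Up` when `logFC > hi` and `p <= p_max`; `Down` when `logFC < lo` and
#' `p <= p_max`; otherwise `NotSig`. The gate comes from [fc_gate()]; the
#' p-value filter is on the raw p-value (the adjusted p is reported but not
#' filtered on).
#'
#' @param de data.frame from [moderated_t_test()].
#' @param gate numeric `c(lo, hi)`.
#' @param p_max raw p-value ceiling (default 0.05).
#' @return `de` with its `change` column set.
#' @export
classify_de <- function(de, gate, p_max = 0.05) {
  lo <- gate[[1L]]
  hi <- gate[[2L]]
  de$change <- ifelse(de$logFC > hi & de$p <= p_max, "Up",
                      ifelse(de$logFC < lo & de$p <= p_max, "Down", "NotSig"))
  de
}

#' Write a differential-expression table as TSV
#'
#' Columns are emitted with the conventional display names
#' (`log FC`, `Ave Expr`, `t`, `p value`, `adj p value`, `Change`).
#'
#' @param de data.frame from [moderated_t_test()] / [classify_de()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  out <- de
  names(out) <- c("Genes", "log FC", "Ave Expr", "t", "p value",
                  "adj p value", "Change")[seq_along(names(out))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
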