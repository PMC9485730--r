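#' Compare risk scores across clinical factor levels
#'
#' Two-level factors use the Wilcoxon rank-sum test (exact when both sides
#' have at most 10 untied observations, otherwise the normal approximation
#' with continuity correction); factors with more than two levels use
#' Kruskal-Wallis. Rank-based, so the p-values are invariant under strictly
#' increasing transforms of the scores.
#'
#' @param assign data.frame from [stratify()] (needs `sample`, `riskscore`).
#' @param clin clinical table covering the samples.
#' @param features character vector of clinical column names to compare.
#' @return data.frame with `feature`, `levels`, `test`, `statistic`, `p`,
#'   `effect_direction` (level with the highest median score).
#' @export
riskscore_by_clinical <- function(assign, clin, features) {
  check_clinical_table(clin)
  m <- match(assign$sample, clin$sample)
  if (anyNA(m)) stop_key("samples in assignment missing from clinical table")
  score <- assign$riskscore
  out <- lapply(features, function(f) {
    if (!f %in% names(clin)) stop_key("unknown clinical feature: ", f)
    g <- clin[[f]][m]
    ok <- !is.na(g)
    lev <- unique(g[ok])
    if (length(lev) < 2L) {
      stop_validation("feature '", f, "' has fewer than 2 nonempty levels")
    }
    if (length(lev) == 2L) {
      x <- score[ok & g == lev[1L]]
      y <- score[ok & g == lev[2L]]
      exact <- max(length(x), length(y)) <= 10 &&
        !any(duplicated(c(x, y)))
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = TRUE))
      # fully tied scores: no rank information, no evidence of a shift
      if (is.nan(ht$p.value)) ht$p.value <- 1
      test <- "wilcoxon"
    } else {
      ht <- stats::kruskal.test(score[ok], factor(g[ok]))
      test <- "kruskal-wallis"
    }
    med <- tapply(score[ok], g[ok], stats::median)
    data.frame(feature = f,
               levels = paste(lev, collapse = "/"),
               test = test,
               statistic = unname(ht$statistic),
               p = ht$p.value,
               effect_direction = names(med)[which.max(med)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Differential expression of a gene subset
#'
#' Moderated-t differential expression restricted to a gene subset (typically
#' the reverse-extracted immune genes), with direction calls. Results are
#' independent of genes outside the subset: the variance prior is fitted on
#' the subset alone.
#'
#' @param expr expression matrix.
#' @param groups two-level factor over samples.
#' @param gene_subset nonempty character vector of genes in `expr`.
#' @param gate optional fold-change gate; default `c(0, 0)`, i.e. direction by
#'   sign of logFC subject to the p filter.
#' @param p_max raw p ceiling for calls (default 0.05).
#' @return data.frame as from [classify_de()].
#' @export
immune_gene_dea <- function(expr, groups, gene_subset, gate = c(0, 0),
                            p_max = 0.05) {
  if (!length(gene_subset)) stop_validation("gene_subset must be nonempty")
  missing_g <- setdiff(gene_subset, rownames(expr))
  if (length(missing_g)) {
    stop_key("genes absent from expression matrix: ",
             paste(utils::head(missing_g, 5L), collapse = ", "))
  }
  de <- moderated_t_test(expr[gene_subset, , drop = FALSE], groups)
  classify_de(de, gate, p_max = p_max)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set against a hit list, within
#' a stated universe. Each set is intersected with the universe before
#' testing. `adj_p` is Benjamini-Hochberg; the `q` column repeats the BH
#' estimate (the convention in the enrichment tables this mirrors). Results
#' are sorted by p-value.
#'
#' @param hits character vector of hit genes (must be a subset of `universe`).
#' @param universe character vector, the gene universe.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @return data.frame with `set`, `overlap`, `set_size`, `universe_size`,
#'   `draws`, `p`, `adj_p`, `q`, `members_hit`.
#' @export
ora_hypergeometric <- function(hits, universe, sets) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop_validation("empty universe")
  hits <- unique(toupper(hits))
  if (length(setdiff(hits, universe))) {
    stop_validation("hits must be a subset of the universe")
  }
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(toupper(sets[[nm]])), universe)
    ov <- intersect(hits, s)
    # P(X >= overlap), X ~ Hypergeom(set, universe-set, draws)
    p <- stats::phyper(length(ov) - 1L, length(s),
                       length(universe) - length(s), length(hits),
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = length(ov), set_size = length(s),
               universe_size = length(universe), draws = length(hits),
               p = p, members_hit = paste(sort(ov), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res$q <- res$adj_p
  res <- res[order(res$p), c("set", "overlap", "set_size", "universe_size",
                             "draws", "p", "adj_p", "q", "members_hit")]
  rownames(res) <- NULL
  res
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_case - Ct_ref_case) - (Ct_target_ctrl - Ct_ref_ctrl)`;
#' the fold change of the target in the case condition relative to control,
#' normalized to the reference gene, is `2^-ddCt`. Replicates should be
#' averaged upstream. Invariant under a common shift of all four Ct values.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in the
#'   case condition.
#' @param ct_target_ctrl,ct_ref_ctrl same in the control condition.
#' @return fold change (vectorized).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
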