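canonical_pair <- function(a, b) {
  flip <- vapply(seq_along(a),
                 function(i) sort(c(a[i], b[i]), method = "radix")[1L] != a[i],
                 logical(1L))
  list(gene_a = ifelse(flip, b, a), gene_b = ifelse(flip, a, b), flipped = flip)
}

pair_label <- function(a, b) paste(a, b, sep = "|")

new_pair_matrix <- function(pairs, indicators, samples) {
  rownames(indicators) <- pairs$label
  colnames(indicators) <- samples
  structure(list(pairs = pairs,
                 samples = samples,
                 indicators = indicators,
                 pair_ratio = rowMeans(indicators)),
            class = "pair_matrix")
}

#' Encode relative-expression 0/1 gene pairs
#'
#' For every unordered pair of the given genes, the per-sample indicator is 1
#' when the first gene's expression strictly exceeds the second's, else 0
#' (ties count as 0). Pairs are stored in canonical orientation
#' (lexicographically smaller symbol first); the orientation implied by the
#' input gene order is kept as a display label so externally reported pair
#' labels can be reconciled. The per-pair `pair_ratio` is the fraction of
#' samples with indicator 1. Because the encoding compares two genes within
#' the same sample it is rank-based per sample and needs no cross-sample
#' normalization.
#'
#' @param expr expression matrix (genes x samples).
#' @param genes character vector (>= 2, no duplicates) of genes in `expr`.
#' @return a `pair_matrix`: list with `pairs` (data.frame `gene_a`, `gene_b`,
#'   `label`, `display_label`), `samples`, `indicators` (0/1 matrix pairs x
#'   samples) and `pair_ratio`.
#' @export
encode_pairs <- function(expr, genes) {
  check_expression_matrix(expr)
  if (anyDuplicated(genes)) stop_validation("duplicate gene in pair gene list")
  if (length(genes) < 2L) stop_validation("need at least 2 genes to form pairs")
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g)) {
    stop_key("genes absent from expression matrix: ",
             paste(utils::head(missing_g, 5L), collapse = ", "))
  }
  cmb <- utils::combn(genes, 2L)
  canon <- canonical_pair(cmb[1L, ], cmb[2L, ])
  pairs <- data.frame(gene_a = canon$gene_a,
                      gene_b = canon$gene_b,
                      label = pair_label(canon$gene_a, canon$gene_b),
                      display_label = pair_label(cmb[1L, ], cmb[2L, ]),
                      stringsAsFactors = FALSE)
  ind <- (expr[pairs$gene_a, , drop = FALSE] >
            expr[pairs$gene_b, , drop = FALSE]) * 1
  new_pair_matrix(pairs, ind, colnames(expr))
}

#' Filter pairs by matching rate
#'
#' Retains pairs whose indicator is 1 in a non-degenerate fraction of samples:
#' `lo < pair_ratio < hi`, strict on both sides (default open interval
#' (0.2, 0.8)). Pairs with near-constant indicators carry no discriminative
#' information. Idempotent; preserves pair order.
#'
#' @param pm a `pair_matrix`.
#' @param lo,hi bounds with `0 <= lo < hi <= 1`.
#' @return filtered `pair_matrix`.
#' @export
pair_ratio_filter <- function(pm, lo = 0.2, hi = 0.8) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop_validation("pair-ratio bounds must satisfy 0 <= lo < hi <= 1")
  }
  keep <- pm$pair_ratio > lo & pm$pair_ratio < hi
  subset_pair_matrix(pm, which(keep))
}

subset_pair_matrix <- function(pm, idx) {
  new_pair_matrix(pm$pairs[idx, , drop = FALSE],
                  pm$indicators[idx, , drop = FALSE],
                  pm$samples)
}

#' Intersect two pair matrices on canonical pair labels
#'
#' Returns the pairs present in both matrices (matched on canonical `A|B`
#' labels, so orientation differences cannot prevent a match) together with
#' aligned row-subset views of both inputs sharing that common order.
#'
#' @param a,b `pair_matrix` objects.
#' @return list with `pairs` (common canonical labels, in `a`'s order), and
#'   `a`, `b` (the aligned subset views).
#' @export
intersect_pairs <- function(a, b) {
  stopifnot(inherits(a, "pair_matrix"), inherits(b, "pair_matrix"))
  common <- a$pairs$label[a$pairs$label %in% b$pairs$label]
  list(pairs = common,
       a = subset_pair_matrix(a, match(common, a$pairs$label)),
       b = subset_pair_matrix(b, match(common, b$pairs$label)))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat("pair_matrix:", nrow(x$indicators), "pairs x", length(x$samples),
      "samples\n")
  cat("pair_ratio range:",
      if (length(x$pair_ratio)) paste(signif(range(x$pair_ratio), 3), collapse = " - ")
      else "(empty)", "\n")
  invisible(x)
}

#' Write a pair matrix as TSV
#'
#' One row per pair: canonical label, display label, `pair_ratio`, then the
#' 0/1 indicators per sample. [read_pair_matrix()] inverts this exactly.
#'
#' @param pm a `pair_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "pair_matrix"))
  df <- data.frame(pair = pm$pairs$label,
                   display = pm$pairs$display_label,
                   pair_ratio = pm$pair_ratio,
                   pm$indicators, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair matrix written by [write_pair_matrix()]
#'
#' @param path path to the TSV.
#' @return a `pair_matrix`.
#' @export
read_pair_matrix <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- strsplit(df$pair, "|", fixed = TRUE)
  pairs <- data.frame(gene_a = vapply(genes, `[[`, "", 1L),
                      gene_b = vapply(genes, `[[`, "", 2L),
                      label = df$pair,
                      display_label = df$display,
                      stringsAsFactors = FALSE)
  ind <- as.matrix(df[, -(1:3), drop = FALSE])
  new_pair_matrix(pairs, ind, colnames(ind))
}
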