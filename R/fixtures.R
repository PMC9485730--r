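fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "irlncpair")
  if (p == "") p <- file.path("inst", "extdata", name)  # pre-install fallback
  if (!file.exists(p)) stop_format("fixture not found: ", name)
  p
}

#' Published differential-expression table for the 26 ir-lncRNAs
#'
#' The 26 immune-related lncRNAs called differentially expressed between
#' radioresistant non-responders and responders in the discovery cohort, with
#' their moderated-t statistics: 14 down- and 12 up-regulated in the
#' non-responder group.
#'
#' @return data.frame with columns `gene`, `logFC`, `AveExpr`, `t`, `p`,
#'   `adj_p`, `change`.
#' @export
table1_fixture <- function() {
  utils::read.delim(fixture_path("table1_ir_lncRNA_de.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published clinical margins of the survival cohort
#'
#' Level counts (and printed percentages) of the categorical clinical
#' covariates of the 179-patient survival cohort. Used by the synthetic
#' generator to draw covariates with matching margins.
#'
#' @return data.frame with columns `item`, `level`, `count`, `percent`.
#' @export
table2_fixture <- function() {
  utils::read.delim(fixture_path("table2_clinical_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published Cox regression table for the prognostic ir-lncRNA pairs
#'
#' Six univariate and three multivariate Cox fits of pair indicators on
#' overall survival: coefficient, standard error, hazard ratio with 95%
#' confidence bounds, and Wald p-value.
#'
#' @return data.frame with columns `pair`, `model`, `beta`, `se`, `hr`,
#'   `hr_lo`, `hr_hi`, `p`.
#' @export
table3_fixture <- function() {
  utils::read.delim(fixture_path("table3_cox.tsv"), stringsAsFactors = FALSE)
}

#' The published 3-pair risk model
#'
#' Convenience constructor for the final multivariate model: the three pair
#' indicators and their Cox coefficients (0.687, 0.863, 0.419).
#'
#' @return a [risk_model()].
#' @export
published_risk_model <- function() {
  t3 <- table3_fixture()
  m <- t3[t3$model == "Multivariate", ]
  risk_model(pairs = m$pair, coefs = m$beta)
}
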