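#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for clinical staging fields.
.stage_vocab <- list(
  t_stage   = c("T1", "T2", "T3", "T4"),
  n_stage   = c("N0", "N1", "N2", "N3"),
  tnm_stage = c("Stage I", "Stage II", "Stage III"),
  grade     = c("Poorly", "Moderately", "Well")
)

.required_clinical <- c("sample", "os_time", "os_event")

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("irlnc_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("irlnc_format_error", "error")))
}

stop_key <- function(...) {
  stop(errorCondition(paste0(...), class = c("irlnc_key_error", "error")))
}

#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix (log2 scale) with unique gene
#' symbols as row names and unique sample IDs as column names.
#'
#' @param x numeric matrix to check.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @keywords internal
check_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_validation("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(x)) || anyNA(rownames(x)) || any(rownames(x) == "")) {
    stop_validation("expression matrix must have non-empty gene symbols as rownames")
  }
  if (anyDuplicated(rownames(x))) {
    stop_validation("duplicate gene symbols in expression matrix")
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop_validation("expression matrix must have unique sample IDs as colnames")
  }
  invisible(x)
}

#' Validate a clinical table
#'
#' @param clin data.frame with at least `sample`, `os_time` (positive months)
#'   and `os_event` (0/1); staging columns, when present, must use the
#'   controlled vocabularies (T1-T4, N0-N3, Stage I-III,
#'   Poorly/Moderately/Well). Missing values are allowed in covariates but not
#'   in `os_time`/`os_event`.
#' @return `clin`, invisibly.
#' @export
check_clinical_table <- function(clin) {
  if (!is.data.frame(clin)) stop_validation("clinical table must be a data.frame")
  miss <- setdiff(.required_clinical, names(clin))
  if (length(miss)) {
    stop_validation("clinical table missing required columns: ",
                    paste(miss, collapse = ", "))
  }
  if (anyDuplicated(clin$sample)) stop_validation("duplicate sample IDs in clinical table")
  if (anyNA(clin$os_time) || any(clin$os_time <= 0)) {
    stop_validation("os_time must be positive and non-missing")
  }
  if (anyNA(clin$os_event) || !all(clin$os_event %in% c(0, 1))) {
    stop_validation("os_event must be 0 or 1")
  }
  for (col in names(.stage_vocab)) {
    if (col %in% names(clin)) {
      vals <- clin[[col]][!is.na(clin[[col]])]
      bad <- setdiff(vals, .stage_vocab[[col]])
      if (length(bad)) {
        stop_validation("invalid ", col, " value(s): ", paste(unique(bad), collapse = ", "))
      }
    }
  }
  invisible(clin)
}

## split one user seed into reproducible per-stream sub-seeds so that
## changing one generator (e.g. adding genes) does not perturb another
sub_seed <- function(seed, stream) {
  streams <- c(expression = 11L, groups = 23L, survival = 37L,
               clinical = 53L, censor = 71L, folds = 89L, noise = 101L)
  if (!stream %in% names(streams)) stop_key("unknown RNG stream: ", stream)
  (as.integer(seed) * 1009L + streams[[stream]]) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
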