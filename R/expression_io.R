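#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene symbols.
#' Values must be numeric (log2 scale by convention). Duplicate gene symbols
#' are collapsed to the single row with the highest mean expression, the usual
#' array convention when several probes map to one symbol; the collapse is
#' independent of input row order. Symbols are upper-cased.
#'
#' @param path path to a tab-separated file.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` to the values (use for
#'   matrices stored on the linear scale). Default `FALSE`: values are assumed
#'   already log2.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", quote = ""),
    error = function(e) stop_format("empty or malformed expression file: ",
                                    path, " (", conditionMessage(e), ")"))
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop_format("empty or malformed expression file: ", path)
  }
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) stop_format("duplicate sample IDs in header of ", path)
  genes <- toupper(trimws(raw[[1L]]))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num) && !anyNA(vals)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop_format("non-numeric value at row ", bad[1L], ", column ", bad[2L] + 1L,
                " of ", path)
  }
  dimnames(num) <- list(genes, samples)
  if (log2_transform) num <- log2(num + 1)
  num <- collapse_duplicate_symbols(num)
  check_expression_matrix(num)
  num
}

#' Collapse duplicate gene symbols to the max-mean row
#'
#' @param x genes x samples matrix, possibly with repeated rownames.
#' @return matrix with unique rownames; among duplicates the row with maximal
#'   mean expression is kept (ties broken by first occurrence in a
#'   mean-then-original-order sort, which makes the result order-independent).
#' @keywords internal
collapse_duplicate_symbols <- function(x) {
  if (!anyDuplicated(rownames(x))) return(x)
  means <- rowMeans(x)
  # stable order: by symbol, then decreasing mean; first row per symbol wins
  ord <- order(rownames(x), -means)
  x <- x[ord, , drop = FALSE]
  keep <- !duplicated(rownames(x))
  x[keep, , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' First column `gene`, then one column per sample; values formatted with six
#' significant digits so a write/read round trip is the identity at that
#' precision.
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  check_expression_matrix(x)
  df <- data.frame(gene = rownames(x),
                   signif(x, 6L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix style file
#'
#' Minimal reader for the series-matrix dialect: `!`-prefixed annotation lines
#' and a quoted expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Sample characteristics lines
#' (`!Sample_characteristics_ch1`) are returned as annotations.
#'
#' @param path path to a series-matrix text file.
#' @return list with `expr` (matrix, identifiers x samples) and `annotations`
#'   (data.frame, one row per sample, one column per characteristics line).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop_format("missing or malformed series-matrix table delimiters in ", path)
  }
  tbl <- lines[(beg + 1L):(end - 1L)]
  con <- textConnection(tbl)
  on.exit(close(con))
  raw <- utils::read.delim(con, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- gsub('^"|"$', "", as.character(raw[[1L]]))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(ids, gsub('^"|"$', "", colnames(raw)[-1L]))

  char_lines <- lines[grepl("^!Sample_characteristics_ch", lines)]
  ann <- NULL
  if (length(char_lines)) {
    fields <- lapply(strsplit(char_lines, "\t", fixed = TRUE), function(f) {
      gsub('^"|"$', "", f[-1L])
    })
    ann <- as.data.frame(fields, col.names = paste0("characteristics_", seq_along(fields)),
                         stringsAsFactors = FALSE)
    rownames(ann) <- colnames(vals)[seq_len(nrow(ann))]
  }
  list(expr = vals, annotations = ann)
}

#' Read a one-symbol-per-line gene list
#'
#' Used for ImmPort-style immune gene lists. Symbols are upper-cased and
#' deduplicated; a header line equal to `gene`/`symbol` (case-insensitive) is
#' dropped.
#'
#' @param path path to the list file.
#' @return character vector of unique upper-case symbols.
#' @export
read_symbol_list <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  if (length(lines) && tolower(lines[1L]) %in% c("gene", "symbol", "genes")) {
    lines <- lines[-1L]
  }
  out <- unique(toupper(lines))
  if (!length(out)) stop_format("no gene symbols found in ", path)
  out
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: tab-separated lines of set name, description, then
#' member symbols. Members are upper-cased and deduplicated; empty lines are
#' skipped.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (the gene sets), with a
#'   `description` attribute carrying one description per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (!length(lines)) stop_format("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop_format("GMT line ", bad[1L], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(toupper(trimws(p[-(1:2)]))))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Read a clinical table from TSV
#'
#' Requires `sample`, `os_time` (positive, months) and `os_event` (0/1)
#' columns; staging columns are checked against their controlled vocabularies.
#' Missing covariate values are allowed (empty string or NA), but survival
#' time/event are mandatory.
#'
#' @param path path to a tab-separated clinical file with a header.
#' @return data.frame, one row per sample.
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  clin <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE, na.strings = c("NA", ""))
  check_clinical_table(clin)
  clin
}

#' Write a clinical table as TSV
#'
#' @param clin clinical data.frame (validated before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_tsv <- function(clin, path) {
  check_clinical_table(clin)
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
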