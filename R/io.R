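# Readers and writers for the plain-text formats the package exchanges:
# expression TSV (header = sample IDs, first column = gene ID), GEO
# series-matrix text files, two-column stage maps, and the candidate table.

read_stage_map <- function(path) {
  if (!file.exists(path))
    abort_io("stage map file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "stage") %in% names(df)))
    abort_validation("stage map must have columns 'sample_id' and 'stage': ", path)
  stats::setNames(df$stage, normalize_sample_id(df$sample_id))
}

# Shared back end: takes gene ids plus a character matrix of cells (as read
# from file) and builds a validated staged_matrix with precise error
# coordinates for malformed cells.
build_staged <- function(gene_ids, sample_ids, cells, stage_map,
                         na_action = c("error", "drop"),
                         log2_transform = FALSE) {
  na_action <- match.arg(na_action)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    abort_validation("duplicate gene identifiers: ", paste(dup, collapse = ", "))

  num <- suppressWarnings(
    matrix(as.numeric(cells), nrow = length(gene_ids),
           dimnames = list(gene_ids, sample_ids))
  )
  declared_na <- is.na(cells) | trimws(cells) %in% c("", "NA", "null")
  garbled <- is.na(num) & !declared_na
  if (any(garbled)) {
    bad <- which(garbled, arr.ind = TRUE)[1L, ]
    abort_validation("non-numeric value '", cells[bad[1L], bad[2L]],
                     "' at gene '", gene_ids[bad[1L]],
                     "', sample '", sample_ids[bad[2L]], "'")
  }
  if (anyNA(num)) {
    if (na_action == "error") {
      bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
      abort_validation("missing value at gene '", gene_ids[bad[1L]],
                       "', sample '", sample_ids[bad[2L]],
                       "' (use na_action = \"drop\" to discard such genes)")
    }
    keep <- !apply(is.na(num), 1L, any)
    message("dropping ", sum(!keep), " gene(s) with missing values")
    num <- num[keep, , drop = FALSE]
  }
  if (log2_transform) num <- log2(num + 1)
  staged_matrix(num, stage_map)
}

#' Read an expression matrix from a TSV file
#'
#' Expects a header row of sample identifiers and one row per gene with the
#' gene (probe-set) identifier in the first column. Row and column order are
#' preserved. Sample identifiers are matched to the stage map after stripping
#' internal whitespace, so headers printed as `GSM 21215` work unchanged.
#'
#' @param path Path to the tab-separated expression matrix.
#' @param stage_map_path Path to a two-column TSV with header
#'   `sample_id<TAB>stage`; every sample in the matrix must appear, with a
#'   stage from [ada_stages()].
#' @param na_action `"error"` (default) rejects matrices containing missing
#'   values; `"drop"` removes genes with any missing entry and reports how
#'   many were dropped. Silent imputation is deliberately not offered because
#'   it would distort the amplitude sigma estimates downstream.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to every cell. The
#'   default assumes the input is already log-scale, which is how microarray
#'   intensity tables of this kind are usually distributed.
#' @return A validated [staged_matrix()].
#' @export
read_matrix_tsv <- function(path, stage_map_path,
                            na_action = c("error", "drop"),
                            log2_transform = FALSE) {
  if (!file.exists(path))
    abort_io("expression matrix file not found: ", path)
  stage_map <- read_stage_map(stage_map_path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "")
  if (ncol(df) < 2L)
    abort_validation("expression TSV needs a gene-ID column plus >= 1 sample column: ", path)
  gene_ids <- df[[1L]]
  sample_ids <- normalize_sample_id(names(df)[-1L])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  build_staged(gene_ids, sample_ids, cells, stage_map,
               na_action = na_action, log2_transform = log2_transform)
}

#' Read an expression matrix from a GEO series-matrix file
#'
#' Parses the text format distributed by NCBI GEO: `!`-prefixed metadata
#' lines, then a tab-separated table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` whose header row carries the sample (GSM)
#' identifiers and whose first column (`ID_REF`) carries the probe-set
#' identifiers. Metadata lines are ignored; the table is subject to the same
#' validation as [read_matrix_tsv()].
#'
#' @inheritParams read_matrix_tsv
#' @return A validated [staged_matrix()].
#' @export
read_series_matrix <- function(path, stage_map_path,
                               na_action = c("error", "drop"),
                               log2_transform = FALSE) {
  if (!file.exists(path))
    abort_io("series-matrix file not found: ", path)
  stage_map <- read_stage_map(stage_map_path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    abort_validation("not a series-matrix file (missing or empty ",
                     "!series_matrix_table_begin/!series_matrix_table_end block): ",
                     path)
  tbl <- lines[(begin + 1L):(end - 1L)]
  df <- utils::read.delim(text = tbl, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "\"")
  gene_ids <- gsub("\"", "", df[[1L]])
  sample_ids <- normalize_sample_id(gsub("\"", "", names(df)[-1L]))
  cells <- as.matrix(df[, -1L, drop = FALSE])
  build_staged(gene_ids, sample_ids, cells, stage_map,
               na_action = na_action, log2_transform = log2_transform)
}

# Full-precision numeric formatting so text round trips are bit exact.
fmt_full <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1L))
  out[is.na(x)] <- "NA"
  out
}

#' Write a stage-labelled matrix (and its stage map) back to TSV
#'
#' Values are serialised with 17 significant digits, so reading the file back
#' with [read_matrix_tsv()] reproduces the doubles bit-exactly.
#'
#' @param x A [staged_matrix()].
#' @param path Output path for the expression TSV.
#' @param stage_map_path Optional output path for the matching
#'   `sample_id / stage` TSV; skipped when `NULL`.
#' @return Invisibly, `x`.
#' @export
write_matrix_tsv <- function(x, path, stage_map_path = NULL) {
  stopifnot(inherits(x, "staged_matrix"))
  con <- tryCatch(file(path, "w"), error = function(e)
    abort_io("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  writeLines(paste(c("gene_id", x$sample_ids), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(row) paste(fmt_full(row), collapse = "\t"))
  writeLines(paste(x$gene_ids, body, sep = "\t"), con)
  if (!is.null(stage_map_path)) {
    utils::write.table(
      data.frame(sample_id = x$sample_ids, stage = unname(x$stages)),
      stage_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

candidate_columns <- function() {
  c("gene_id", "direction", "criterion",
    "A_incip", "A_moder", "A_severe",
    "D_ctrl", "D_incip", "D_moder", "D_severe")
}

#' Write a candidate-gene table to TSV
#'
#' Columns are `gene_id, direction, criterion, A_incip, A_moder, A_severe,
#' D_ctrl, D_incip, D_moder, D_severe`; rows are ordered deterministically by
#' criterion, then direction, then gene identifier. An empty candidate set
#' produces a header-only file.
#'
#' @param calls Candidate data frame as returned in the `candidates` element
#'   of [run_ada()].
#' @param path Output path.
#' @return Invisibly, the (reordered) data frame that was written.
#' @export
write_candidates <- function(calls, path) {
  cols <- candidate_columns()
  if (nrow(calls) > 0L) {
    calls <- calls[order(calls$criterion, calls$direction, calls$gene_id), cols]
  } else {
    calls <- calls[, cols]
  }
  ok <- tryCatch({
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_io("cannot write candidate table to ", path,
             " (", conditionMessage(ok), ")")
  invisible(calls)
}
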