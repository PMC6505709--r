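# Fixture builders shared across the suite. Everything is generated in code;
# no data files ship with the tests.

default_counts <- c(control = 3L, incipient = 2L, moderate = 2L, severe = 2L)

# A small staged matrix with reproducible random values.
make_staged <- function(n_genes = 6, counts = default_counts, seed = 1,
                        values = NULL) {
  n <- sum(counts)
  sample_ids <- paste0("s", seq_len(n))
  stages <- stats::setNames(rep(names(counts), counts), sample_ids)
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rnorm(n_genes * n, mean = 8, sd = 1), n_genes, n)
  }
  dimnames(values) <- list(paste0("g", seq_len(nrow(values))), sample_ids)
  staged_matrix(values, stages)
}

# Write a staged matrix as the plain TSV pair (matrix + stage map) and return
# the two paths.
write_tsv_pair <- function(x, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             stages = file.path(dir, "stages.tsv"))
  write_matrix_tsv(x, paths[["matrix"]], paths[["stages"]])
  paths
}

# Write the same content as a GEO-style series-matrix file (quoted IDs,
# !-prefixed metadata) plus a stage map.
write_series_pair <- function(x, dir = withr::local_tempdir(.local_envir = parent.frame()),
                              sample_ids = x$sample_ids) {
  mpath <- file.path(dir, "series_matrix.txt")
  spath <- file.path(dir, "stages.tsv")
  lines <- c(
    "!Series_title\t\"synthetic fixture\"",
    paste(c("!Sample_geo_accession",
            sprintf("\"%s\"", sample_ids)), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf("\"%s\"", sample_ids)), collapse = "\t"),
    vapply(seq_along(x$gene_ids), function(i) {
      paste(c(sprintf("\"%s\"", x$gene_ids[i]),
              sprintf("%.17g", x$values[i, ])), collapse = "\t")
    }, character(1)),
    "!series_matrix_table_end")
  writeLines(lines, mpath)
  utils::write.table(
    data.frame(sample_id = normalize_ids(sample_ids), stage = unname(x$stages)),
    spath, sep = "\t", quote = FALSE, row.names = FALSE)
  c(matrix = mpath, stages = spath)
}

normalize_ids <- function(x) gsub("[[:space:]]+", "", x)

# Precision / recall of a candidate table against a simulation truth table,
# counting a call correct only if its direction matches the plant.
recovery_stats <- function(calls, truth) {
  planted <- truth[truth$status != "null", ]
  key_true <- paste(planted$gene_id, planted$status)
  key_call <- paste(calls$gene_id, calls$direction)
  tp <- sum(key_call %in% key_true)
  list(precision = if (nrow(calls)) tp / nrow(calls) else 1,
       recall = if (nrow(planted)) tp / nrow(planted) else 1)
}
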