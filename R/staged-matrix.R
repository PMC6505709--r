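#' Disease stage labels
#'
#' The four patient groups recognised by the package, in progression order:
#' `control`, `incipient`, `moderate`, `severe`. All stage arguments and
#' stage-map files must use these labels.
#'
#' @return Character vector of the four stage labels in progression order.
#' @export
ada_stages <- function() c("control", "incipient", "moderate", "severe")

disease_stages <- function() ada_stages()[-1L]

# Sample IDs are matched after stripping all internal whitespace, so a header
# printed as "GSM 21215" and a stage map entry "GSM21215" refer to the same
# sample.
normalize_sample_id <- function(x) gsub("[[:space:]]+", "", x)

#' Construct a stage-labelled expression matrix
#'
#' Bundles a genes-by-samples matrix of log-scale expression intensities with
#' a sample-to-stage assignment and validates the pair: unique gene and sample
#' identifiers, finite values, a known stage for every sample, and at least
#' two samples per stage present (per-stage column centering is meaningless
#' for a single sample).
#'
#' @param values Numeric matrix, rows = genes, columns = samples, with
#'   rownames (gene/probe-set identifiers) and colnames (sample identifiers).
#' @param stages Named character vector mapping sample identifier to one of
#'   [ada_stages()]. Names are matched to `colnames(values)` after stripping
#'   internal whitespace.
#'
#' @return An object of class `staged_matrix`: a list with elements `values`
#'   (the numeric matrix), `stages` (named character vector aligned with the
#'   matrix columns), `gene_ids` and `sample_ids`.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' staged_matrix(m, c(s1 = "control", s2 = "control",
#'                    s3 = "severe",  s4 = "severe"))
staged_matrix <- function(values, stages) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_validation("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    abort_validation("`values` must carry rownames (genes) and colnames (samples)")

  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    abort_validation("duplicate gene identifiers: ",
                     paste(dup_g, collapse = ", "))
  sample_ids <- normalize_sample_id(sample_ids)
  colnames(values) <- sample_ids
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    abort_validation("duplicate sample identifiers: ",
                     paste(dup_s, collapse = ", "))

  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort_validation("non-finite expression value at gene '",
                     gene_ids[bad[1L]], "', sample '", sample_ids[bad[2L]], "'")
  }

  if (is.null(names(stages)))
    abort_validation("`stages` must be a named vector (sample_id -> stage)")
  stages <- stats::setNames(as.character(stages),
                            normalize_sample_id(names(stages)))
  missing <- setdiff(sample_ids, names(stages))
  if (length(missing))
    abort_validation("samples missing from the stage map: ",
                     paste(missing, collapse = ", "))
  stages <- stages[sample_ids]

  unknown <- unique(stages[!stages %in% ada_stages()])
  if (length(unknown))
    abort_validation("unknown stage label(s): ", paste(unknown, collapse = ", "),
                     " (expected one of ", paste(ada_stages(), collapse = ", "), ")")

  counts <- table(stages)
  small <- names(counts)[counts < 2L]
  if (length(small))
    abort_validation("stage(s) with fewer than 2 samples: ",
                     paste(small, collapse = ", "))

  structure(
    list(values = values, stages = stages,
         gene_ids = gene_ids, sample_ids = sample_ids),
    class = "staged_matrix"
  )
}

#' @export
print.staged_matrix <- function(x, ...) {
  counts <- table(factor(x$stages, levels = ada_stages()))
  cat("staged_matrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  cat("  samples per stage:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the sample columns of one stage
#'
#' @param x A [staged_matrix()].
#' @param stage One of [ada_stages()].
#' @return Numeric matrix holding only the columns of `stage`, row and column
#'   order preserved.
#' @export
stage_slice <- function(x, stage) {
  stopifnot(inherits(x, "staged_matrix"))
  if (!stage %in% x$stages)
    abort_validation("stage '", stage, "' not present in the matrix")
  x$values[, x$stages == stage, drop = FALSE]
}
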