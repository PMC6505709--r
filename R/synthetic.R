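#' Describe a synthetic stage-labelled expression study
#'
#' Specifies a simulated study with four patient groups sharing one gene list,
#' a majority of null genes whose stage means are constant, and planted genes
#' whose stage means rise (or fall) monotonically across
#' control -> incipient -> moderate -> severe. Values are generated on the log
#' scale as `baseline_i + stage_shift(i, stage_j) + sample_offset_j +
#' noise_ij`, so per-sample additive offsets — the artefact the column
#' centering removes — are part of the model.
#'
#' @param n_genes Total number of genes.
#' @param samples_per_stage Named integer vector of sample counts for
#'   `control, incipient, moderate, severe`; the default 9/7/8/7 mirrors a
#'   typical staged microarray study layout.
#' @param n_up,n_down Numbers of planted monotonically up- and down-regulated
#'   genes (`n_up + n_down <= n_genes`).
#' @param noise_sd Per-observation Gaussian noise SD in log2 units
#'   (default 0.25, a typical residual scale for log2 microarray
#'   intensities).
#' @param effect_profile Increasing per-stage mean shifts (incipient,
#'   moderate, severe) for up-regulated plants, in log2 units; negated for
#'   down-regulated plants. Default `c(8, 10, 12) * noise_sd`.
#' @param sample_offset_sd SD of the per-sample additive offset (default
#'   0.3 log2 units).
#' @param baseline_mean_range Interval from which per-gene baseline
#'   log2 intensities are drawn uniformly (default 5 to 12).
#' @param seed Integer seed making the simulation fully reproducible;
#'   `NULL` uses the current RNG state.
#' @return An object of class `synthetic_design` (a validated list of the
#'   above fields).
#' @export
synthetic_design <- function(n_genes = 1000L,
                             samples_per_stage = c(control = 9L, incipient = 7L,
                                                   moderate = 8L, severe = 7L),
                             n_up = 10L, n_down = 10L,
                             noise_sd = 0.25,
                             effect_profile = c(8, 10, 12) * noise_sd,
                             sample_offset_sd = 0.3,
                             baseline_mean_range = c(5, 12),
                             seed = NULL) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    abort_validation("`n_genes` must be a positive integer")
  if (!all(ada_stages() %in% names(samples_per_stage)))
    abort_validation("`samples_per_stage` must name all of: ",
                     paste(ada_stages(), collapse = ", "))
  samples_per_stage <- samples_per_stage[ada_stages()]
  if (any(samples_per_stage < 2))
    abort_validation("every stage needs >= 2 samples")
  if (n_up < 0 || n_down < 0 || n_up + n_down > n_genes)
    abort_validation("need n_up >= 0, n_down >= 0, n_up + n_down <= n_genes")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    abort_validation("`noise_sd` must be > 0")
  if (length(effect_profile) != 3L || any(effect_profile < 0))
    abort_validation("`effect_profile` must be three non-negative shifts ",
                     "(incipient, moderate, severe)")
  if (sample_offset_sd < 0)
    abort_validation("`sample_offset_sd` must be >= 0")
  if (length(baseline_mean_range) != 2L ||
      baseline_mean_range[1L] > baseline_mean_range[2L])
    abort_validation("`baseline_mean_range` must be an interval c(lo, hi)")

  structure(
    list(n_genes = as.integer(n_genes),
         samples_per_stage = stats::setNames(as.integer(samples_per_stage),
                                             ada_stages()),
         n_up = as.integer(n_up), n_down = as.integer(n_down),
         noise_sd = noise_sd,
         effect_profile = stats::setNames(effect_profile, disease_stages()),
         sample_offset_sd = sample_offset_sd,
         baseline_mean_range = baseline_mean_range,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "synthetic_design"
  )
}

with_design_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a stage-labelled expression matrix with known truth
#'
#' Draws per-gene baselines, per-sample offsets, Gaussian (or Student-t)
#' observation noise, and applies the planted monotone stage shifts of the
#' design. Planted gene positions are sampled uniformly among the genes. The
#' result is bit-reproducible for a given design seed.
#'
#' @param design A [synthetic_design()].
#' @param noise `"gaussian"` (default) or `"t"`; the Student-t option (with
#'   `t_df` degrees of freedom, scaled to SD `noise_sd`) generates
#'   heavy-tailed noise for stress-testing the 3-sigma cutoff.
#' @param t_df Degrees of freedom for `noise = "t"` (must exceed 2).
#' @return List with `matrix` (a [staged_matrix()]), `truth` (data frame
#'   `gene_id`, `status` in `null/up/down`), and `design`.
#' @export
#' @examples
#' sim <- simulate_expression(synthetic_design(n_genes = 100, seed = 7))
#' table(sim$truth$status)
simulate_expression <- function(design, noise = c("gaussian", "t"), t_df = 3) {
  stopifnot(inherits(design, "synthetic_design"))
  noise <- match.arg(noise)
  if (noise == "t" && t_df <= 2)
    abort_validation("`t_df` must exceed 2 so the noise variance is finite")

  with_design_seed(design$seed, {
    m <- design$n_genes
    counts <- design$samples_per_stage
    n <- sum(counts)
    stage_of_col <- rep(ada_stages(), counts)
    sample_ids <- unlist(lapply(ada_stages(), function(s)
      sprintf("%s_%d", s, seq_len(counts[[s]]))), use.names = FALSE)
    gene_ids <- sprintf("gene_%0*d", nchar(m), seq_len(m))

    status <- rep("null", m)
    planted <- sample.int(m, design$n_up + design$n_down)
    status[planted[seq_len(design$n_up)]] <- "up"
    if (design$n_down > 0)
      status[planted[design$n_up + seq_len(design$n_down)]] <- "down"

    baseline <- stats::runif(m, design$baseline_mean_range[1L],
                             design$baseline_mean_range[2L])
    offsets <- stats::rnorm(n, 0, design$sample_offset_sd)

    shift <- matrix(0, m, n)
    for (s in disease_stages()) {
      cols <- which(stage_of_col == s)
      shift[status == "up", cols] <- design$effect_profile[[s]]
      shift[status == "down", cols] <- -design$effect_profile[[s]]
    }

    eps <- if (noise == "gaussian") {
      stats::rnorm(m * n, 0, design$noise_sd)
    } else {
      stats::rt(m * n, df = t_df) * design$noise_sd / sqrt(t_df / (t_df - 2))
    }
    values <- baseline + shift + rep(offsets, each = m) +
      matrix(eps, m, n)
    dimnames(values) <- list(gene_ids, sample_ids)

    list(matrix = staged_matrix(values, stats::setNames(stage_of_col, sample_ids)),
         truth = data.frame(gene_id = gene_ids, status = status,
                            stringsAsFactors = FALSE),
         design = design)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits three TSV files into `dir`: `matrix.tsv` (expression values at full
#' precision), `stages.tsv` (sample-to-stage map), and `truth.tsv` (planted
#' status per gene).
#'
#' @param sim Result of [simulate_expression()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, named vector of the three file paths.
#' @export
write_synthetic <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             stages = file.path(dir, "stages.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix_tsv(sim$matrix, paths[["matrix"]], paths[["stages"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
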