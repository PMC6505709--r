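#' Column-center one stage of an expression matrix
#'
#' Expression intensities from different samples (array hybridisations) are
#' not directly comparable: each sample carries its own additive offset on the
#' log scale. Centering subtracts from every cell the across-gene mean of its
#' column, so `S(i, j) = T(i, j) - mean_i T(i, j)`. Each centered column sums
#' to zero, and any constant added to a whole sample column cancels exactly.
#'
#' @param x A [staged_matrix()].
#' @param stage One of [ada_stages()]; the stage whose sample columns are
#'   centered.
#' @return An object of class `deviation_matrix`: list with `stage`,
#'   `gene_ids`, and `values` (the centered genes-by-samples matrix for that
#'   stage).
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 3, 4, 5), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' sm <- staged_matrix(m, c(s1 = "control", s2 = "control"))
#' column_center(sm, "control")$values   # columns sum to zero
column_center <- function(x, stage) {
  slice <- stage_slice(x, stage)  # validates stage presence
  centered <- sweep(slice, 2L, colMeans(slice), "-")
  structure(
    list(stage = stage, gene_ids = rownames(slice), values = centered),
    class = "deviation_matrix"
  )
}

#' Per-gene overall deviation of one stage
#'
#' Averages a gene's centered deviations across the samples of one stage:
#' `D(i) = (1/n) * sum_j S(i, j)`. Averaging over replicate samples damps
#' sample-specific measurement error before stages are compared.
#'
#' @param dev A `deviation_matrix` from [column_center()].
#' @return Named numeric vector, one overall deviation per gene.
#' @export
overall_deviation <- function(dev) {
  stopifnot(inherits(dev, "deviation_matrix"))
  rowMeans(dev$values)
}

#' Overall deviations for all four stages
#'
#' Runs [column_center()] and [overall_deviation()] on every stage and
#' assembles the per-gene profile used by the selection rules.
#'
#' @param x A [staged_matrix()] containing all four stages.
#' @return Numeric matrix, genes by stages, with columns
#'   `control, incipient, moderate, severe`.
#' @export
deviation_profile <- function(x) {
  stopifnot(inherits(x, "staged_matrix"))
  missing <- setdiff(ada_stages(), unique(x$stages))
  if (length(missing))
    abort_validation("matrix is missing stage(s): ",
                     paste(missing, collapse = ", "))
  cols <- lapply(ada_stages(), function(s) overall_deviation(column_center(x, s)))
  D <- do.call(cbind, cols)
  dimnames(D) <- list(x$gene_ids, ada_stages())
  D
}

#' Signed deviation amplitudes
#'
#' For each disease stage `t` (incipient, moderate, severe) and gene `i`, the
#' signed amplitude is the change of overall deviation relative to control:
#' `A_t(i) = D_t(i) - D_control(i)`. Its sign records the direction of the
#' expression shift.
#'
#' @param profile Deviation profile from [deviation_profile()] (genes x 4
#'   stages).
#' @return Numeric matrix, genes by the three disease stages.
#' @export
signed_amplitude <- function(profile) {
  stopifnot(is.matrix(profile), all(ada_stages() %in% colnames(profile)))
  profile[, disease_stages(), drop = FALSE] - profile[, "control"]
}

#' Absolute deviation amplitudes
#'
#' The magnitude variant of [signed_amplitude()]:
#' `A'_t(i) = |D_t(i) - D_control(i)|`. Because magnitudes have a positive
#' mean, their spread (and hence the 3-sigma cutoff derived from it) is
#' smaller than that of the signed amplitudes, which is what makes the
#' criterion-based selection rule more permissive than the strict rule.
#'
#' @inheritParams signed_amplitude
#' @return Numeric matrix of non-negative amplitudes, genes by the three
#'   disease stages.
#' @export
absolute_amplitude <- function(profile) {
  abs(signed_amplitude(profile))
}

#' Combine signed and absolute amplitudes
#'
#' @inheritParams signed_amplitude
#' @return An object of class `amplitude_profile`: list with `gene_ids`,
#'   `signed`, and `absolute` matrices (genes x incipient/moderate/severe).
#' @export
amplitude_profile <- function(profile) {
  s <- signed_amplitude(profile)
  structure(
    list(gene_ids = rownames(profile), signed = s, absolute = abs(s)),
    class = "amplitude_profile"
  )
}

#' Mean and standard deviation of an amplitude vector
#'
#' Computes `mean = E(x)` and `sigma = sqrt(E(x^2) - E(x)^2)`. The default is
#' the population convention (divide by `N`), the raw-moment identity the
#' threshold rule is defined with; `convention = "sample"` divides by `N - 1`
#' for sensitivity analysis.
#'
#' @param x Non-empty numeric vector of amplitudes, all finite.
#' @param convention `"population"` (default) or `"sample"`.
#' @return Named list with `mean` and `sigma`.
#' @export
#' @examples
#' estimate_sigma(c(0, 0, 0, 4))  # mean 1, sigma sqrt(3)
estimate_sigma <- function(x, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (length(x) == 0L)
    abort_validation("cannot estimate sigma from an empty vector")
  if (any(!is.finite(x)))
    abort_validation("amplitudes must be finite")
  m <- mean(x)
  v <- mean(x^2) - m^2
  v <- max(v, 0)  # guard against negative rounding residue
  if (convention == "sample" && length(x) > 1L)
    v <- v * length(x) / (length(x) - 1L)
  list(mean = m, sigma = sqrt(v))
}

#' Per-stage 3-sigma thresholds for the selection rules
#'
#' For each disease stage, estimates the mean and sigma of the signed
#' amplitudes (used by the strict rule, which centers on the mean) and the
#' sigma of the absolute amplitudes (used by the relaxed criteria). Cutoffs
#' are `multiplier * sigma`; thresholds are per stage because the amplitude
#' spread grows with disease severity.
#'
#' @param amps An [amplitude_profile()].
#' @param multiplier Positive cutoff multiplier; 3 encodes the three-sigma
#'   rule (99.7% of normal data falls within three sigma of the mean).
#' @param convention Variance convention passed to [estimate_sigma()].
#' @return An object of class `threshold_set`: data frame with one row per
#'   disease stage and columns `stage, mean_signed, sigma_signed,
#'   sigma_absolute, cutoff_strict, cutoff_relaxed`.
#' @export
amplitude_thresholds <- function(amps, multiplier = 3,
                                 convention = c("population", "sample")) {
  stopifnot(inherits(amps, "amplitude_profile"))
  convention <- match.arg(convention)
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0)
    abort_validation("`multiplier` must be a single positive number")
  rows <- lapply(disease_stages(), function(s) {
    sg <- estimate_sigma(amps$signed[, s], convention)
    ab <- estimate_sigma(amps$absolute[, s], convention)
    data.frame(stage = s, mean_signed = sg$mean, sigma_signed = sg$sigma,
               sigma_absolute = ab$sigma,
               cutoff_strict = multiplier * sg$sigma,
               cutoff_relaxed = multiplier * ab$sigma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$stage
  attr(out, "multiplier") <- multiplier
  attr(out, "convention") <- convention
  class(out) <- c("threshold_set", "data.frame")
  out
}

monotone_up <- function(profile) {
  (profile[, "control"] < profile[, "incipient"]) &
    (profile[, "incipient"] < profile[, "moderate"]) &
    (profile[, "moderate"] < profile[, "severe"])
}

monotone_down <- function(profile) {
  (profile[, "control"] > profile[, "incipient"]) &
    (profile[, "incipient"] > profile[, "moderate"]) &
    (profile[, "moderate"] > profile[, "severe"])
}

empty_candidates <- function() {
  data.frame(gene_id = character(), direction = character(),
             criterion = character(),
             A_incip = numeric(), A_moder = numeric(), A_severe = numeric(),
             D_ctrl = numeric(), D_incip = numeric(), D_moder = numeric(),
             D_severe = numeric(), stringsAsFactors = FALSE)
}

build_calls <- function(idx, direction, criterion, profile, amps) {
  if (!length(idx)) return(empty_candidates())
  data.frame(
    gene_id = rownames(profile)[idx],
    direction = direction,
    criterion = criterion,
    A_incip = unname(amps$signed[idx, "incipient"]),
    A_moder = unname(amps$signed[idx, "moderate"]),
    A_severe = unname(amps$signed[idx, "severe"]),
    D_ctrl = unname(profile[idx, "control"]),
    D_incip = unname(profile[idx, "incipient"]),
    D_moder = unname(profile[idx, "moderate"]),
    D_severe = unname(profile[idx, "severe"]),
    stringsAsFactors = FALSE
  )
}

#' Strict 3-sigma candidate selection
#'
#' The conservative rule: a gene is called only if its mean-centered signed
#' amplitude exceeds the per-stage cutoff in magnitude,
#' `|A_t(i) - mean(A_t)| > multiplier * sigma_t`, in *all three* disease
#' stages, and its overall deviations move strictly monotonically across
#' control -> incipient -> moderate -> severe. Direction (`up`/`down`) is the
#' direction of that monotone trend.
#'
#' @param profile Deviation profile from [deviation_profile()].
#' @param amps Matching [amplitude_profile()].
#' @param thr Matching [amplitude_thresholds()].
#' @return Candidate data frame (see [write_candidates()] for the columns)
#'   with `criterion = "strict3sigma"`.
#' @export
strict_3sigma_candidates <- function(profile, amps, thr) {
  stopifnot(inherits(amps, "amplitude_profile"), inherits(thr, "threshold_set"))
  centered <- sweep(amps$signed, 2L, thr[disease_stages(), "mean_signed"], "-")
  exceeds <- sweep(abs(centered), 2L,
                   thr[disease_stages(), "cutoff_strict"], ">")
  all_stages <- rowSums(exceeds) == length(disease_stages())
  up <- which(all_stages & monotone_up(profile))
  down <- which(all_stages & monotone_down(profile))
  rbind(build_calls(up, "up", "strict3sigma", profile, amps),
        build_calls(down, "down", "strict3sigma", profile, amps))
}

#' Relaxed criterion-based candidate selection
#'
#' The two relaxed selection criteria. Criterion 1 (direction `up`): the
#' amplitude magnitude exceeds the relaxed per-stage cutoff in all three
#' disease stages *and* the overall deviations increase strictly across the
#' four stages. Criterion 2 (direction `down`): same amplitude gate, strictly
#' decreasing deviations. The cutoffs default to `multiplier * sigma*_t`,
#' where `sigma*_t` is estimated from the absolute amplitudes; because
#' `sigma* <= sigma` for amplitude distributions centered near zero, this
#' admits more genes than the strict rule while the monotone-trend gate keeps
#' direction consistency. A gene can satisfy at most one criterion (a chain
#' of strict inequalities cannot run both ways).
#'
#' @inheritParams strict_3sigma_candidates
#' @param definition Which amplitude spread sets the cutoff: `"absolute"`
#'   (default) gates `A'_t(i) > multiplier * sigma*_t`; `"signed"` gates
#'   `|A_t(i)| > multiplier * sigma_t`, for exploring the alternative reading
#'   of the amplitude definition.
#' @return Candidate data frame with `criterion` equal to `"criterion1"`
#'   (up-regulated) or `"criterion2"` (down-regulated).
#' @export
criterion_candidates <- function(profile, amps, thr,
                                 definition = c("absolute", "signed")) {
  stopifnot(inherits(amps, "amplitude_profile"), inherits(thr, "threshold_set"))
  definition <- match.arg(definition)
  cutoff <- if (definition == "absolute") {
    thr[disease_stages(), "cutoff_relaxed"]
  } else {
    thr[disease_stages(), "cutoff_strict"]
  }
  exceeds <- sweep(amps$absolute, 2L, cutoff, ">")
  all_stages <- rowSums(exceeds) == length(disease_stages())
  up <- which(all_stages & monotone_up(profile))
  down <- which(all_stages & monotone_down(profile))
  rbind(build_calls(up, "up", "criterion1", profile, amps),
        build_calls(down, "down", "criterion2", profile, amps))
}

#' Run the full amplitude-deviation screen
#'
#' Executes the pipeline end to end: (1) column-center each stage, (2) average
#' to per-gene overall deviations, (3) signed amplitudes relative to control,
#' (4) absolute amplitudes, (5) candidate selection by the strict 3-sigma rule
#' and/or the two relaxed criteria. All intermediates are returned for
#' inspection and diagnostics.
#'
#' @param x A [staged_matrix()] containing all four stages, each with at
#'   least two samples.
#' @param method `"both"` (default) runs the strict rule and the relaxed
#'   criteria and reports their calls separately (never merged); `"strict"`
#'   or `"relaxed"` runs one of them.
#' @param multiplier Cutoff multiplier, default 3 (the three-sigma rule).
#' @param convention Variance convention for sigma estimation, see
#'   [estimate_sigma()].
#' @param relaxed_definition Amplitude definition gating the relaxed rule,
#'   see [criterion_candidates()].
#' @return An object of class `ada_result`: list with `profile` (genes x 4
#'   overall deviations), `amplitudes` ([amplitude_profile()]), `thresholds`
#'   ([amplitude_thresholds()]), `candidates` (data frame), and `config`.
#' @export
#' @examples
#' design <- synthetic_design(n_genes = 200, seed = 1)
#' sim <- simulate_expression(design)
#' res <- run_ada(sim$matrix)
#' table(res$candidates$criterion, res$candidates$direction)
run_ada <- function(x, method = c("both", "strict", "relaxed"),
                    multiplier = 3,
                    convention = c("population", "sample"),
                    relaxed_definition = c("absolute", "signed")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  relaxed_definition <- match.arg(relaxed_definition)
  stopifnot(inherits(x, "staged_matrix"))

  profile <- deviation_profile(x)          # steps 1-2
  amps <- amplitude_profile(profile)       # steps 3-4
  thr <- amplitude_thresholds(amps, multiplier, convention)

  calls <- empty_candidates()              # step 5
  if (method %in% c("both", "strict"))
    calls <- rbind(calls, strict_3sigma_candidates(profile, amps, thr))
  if (method %in% c("both", "relaxed"))
    calls <- rbind(calls, criterion_candidates(profile, amps, thr,
                                               relaxed_definition))
  calls <- calls[order(calls$criterion, calls$direction, calls$gene_id), ]
  rownames(calls) <- NULL

  structure(
    list(profile = profile, amplitudes = amps, thresholds = thr,
         candidates = calls,
         config = list(method = method, multiplier = multiplier,
                       convention = convention,
                       relaxed_definition = relaxed_definition)),
    class = "ada_result"
  )
}

#' @export
print.ada_result <- function(x, ...) {
  cat("Amplitude deviation screen:", nrow(x$profile), "genes\n")
  cat("  method:", x$config$method,
      "| multiplier:", x$config$multiplier,
      "| convention:", x$config$convention, "\n")
  cat("  per-stage sigma (signed):",
      paste(sprintf("%s=%.4g", x$thresholds$stage, x$thresholds$sigma_signed),
            collapse = ", "), "\n")
  if (nrow(x$candidates)) {
    tab <- table(x$candidates$criterion, x$candidates$direction)
    cat("  candidates:\n")
    print(tab)
  } else {
    cat("  candidates: none\n")
  }
  invisible(x)
}
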