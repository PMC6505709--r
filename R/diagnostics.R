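# Distribution diagnostics for the amplitude statistics. The 3-sigma rule is
# only meaningful when the amplitude distribution is roughly normal, so the
# package reports moments and histograms for both amplitude definitions and,
# on request, an omnibus normality statistic.

pop_moments <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  list(mean = m, variance = m2,
       skewness = if (m2 > 0) mean(d^3) / m2^1.5 else NA_real_,
       excess_kurtosis = if (m2 > 0) mean(d^4) / m2^2 - 3 else NA_real_)
}

#' D'Agostino's K-squared omnibus normality test
#'
#' Combines the standard-normal transforms of sample skewness (D'Agostino
#' 1970) and sample kurtosis (Anscombe-Glynn 1983) into
#' `K2 = Z1^2 + Z2^2`, which is approximately chi-squared with 2 degrees of
#' freedom under normality.
#'
#' @param x Numeric vector, `length(x) >= 20` (the kurtosis approximation is
#'   poor below that).
#' @return List with `statistic` (K2) and `p_value`.
#' @export
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 20L)
    abort_validation("omnibus normality test needs n >= 20, got ", n)
  mom <- pop_moments(x)
  if (!is.finite(mom$skewness))
    abort_validation("omnibus normality test undefined for constant input")
  g1 <- mom$skewness
  g2 <- mom$excess_kurtosis + 3

  # skewness transform
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis transform
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- Z1^2 + Z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Summarise one amplitude distribution
#'
#' Computes population-convention moments, an equal-width histogram, and the
#' fraction of genes within three sigma of the mean for one stage and one
#' amplitude definition. For normally distributed amplitudes that fraction is
#' about 0.997; a markedly lower value warns that the 3-sigma cutoff is being
#' applied to a heavy-tailed or skewed distribution.
#'
#' @param amps An [amplitude_profile()].
#' @param definition `"signed"` or `"absolute"`.
#' @param stage One of the disease stages (`incipient`, `moderate`,
#'   `severe`).
#' @param n_bins Number of equal-width histogram bins over the data range
#'   (default 60).
#' @param normality If `TRUE`, attach the [dagostino_k2()] omnibus statistic.
#' @return An object of class `amplitude_summary`: list with `stage`,
#'   `definition`, `n`, `mean`, `variance`, `sigma`, `skewness`,
#'   `excess_kurtosis`, `breaks`, `counts`, `fraction_within_3sigma`, and
#'   optionally `normality`.
#' @export
summarize_amplitudes <- function(amps, definition = c("signed", "absolute"),
                                 stage = disease_stages(), n_bins = 60,
                                 normality = FALSE) {
  stopifnot(inherits(amps, "amplitude_profile"))
  definition <- match.arg(definition)
  stage <- match.arg(stage)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1)
    abort_validation("`n_bins` must be a positive integer")
  x <- amps[[definition]][, stage]
  if (!length(x))
    abort_validation("empty amplitude vector")

  mom <- pop_moments(x)
  sigma <- sqrt(mom$variance)
  rng <- range(x)
  breaks <- if (rng[1L] == rng[2L]) {
    c(rng[1L] - 0.5, rng[1L] + 0.5)
  } else {
    seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  frac <- if (sigma > 0) mean(abs(x - mom$mean) <= 3 * sigma) else 1

  out <- c(list(stage = stage, definition = definition, n = length(x)),
           mom,
           list(sigma = sigma, breaks = h$breaks, counts = h$counts,
                fraction_within_3sigma = frac))
  if (normality) out$normality <- dagostino_k2(x)
  structure(out, class = "amplitude_summary")
}

#' @export
print.amplitude_summary <- function(x, ...) {
  cat(sprintf("amplitude summary: %s / %s (n = %d)\n",
              x$definition, x$stage, x$n))
  cat(sprintf("  mean %.4g, variance %.4g, skewness %.3g, excess kurtosis %.3g\n",
              x$mean, x$variance, x$skewness, x$excess_kurtosis))
  cat(sprintf("  fraction within 3 sigma: %.4f\n", x$fraction_within_3sigma))
  if (!is.null(x$normality))
    cat(sprintf("  omnibus K2 = %.3g (p = %.3g)\n",
                x$normality$statistic, x$normality$p_value))
  invisible(x)
}

#' @export
plot.amplitude_summary <- function(x, ...) {
  mids <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2
  graphics::plot(mids, x$counts, type = "h", lwd = 3,
                 xlab = sprintf("%s amplitude (%s)", x$definition, x$stage),
                 ylab = "genes", ...)
  invisible(x)
}

#' Summaries for every stage and both amplitude definitions
#'
#' @inheritParams summarize_amplitudes
#' @return Named list of [summarize_amplitudes()] results, keyed
#'   `<definition>.<stage>`.
#' @export
diagnose_amplitudes <- function(amps, n_bins = 60, normality = FALSE) {
  combos <- expand.grid(definition = c("signed", "absolute"),
                        stage = disease_stages(),
                        stringsAsFactors = FALSE)
  out <- Map(function(d, s) summarize_amplitudes(amps, d, s, n_bins, normality),
             combos$definition, combos$stage)
  names(out) <- paste(combos$definition, combos$stage, sep = ".")
  out
}

#' Write amplitude summaries (and optionally thresholds) as JSON
#'
#' @param summaries List of `amplitude_summary` objects, e.g. from
#'   [diagnose_amplitudes()].
#' @param path Output path for the JSON document.
#' @param thresholds Optional [amplitude_thresholds()] to embed.
#' @return Invisibly, `path`.
#' @export
write_diagnostics_json <- function(summaries, path, thresholds = NULL) {
  payload <- lapply(summaries, unclass)
  if (!is.null(thresholds))
    payload <- list(thresholds = as.data.frame(thresholds),
                    summaries = payload)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_io("cannot write diagnostics JSON to ", path,
             " (", conditionMessage(ok), ")")
  invisible(path)
}

#' Save amplitude histograms as PNG files
#'
#' One file per stage and definition, named
#' `amplitude_<definition>_<stage>.png`.
#'
#' @inheritParams diagnose_amplitudes
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
save_amplitude_plots <- function(amps, dir, n_bins = 60) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summaries <- diagnose_amplitudes(amps, n_bins)
  paths <- vapply(summaries, function(s) {
    p <- file.path(dir, sprintf("amplitude_%s_%s.png", s$definition, s$stage))
    grDevices::png(p, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    plot(s, main = sprintf("%s amplitudes, %s stage", s$definition, s$stage))
    p
  }, character(1L))
  invisible(paths)
}
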