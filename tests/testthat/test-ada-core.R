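test_that("column centering matches hand-computed deviations", {
  values <- matrix(c(1, 2, 3, 3, 4, 5), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  sm <- staged_matrix(values, c(s1 = "control", s2 = "control"))
  S <- column_center(sm, "control")$values
  expect_equal(unname(S), matrix(c(-1, 0, 1, -1, 0, 1), nrow = 3))
  expect_equal(unname(colSums(S)), c(0, 0))
  # overall deviation averages the centered rows
  D <- overall_deviation(column_center(sm, "control"))
  expect_equal(unname(D), c(-1, 0, 1))
})

test_that("centering a constant column yields zeros and is idempotent", {
  values <- cbind(rep(4.2, 5), rnorm(5, 8))
  dimnames(values) <- list(paste0("g", 1:5), c("s1", "s2"))
  sm <- staged_matrix(values, c(s1 = "control", s2 = "control"))
  S <- column_center(sm, "control")$values
  expect_equal(unname(S[, "s1"]), rep(0, 5))

  # idempotence: centering already-centered data is the identity
  sm2 <- staged_matrix(S, c(s1 = "control", s2 = "control"))
  S2 <- column_center(sm2, "control")$values
  expect_equal(S2, S, tolerance = 1e-12)

  expect_error(column_center(sm, "severe"), "not present",
               class = "adascreen_validation_error")
})

test_that("deviations and overall deviations agree with a scalar-loop oracle", {
  x <- make_staged(n_genes = 6, seed = 11)
  ref <- oracle_screen(x$values, x$stages)
  for (s in ada_stages()) {
    S <- column_center(x, s)$values
    cols <- which(x$stages == s)
    for (jj in seq_along(cols)) {
      j <- cols[jj]
      exp_col <- x$values[, j] - sum(x$values[, j]) / nrow(x$values)
      expect_equal(unname(S[, jj]), unname(exp_col), tolerance = 1e-12)
    }
  }
  expect_equal(deviation_profile(x), ref$D, tolerance = 1e-12)
})

test_that("amplitudes are control-relative differences with |A| as magnitude", {
  D <- rbind(g1 = c(0.5, 1.0, 2.0, 2.5),
             g2 = c(1.0, 1.0, 1.0, 1.0),
             g3 = c(0.5, 0.0, -1.0, -1.5))
  colnames(D) <- ada_stages()
  A <- signed_amplitude(D)
  expect_equal(unname(A["g1", ]), c(0.5, 1.5, 2.0))
  expect_equal(unname(A["g2", ]), c(0, 0, 0))
  expect_equal(unname(A["g3", ]), c(-0.5, -1.5, -2.0))
  expect_equal(absolute_amplitude(D), abs(A))

  # swapping control with a disease stage flips the sign of that amplitude
  Dsw <- D[, c("incipient", "control", "moderate", "severe")]
  colnames(Dsw) <- ada_stages()
  expect_equal(signed_amplitude(Dsw)[, "incipient"], -A[, "incipient"])

  ap <- amplitude_profile(D)
  expect_true(all(ap$absolute >= 0))
  expect_identical(ap$absolute, abs(ap$signed))
})

test_that("sigma estimation uses the raw-moment identity", {
  expect_equal(estimate_sigma(c(1, 1, 1)), list(mean = 1, sigma = 0))
  s <- estimate_sigma(c(0, 0, 0, 4))
  expect_equal(s$mean, 1)
  expect_equal(s$sigma, sqrt(3))

  # shift invariance and absolute-scale equivariance
  set.seed(9)
  x <- rnorm(50)
  base <- estimate_sigma(x)$sigma
  expect_equal(estimate_sigma(x + 17.3)$sigma, base, tolerance = 1e-10)
  expect_equal(estimate_sigma(x * -2.5)$sigma, 2.5 * base, tolerance = 1e-10)

  # sample convention rescales by n/(n-1) under the square root
  expect_equal(estimate_sigma(x, "sample")$sigma,
               base * sqrt(50 / 49), tolerance = 1e-10)
  expect_error(estimate_sigma(numeric(0)), "empty",
               class = "adascreen_validation_error")
})

test_that("thresholds are per stage and exactly multiplier * sigma", {
  x <- make_staged(n_genes = 40, seed = 2)
  amps <- amplitude_profile(deviation_profile(x))
  thr <- amplitude_thresholds(amps, multiplier = 3)
  expect_equal(thr$stage, c("incipient", "moderate", "severe"))
  expect_identical(thr$cutoff_strict, 3 * thr$sigma_signed)
  expect_identical(thr$cutoff_relaxed, 3 * thr$sigma_absolute)
  expect_true(all(thr$sigma_signed >= 0 & thr$sigma_absolute >= 0))
  expect_error(amplitude_thresholds(amps, multiplier = -1),
               class = "adascreen_validation_error")
})

test_that("strict rule requires the 3-sigma gate in every stage plus a monotone trend", {
  # 99 null genes with tiny amplitudes, one plant far outside every gate
  set.seed(4)
  m <- 100
  D <- cbind(control = rnorm(m, 0, 0.01), incipient = rnorm(m, 0, 0.01),
             moderate = rnorm(m, 0, 0.01), severe = rnorm(m, 0, 0.01))
  rownames(D) <- sprintf("g%03d", seq_len(m))
  D["g100", ] <- c(0, 10, 12, 15)  # ~ +10/12/15 sigma amplitudes, increasing
  amps <- amplitude_profile(D)
  thr <- amplitude_thresholds(amps)
  calls <- strict_3sigma_candidates(D, amps, thr)
  expect_equal(calls$gene_id, "g100")
  expect_equal(calls$direction, "up")
  expect_equal(calls$criterion, "strict3sigma")

  # exceeding the gate in two stages out of three is not enough
  D2 <- D
  D2["g100", ] <- c(0, 10, 12, 0.005)
  amps2 <- amplitude_profile(D2)
  calls2 <- strict_3sigma_candidates(D2, amps2, amplitude_thresholds(amps2))
  expect_false("g100" %in% calls2$gene_id)

  # an all-zero-amplitude gene among genes with spread is never called
  expect_false("g001" %in% calls$gene_id)
})

test_that("relaxed criteria recover planted monotone genes with exclusive directions", {
  sim <- simulate_expression(synthetic_design(n_genes = 1000, n_up = 10,
                                              n_down = 10, seed = 77))
  res <- run_ada(sim$matrix, method = "relaxed")
  calls <- res$candidates
  expect_setequal(unique(calls$criterion), c("criterion1", "criterion2"))
  expect_true(all(calls$direction[calls$criterion == "criterion1"] == "up"))
  expect_true(all(calls$direction[calls$criterion == "criterion2"] == "down"))
  # no gene can satisfy both criteria
  expect_false(any(duplicated(calls$gene_id)))
  stats <- recovery_stats(calls, sim$truth)
  expect_gte(stats$precision, 0.95)
  expect_gte(stats$recall, 0.95)

  # strict calls on the same data are a subset of the relaxed calls here:
  # sigma* <= sigma and the signed-amplitude mean is near zero
  both <- run_ada(sim$matrix, method = "both")
  thr <- both$thresholds
  expect_true(all(thr$sigma_absolute <= thr$sigma_signed))
  expect_true(all(abs(thr$mean_signed) < 0.1 * thr$sigma_signed))
  strict_ids <- both$candidates$gene_id[both$candidates$criterion == "strict3sigma"]
  relaxed_ids <- both$candidates$gene_id[both$candidates$criterion != "strict3sigma"]
  expect_true(all(strict_ids %in% relaxed_ids))
})

test_that("run_ada removes per-sample offsets and keeps rule outputs separate", {
  # four stage blocks identical gene-wise up to per-sample constant offsets
  set.seed(13)
  gene_part <- rnorm(30, 8)
  counts <- default_counts
  n <- sum(counts)
  values <- matrix(gene_part, 30, n) +
    matrix(rep(rnorm(n, 0, 2), each = 30), 30, n)
  dimnames(values) <- list(paste0("g", 1:30), paste0("s", 1:n))
  sm <- staged_matrix(values, setNames(rep(names(counts), counts),
                                       paste0("s", 1:n)))
  res <- run_ada(sm)
  expect_equal(max(abs(res$amplitudes$signed)), 0, tolerance = 1e-10)
  expect_equal(nrow(res$candidates), 0L)

  # method = "both" reports strict and criterion calls separately
  sim <- simulate_expression(synthetic_design(n_genes = 300, n_up = 3,
                                              n_down = 3, seed = 5))
  res2 <- run_ada(sim$matrix, method = "both")
  expect_true(all(res2$candidates$criterion %in%
                    c("strict3sigma", "criterion1", "criterion2")))
  strict <- res2$candidates[res2$candidates$criterion == "strict3sigma", ]
  relaxed <- res2$candidates[res2$candidates$criterion != "strict3sigma", ]
  expect_gt(nrow(strict), 0)
  expect_gt(nrow(relaxed), 0)

  # a missing stage is reported by name
  bad <- values[, 1:4]
  smap <- setNames(rep(c("control", "incipient"), each = 2), paste0("s", 1:4))
  expect_error(run_ada(staged_matrix(bad, smap)), "moderate, severe",
               class = "adascreen_validation_error")
})

test_that("adding a constant to any single sample column changes nothing", {
  x <- make_staged(n_genes = 25, seed = 21)
  base <- run_ada(x)
  shifted <- x$values
  shifted[, 4] <- shifted[, 4] + 123.4
  res <- run_ada(staged_matrix(shifted, x$stages))
  expect_equal(res$profile, base$profile, tolerance = 1e-9)
  expect_equal(res$thresholds$sigma_signed, base$thresholds$sigma_signed,
               tolerance = 1e-9)
  expect_identical(res$candidates$gene_id, base$candidates$gene_id)
})
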