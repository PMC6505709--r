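# Independent straight-loop reimplementation of the whole screen, kept free
# of any package internals (scalar loops only). Used as the reference the
# vectorized pipeline must agree with on small matrices.

oracle_screen <- function(values, stages, multiplier = 3) {
  stage_names <- c("control", "incipient", "moderate", "severe")
  disease <- stage_names[-1]
  m <- nrow(values)

  # deviations and per-stage overall deviations
  D <- matrix(NA_real_, m, 4, dimnames = list(rownames(values), stage_names))
  for (s in stage_names) {
    cols <- which(stages == s)
    for (i in seq_len(m)) {
      acc <- 0
      for (j in cols) {
        colmean <- 0
        for (k in seq_len(m)) colmean <- colmean + values[k, j]
        colmean <- colmean / m
        acc <- acc + (values[i, j] - colmean)
      }
      D[i, s] <- acc / length(cols)
    }
  }

  # signed and absolute amplitudes
  A <- matrix(NA_real_, m, 3, dimnames = list(rownames(values), disease))
  for (t in disease) for (i in seq_len(m)) A[i, t] <- D[i, t] - D[i, "control"]
  Aabs <- abs(A)

  # per-stage moments, population convention
  mean_signed <- sigma_signed <- sigma_abs <- setNames(numeric(3), disease)
  for (t in disease) {
    s1 <- 0; s2 <- 0; a2 <- 0; a1 <- 0
    for (i in seq_len(m)) {
      s1 <- s1 + A[i, t];    s2 <- s2 + A[i, t]^2
      a1 <- a1 + Aabs[i, t]; a2 <- a2 + Aabs[i, t]^2
    }
    mean_signed[t] <- s1 / m
    sigma_signed[t] <- sqrt(max(s2 / m - (s1 / m)^2, 0))
    sigma_abs[t] <- sqrt(max(a2 / m - (a1 / m)^2, 0))
  }

  up <- down <- strict_up <- strict_down <- character(0)
  for (i in seq_len(m)) {
    inc <- D[i, "control"] < D[i, "incipient"] &&
      D[i, "incipient"] < D[i, "moderate"] &&
      D[i, "moderate"] < D[i, "severe"]
    dec <- D[i, "control"] > D[i, "incipient"] &&
      D[i, "incipient"] > D[i, "moderate"] &&
      D[i, "moderate"] > D[i, "severe"]

    strict_gate <- TRUE
    relaxed_gate <- TRUE
    for (t in disease) {
      if (!(abs(A[i, t] - mean_signed[t]) > multiplier * sigma_signed[t]))
        strict_gate <- FALSE
      if (!(Aabs[i, t] > multiplier * sigma_abs[t]))
        relaxed_gate <- FALSE
    }
    g <- rownames(values)[i]
    if (strict_gate && inc) strict_up <- c(strict_up, g)
    if (strict_gate && dec) strict_down <- c(strict_down, g)
    if (relaxed_gate && inc) up <- c(up, g)
    if (relaxed_gate && dec) down <- c(down, g)
  }

  list(D = D, A = A, Aabs = Aabs,
       mean_signed = mean_signed, sigma_signed = sigma_signed,
       sigma_abs = sigma_abs,
       strict_up = strict_up, strict_down = strict_down,
       criterion1 = up, criterion2 = down)
}
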