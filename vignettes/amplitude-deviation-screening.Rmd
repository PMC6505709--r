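---
title: "Amplitude deviation screening: model, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude deviation screening: model, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adascreen)
```

## The model

`adascreen` screens a log-scale expression matrix whose samples belong to
four ordered severity groups (control, incipient, moderate, severe) for
genes that progressively escape their controlled expression range. The
underlying picture is homeostatic: in health, regulation keeps each gene's
expression within a band; in progressive disease, a small set of genes
drifts out of that band, and the drift grows with severity.

Three ingredients operationalise this:

* **Column centering.** Raw log intensities from different hybridisations
  differ by sample-level additive offsets (labelling efficiency, scanner
  gain). Subtracting each column's across-gene mean,
  $S(i,j) = T(i,j) - \tfrac1m\sum_i T(i,j)$, makes columns comparable.
  This is the only normalisation applied: the method assumes inputs are
  already log-transformed, and per-sample additive offsets are exactly the
  artefact centering removes. Anything multiplicative on the log scale
  (scale differences between arrays) is *not* removed — a stated
  limitation, see below.
* **Overall deviations and amplitudes.** Averaging deviations over the
  $n_t$ samples of a stage, $D_t(i) = \tfrac1{n_t}\sum_j S(i,j)$, damps
  per-sample measurement error; the amplitude
  $A_t(i) = D_t(i) - D_{ctrl}(i)$ then measures how far stage $t$ has moved
  the gene relative to control, in log-intensity units. The absolute
  variant is $A'_t(i) = |A_t(i)|$.
* **The 3σ gate plus a monotone trend.** Amplitudes across genes are
  approximately normal when most genes are null, so a gene outside three
  standard deviations of the amplitude distribution in *every* disease
  stage is an outlier by the 99.7% rule. The trend requirement — overall
  deviations strictly increasing or strictly decreasing across the four
  stages — ties the outlying amplitude to disease progression rather than
  to a one-stage artefact.

Two selection rules are exposed. The *strict* rule centers signed
amplitudes on their mean and gates on $|A_t(i) - \bar A_t| > 3\sigma_t$.
The *relaxed* criteria gate the magnitudes on $A'_t(i) > 3\sigma^*_t$,
where $\sigma^*_t$ is estimated from the absolute amplitudes. Folding a
roughly symmetric distribution onto the positive half-line shifts its mean
above zero and shrinks its spread, so $\sigma^* \le \sigma$ and the relaxed
cutoff admits more genes; the monotone gate (criterion 1 up, criterion 2
down) keeps direction consistency. On data where the signed amplitudes are
near-symmetric about zero, every strict call also passes the relaxed gate —
the test suite checks this containment on simulated studies.

## Conventions and numerical choices

Several points of the procedure admit more than one reading; the package
fixes them as follows and surfaces each as a configuration argument so the
alternative can be explored without code changes.

* **Absolute amplitudes.** The magnitude definition $A' = |A|$ is adopted
  for the relaxed rule because only a folded (positive-mean) statistic
  yields the smaller spread that motivates the relaxation;
  `relaxed_definition = "signed"` instead gates $|A_t|$ against the
  signed-amplitude sigma.
* **σ convention.** $\sigma = \sqrt{E[x^2]-E[x]^2}$ with division by $N$
  (the population convention, i.e. the raw-moment identity as written);
  `convention = "sample"` switches to $N-1$ for sensitivity analysis. At
  genome scale the difference is negligible; the flag exists so that can be
  demonstrated rather than assumed.
* **Per-stage thresholds.** $\sigma_t$ is estimated separately for
  incipient, moderate, and severe, because amplitude spread grows with
  severity; a single pooled threshold would over-call the severe stage and
  under-call the incipient one.
* **Mean centering in the strict rule.** The gate subtracts the empirical
  amplitude mean $\bar A_t$ even though it is typically near zero —
  subtracting it always is cheap and exact.
* **Strict inequalities, ties fail.** The monotone-trend comparisons use
  `<` and `>` literally. Exact ties are measure-zero for continuous
  intensities; a gene with a tied pair of overall deviations is not called.
* **Multiplier.** The cutoff multiplier defaults to 3 (the three-sigma
  rule) and is a free parameter (`multiplier`), since 3 is a convention,
  not an estimate.
* **Degenerate inputs.** Stages with fewer than two samples are rejected at
  container construction (per-stage averaging of a single sample would make
  "overall" deviation a misnomer and sigma estimates meaningless).
  Missing values are rejected by default; `na_action = "drop"` discards
  affected genes and reports the count. Silent imputation is deliberately
  not offered because it would distort the sigma estimates that the
  cutoffs are built from. Constant amplitude vectors give $\sigma = 0$, an
  empty outlier set, and `NA` skewness/kurtosis in the diagnostics.
* **Probe sets are the unit.** Genes are never deduplicated by symbol:
  distinct probe sets mapping to one gene are screened (and reported)
  separately.

## What the synthetic generator emulates — and what it does not

`synthetic_design()` / `simulate_expression()` generate
$T(i,j) = b_i + \delta(i, \text{stage}(j)) + o_j + \varepsilon_{ij}$: a
per-gene baseline $b_i \sim U(5, 12)$ log2 units (the realistic intensity
range of a log2 microarray), a per-sample offset $o_j \sim N(0, 0.3^2)$
(the artefact column centering removes), Gaussian observation noise with
`noise_sd = 0.25` log2 units (a typical residual scale for log2
intensities), and planted stage shifts. Planted "up" genes gain
`effect_profile` $= (8, 10, 12) \times$ `noise_sd` $= (2.0, 2.5, 3.0)$
log2 units in the incipient/moderate/severe stages; "down" genes lose the
same amounts. The default layout is 9/7/8/7 samples across the four
stages, the shape of a typical staged microarray cohort. A Student-t noise
option (`noise = "t"`) produces heavy tails for stress-testing the 3σ gate.

The generator is deliberately simpler than real array data: no
probe-level (multiplicative/intensity-dependent) noise, no batch structure
beyond per-sample offsets, no correlation between genes, and planted
trends that are exactly monotone in expectation. Passing the recovery and
null-control tests therefore shows that the implementation computes the
statistic correctly and that the gate behaves as designed under its own
assumptions — it does not show that 3σ outliers in a real cohort are
disease genes, nor how the method behaves under gene–gene correlation or
intensity-dependent variance.

Two validation properties are worth spelling out. First, on pure-null data
the conjunction of three 3σ exceedances *and* a strict four-stage monotone
chain has very low null probability, so false-call rates sit far below 1%.
Second, the gate is a gate, not a trend test: plants with monotone shifts
of only $0.5 \times$ `noise_sd` are mostly *not* called (recall below
0.2), because amplitude magnitude, not monotonicity alone, is the primary
filter.

## Validation design and problem sizes

The test suite validates the vectorized pipeline against an independent
scalar-loop reimplementation on matrices of up to 20 genes (agreement to
1e-12 on all intermediates, exact agreement of candidate sets); checks the
99.7% coverage of the 3σ band on $10^5$ standard-normal draws (±0.001);
runs 20-seed null-control and recovery experiments at 1,000 genes with the
default 9/7/8/7 layout (false-call rate < 1%, precision and recall ≥ 0.95
for 8–12× noise plants); and verifies end-to-end that arbitrary per-sample
constants change no candidate call. These sizes keep each experiment
comfortably powered for the stochastic bounds while the whole suite runs
in seconds. The same quantities are recomputed from scratch by
`scripts/acceptance.R`, seeded entirely from its `--seed` argument.

Reproducing a published screen from a public repository requires only the
series-matrix file and a stage map:

```r
## not run: paths to a downloaded GEO series matrix and a hand-made stage map
# x <- read_series_matrix("GSExxxx_series_matrix.txt", "stages.tsv")
# res <- run_ada(x, method = "both")
# res$thresholds          # per-stage sigma and cutoffs
# table(res$candidates$criterion, res$candidates$direction)
```

Sample identifiers are matched after stripping internal whitespace, so
headers printed as `GSM 21215` pair with a stage-map entry `GSM21215`.

## Known limitations

* Column centering removes additive per-sample offsets only; it does not
  correct scale differences between samples or intensity-dependent bias.
  Inputs should be comparably preprocessed log intensities.
* The 3σ gate presumes the amplitude distribution is dominated by null
  genes. In a cohort where a large fraction of the genome shifts, the
  sigma estimates inflate and the screen becomes conservative.
* No multiple-testing correction or permutation null is provided — the 3σ
  rule *is* the error control, with the diagnostics module there to check
  its normality premise (`summarize_amplitudes()`, optionally with the
  D'Agostino-Pearson omnibus statistic via `normality = TRUE`).
* The monotone gate is strict: a gene flat between two disease stages is
  not called even with enormous amplitudes.
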