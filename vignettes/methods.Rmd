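---
title: "Methods: the expression screen, its gate, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the expression screen, its gate, and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoscreen)
```

## The screening model

`oncoscreen` implements the analysis conventions of the historical Oncomine
cancer microarray compendium as a reusable, testable pipeline. The unit of
analysis is one *study*: a genes × samples matrix of pre-processed expression
intensities with a two-group annotation, cancer vs matched normal tissue.
Per study and per gene the screen computes four statistics:

1. **Student's t.** A pooled-variance two-sample t-test with
   \(n_1 + n_2 - 2\) degrees of freedom, two-sided. The test is applied to
   log2-transformed intensities: log-scale testing is the microarray norm and
   stabilises the strong mean–variance coupling of intensity data, while the
   published convention specifies only that *fold change* is linear. Both
   choices are switchable (`log2_transform = FALSE` tests the raw values;
   `var_equal = FALSE` gives Welch's form). The t-test assumes approximate
   normality of the log2 values within groups — exact for the log-normal
   simulator below, approximate for real arrays.
2. **Signed linear fold change.** \(r = \bar{x}_{\text{cancer}} /
   \bar{x}_{\text{normal}}\) on the linear scale, reported as \(r\) when
   \(r \ge 1\) and \(-1/r\) otherwise, so the magnitude is always ≥ 1 and the
   sign carries the direction. This requires strictly positive group means;
   a non-positive mean flags the fold change as undefined (`NA`) rather than
   erroring the study.
3. **Gene rank and percentile.** Genes are ranked by p-value within the
   study (rank 1 = smallest). The gene rank percentile is
   \(\lceil 100 R / N \rceil\) as an integer: with the ceiling, rank 1 of
   14,000 prints as percentile 1, and "top 10%" is exactly `percentile <= 10`.
4. **Q-value.** The rank-based FDR correction \(Q = N P / R\). Because
   \(N/R \ge 1\), \(Q \ge P\) always. The raw formula is the default, matching
   the published definition; `monotone = TRUE` applies the step-up running
   minimum and the cap at 1, which makes Q identical to the
   Benjamini–Hochberg adjusted p-value (the test suite verifies this against
   `stats::p.adjust`).

### Direction and ranking: one ranking per study

The screen uses a single two-sided ranking over all measured genes; the
over/under direction is a label derived from the fold-change sign. The
alternative — separate over- and under-expression rankings from one-sided
tests — would halve each gene's effective N; the published material does not
adjudicate between the two, and the single-ranking convention was chosen
because the printed percentiles are consistent with one ranking per dataset.
For the same reason the gate uses the raw p-value, not Q: the threshold is
stated on p, and Q is reported but never gated on.

## The threshold gate

An analysis (one gene in one study) is *above threshold* when it satisfies
all three criteria jointly (Boolean AND):

| criterion | default | boundary |
|---|---|---|
| p-value | `p_max = 0.05` | strict `<` |
| linear fold change | `fold_min = 2` | inclusive on the magnitude, `|fc| >= 2` |
| gene rank percentile | `percentile_max = 10` | inclusive, after ceiling |

The boundary conventions resolve genuine ambiguities in the source
conventions ("fold change > 2" alongside "a fold change of 2 and greater"):
the inclusive fold reading is consistent with reported borderline analyses
such as −2.071 and 2.05, and the inclusive percentile reading with reported
rows at percentile exactly 10. The p boundary stays strict as stated.
Gating is monotone in each criterion separately — loosening any cut-off can
only grow the record set — and every emitted record re-passes the gate by
construction; both properties are tested.

## Cross-study summaries

**Comparative meta-analysis.** Per (gene, cancer subtype), the median
p-value and median gene rank are taken over *all* \(n\) datasets in which
the gene was measured, not only the above-threshold ones; pairs with
\(n \ge 5\) are eligible (`min_datasets = 5`; the "more than five (n≥5)"
self-contradiction is resolved in favour of the parenthetical, which matches
reported n = 5 summaries). Medians over even \(n\) are the mean of the two
central order statistics, so half-integer median ranks occur. Median rank
uses the raw integer ranks \(R\), not percentiles, keeping its magnitude
comparable to the platform size. An eligible pair with median p ≤ 0.05 is
called significant. Note the multiplicity caveat: the 0.05 level applies per
pair, with no correction across the gene × subtype grid — faithful to the
original convention, and the reason the screen is a survey, not a discovery
procedure with controlled family-wise error.

**Fold aggregation.** Mean ± SEM of the absolute fold changes of the
above-threshold analyses, per (gene, subtype, direction); SEM uses the
\(k-1\) sample standard deviation over \(\sqrt{k}\) and is undefined
(`NA`) for \(k = 1\). Values are stored at full precision; rounding to two
decimals is a display concern confined to the writers.

**Gene summary matrices.** Per direction, the gene × cancer-type matrix of
the best (lowest) percentile among above-threshold analyses, binned
{≤1, ≤5, ≤10} → {1%, 5%, 10%} for heatmap display. The three-bin scheme is a
display convention; the underlying matrices keep the raw best percentiles.

## The simulator: what it emulates, and what it does not

`simulate_studies()` stands in for the multi-study corpus the screen was
designed against. Its defaults are the study conditions of that corpus as
far as they are known, plus explicit conventions where they are not:

| parameter | default | rationale |
|---|---|---|
| `genes_per_platform` | 14000 | the corpus averaged approximately 14,000 genes per platform |
| `studies_per_subtype` | 7 | exercises the n ≥ 5 meta-analysis rule with dropout |
| `n_subtypes` | 3 | small multi-subtype corpus; free choice |
| `samples_per_group` | 10 | typical microarray cohort; group sizes were never published |
| `planted_fraction` | 0.01 | a minority of genes truly differential |
| `planted_log2_effect` | 1.5 | linear fold 2^1.5 ≈ 2.83, comfortably past the 2-fold gate |
| `within_group_log2_sd` | 0.5 | typical log2 intensity noise |
| `baseline_log2_mean_range` | [4, 12] | the usual dynamic range of array intensities |
| `platform_dropout` | 0.05 | per-study gene-panel differences |
| `effect_sign_mix` | 0.5 | over- and under-expression equally likely |

Intensities are log-normal: \(x = 2^{\mu_g + \delta_g [\text{cancer}] +
\varepsilon}\) with per-gene, per-study baselines \(\mu_g\) (platforms
differ), \(\varepsilon \sim N(0, \sigma)\), and \(\delta_g = \pm 1.5\) for
planted genes, direction shared across the studies of a subtype. Because the
same log-normal noise factor multiplies both groups, the expected linear
fold of a planted gene is exactly \(2^{\delta}\) — the Monte-Carlo test at
1000 samples/group checks this closed form. A per-study effect-heterogeneity
knob (`effect_jitter_sd`) exists but defaults to 0: homogeneous effects.

Reproducibility discipline: every study (and each subtype's truth draw) uses
its own seed derived from the collection seed and a fixed counter, so
generation is independent of realisation order and bit-identical across
runs; the global RNG state is restored afterwards.

What the simulator does **not** model: probe-level effects, batch and
normalisation artefacts, correlated genes, heavy-tailed outliers,
between-study effect heterogeneity (unless enabled), and unbalanced group
sizes. Passing recovery tests on this generator therefore demonstrates that
the pipeline's statistics and gating are implemented correctly, not that the
gate has any particular operating characteristic on real arrays.

## Numerical and degenerate-input choices

- Ties in p are broken by lexicographic gene identifier — deterministic
  across runs and platforms.
- Two identical constant groups give t = 0, p = 1 (no evidence, not an
  error); a zero pooled variance with different means gives p clamped to the
  smallest positive double. p-values are clamped to (0, 1].
- A gene left with fewer than two finite values in a group by missingness is
  excluded from that study's N — it was not analysed on that platform.
- All internal math is double precision; tables are written with shortest
  round-trip number formatting so `read(write(x)) == x` exactly.
- Input matrices declared log2 are exponentiated on load: one code path for
  all fold-change math.

## Problem sizes used by the test suite

The suite validates the statistics at desk scale: null calibration uses one
study of 2000 genes at 10+10 samples (binomial 99% band around the nominal
5%); gate/percentile analytics use 100 random vectors of up to 1000 p-values
against brute-force oracles; parameter recovery runs one full-default corpus
(3 subtypes × 7 studies × 14,000 genes) plus twenty single-subtype
replicates for the meta-analysis significance rate. These sizes were chosen
so the full suite runs in about a minute while keeping every statistical
check at its stated strength.

## Interface note

The screen is exposed as R functions (`run_pipeline()` and the per-stage
verbs) rather than a shell executable: inputs and outputs are plain TSV/YAML
files and tibbles, and a scripted run is a three-line Rscript. The
`simulate` / `gate` / `meta` / `summary-matrix` stages correspond one-to-one
to `simulate_studies()` + `write_collection()`, `filter_above_threshold()`,
`meta_summarize()` + `aggregate_folds()`, and `build_summary_matrix()`.

## Known limitations

- No moderated (empirical-Bayes) t statistics or permutation p-values; the
  screen deliberately reproduces the plain Student's t convention.
- No between-study random-effects model or heterogeneity statistics; the
  meta-analysis is medians only, by design.
- No microarray normalisation: inputs are assumed pre-processed,
  positive-valued intensities.
- The significance call on the median p-value is a heuristic summary, not a
  combined-evidence test (it is not a Fisher or Stouffer combination), and
  inherits the per-pair multiplicity caveat above.
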