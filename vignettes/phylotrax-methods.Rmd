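---
title: "Evolutionary transcriptomics with phylotrax: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary transcriptomics with phylotrax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotrax)
```

## The model

phylotrax quantifies how the *evolutionary composition* of a transcriptome
changes across development. Each gene $i$ carries an integer stratum
$s_i \in \{1, \dots, K\}$ — a phylostratum (gene age rank, 1 = oldest), a
tau-stratum (expression-specificity decile) or a divergence-stratum
(dN/dS decile, 1 = strongest purifying selection) — and each developmental
stage $t$ carries expression levels $e_{it}$ (TPM after preparation). The
index at stage $t$ is the expression-weighted mean stratum

$$\mathrm{Index}_t \;=\; \sum_i \frac{s_i \, e_{it}}{\sum_j e_{jt}},$$

which is the transcriptome age index (TAI) under phylostrata, the
transcriptome specificity index (TSI) under tau-strata and the
transcriptome divergence index (TDI) under dN/dS deciles. A lower TAI
marks a transcriptome dominated by evolutionarily older genes; a dip of
the TAI at mid-development is the transcriptomic hourglass, and the stage
at the minimum is the waist (phylotypic period). All three indices are
the *same* weighted mean computed by one engine, `weighted_index()`; only
the `StratumMap` changes, and the test suite holds the engine to three
independently coded naive oracles at $10^{-10}$ relative error.

Per-gene additive contributions ("pTAI"),
$p_{it} = s_i e_{it} / \sum_j e_{jt}$, decompose each stage's index
exactly (`contribution_matrix()`; column sums reproduce the profile to
machine precision), and the dominant contributors at a stage are
selected by an elbow rule on the sorted contribution curve.

## Data preparation

The pipeline order is fixed: **filter → collapse → transform**.

1. *Filter*: genes with mean TPM across **all samples** below 2 are
   removed, on untransformed TPM. The threshold is a tunable
   (`min_tpm`, unitless TPM) and 2 is the default.
2. *Collapse*: replicates are collapsed to one column per stage by the
   median (midpoint for even replicate counts), which is robust to
   outlying libraries.
3. *Transform*: square root (the default used in all downstream
   analyses here), $\log_2(\mathrm{TPM}+1)$, or a within-stage rank
   transform with averaged ties. Transforms tame the dominance of very
   highly expressed genes in the weighted mean. A regularized-log
   transform is deliberately **not** offered: it is a shrinkage
   estimator tied to count-model machinery, whereas this pipeline takes
   TPM tables as input; `log2p1` is the documented substitute and
   `transform_expression()` rejects `"rlog"` with a pointer here. Double
   transformation is rejected via the matrix's `transform_tag`.

Tau (expression specificity) for gene $i$ over $N$ stages is
$\tau_i = \sum_t (1 - \hat e_{it}) / (N - 1)$ with
$\hat e_{it} = e_{it} / \max_t e_{it}$: 0 for uniform expression, 1 for
single-stage expression. All-zero genes have undefined tau and are
reported in a side list, never silently zeroed. Tau is computed on the
same stage set as the index that consumes it. Decile stratification is
rank-based (stratum $= \lceil 10\,r_i/n \rceil$), guaranteeing
near-equal bins; ties are split by stable gene-id order, a heavy tie
mass at the minimum (e.g. many exact-zero dN/dS values from recently
diverged species pairs) triggers a warning, and an all-constant input
degenerates to a single stratum. Gene ages and dN/dS ratios arrive as
tables; isoforms are collapsed by the oldest-isoform rule (minimum
stratum / minimum ratio), and contamination-flagged rows are dropped.

## Uncertainty and the permutation tests

**Bootstrap SD.** Gene-level classical bootstrap: genes are resampled
with replacement and the full profile recomputed; the per-stage SD over
`n_boot` resamples (default 50,000) is reported. The implementation
draws multinomial resampling counts (`rmultinom`) and evaluates the
profiles by matrix products in chunks — distributionally identical to
index resampling, but vectorised. With a fixed seed the result is
bit-reproducible.

**Permutation null.** All three shape tests share one null: the
stratum-to-gene assignment is permuted (expression fixed) and the full
profile recomputed per permutation. Statistics:

* flat-line — the variance of the profile across stages (two-sided
  departure from constancy);
* reductive hourglass — $D = \min(\bar I_{\text{early}} -
  \bar I_{\text{mid}},\; \bar I_{\text{late}} - \bar I_{\text{mid}})$,
  so *both* drops into the waist must be large; stage modules are
  declared by the analyst, never inferred;
* pairwise — $\bar I_A - \bar I_B$ with a one-sided alternative.

The empirical p-value uses the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$, so
it is never exactly zero and never below $1/(n_{\text{perm}}+1)$; it is
the authoritative p. A parametric fit (moment-matched gamma for the
variance null, normal for signed differences) is reported as advisory
only, for comparability with tools that quote fitted tails. Default
`n_perm` is 50,000; the simulation studies in this package run at 1,000,
which bounds the resolvable p at ~0.001 and is ample for rejection-rate
estimation. A single occupied stratum makes every statistic identically
zero; the tests then report the degenerate case with $p = 1$ rather than
a pseudo-significant floating-point residue.

## Driver-gene selection

At each stage, genes are sorted by descending contribution and the cut
is placed at the point of maximum perpendicular distance to the chord
joining the first and last points of the curve (the elbow). The
maximum-distance point is the first gene of the flat background tail, so
the selected head is everything strictly above it. When the curve is
linear (no curvature to machine tolerance) the elbow is undefined and
the cut falls back to the cap, 500 genes — the cap is read as an upper
bound, not a quota. Drivers shared across a stage group are the ordered
intersection of the per-stage lists (mean rank across lists).

## Cross-series comparison

Between two developmental series, expression is compared at orthogroup
level: member-gene TPM is summed per orthogroup (`aggregate_orthogroups`,
on untransformed TPM — aggregate → transform → distance, in that order),
matrices are inner-joined on shared orthogroups, and each stage pair is
scored by Pearson or Spearman correlation, Manhattan distance, or the
Jensen–Shannon distance. JSD here is the square root of the
Jensen–Shannon divergence with log base 2 of the two columns normalized
to probability vectors: symmetric, zero iff equal, bounded in $[0,1]$,
and a metric (the triangle inequality is property-tested). Stage
correspondence is the per-row argmin (argmax for correlations), earlier
stage on ties, with a tie flag. Orthogroup abundance is a plain TPM sum:
length-weighted aggregation would need per-gene effective lengths, which
the TPM input does not carry; since all four metrics are computed on the
same aggregation, the stage ordering they induce is insensitive to this
choice at the scale of the comparisons made here.

## The synthetic-data generator

`generate_dataset()` emulates the data a stage-resolved developmental
RNA-seq study produces, with known ground truth:

* **Sizes.** 8,000 genes, 5 stages, 3 replicates by default — the scale
  of a filtered brown-algal gene set and a compact embryonic series.
* **Ages.** Eight phylostrata drawn from an old-heavy distribution
  (30/17/13/10/8/7/8/7%; ~60% in PS 1–3), mimicking real
  phylostratigraphy where most genes are ancient. PS ≥ 7 (the default
  `young_cutoff`) plays the role of lineage-specific young genes.
* **Expression.** Per-gene log-normal baseline (meanlog 3, sdlog 1.5,
  i.e. median ~20 TPM with a long right tail), independent per-gene
  per-stage log-normal variation (sd 0.5, log scale) giving realistic
  non-flat profiles uncorrelated with age, and log-normal replicate
  noise (sd 0.25).
* **Shapes.** The hourglass is generated by *repressing* young-strata
  expression at mid-role stages by `repression_factor` (default 0.2) —
  the waist arises because young genes are switched off there, which
  makes the cause of the pattern itself testable. `early_conservation`
  ramps young-gene expression up across stages (monotone profile, no
  waist); `flat` leaves ages and expression independent (the null);
  `unicellular_high` represses young genes at all multicellular-role
  stages.
* **dN/dS.** A Beta(2, 6) bulk on (0, 1) with a configurable fraction
  (default 0.5%) above 1, so the divergence deciles reflect
  overwhelmingly purifying selection; gamete-role stages can carry
  boosted expression of the weakest-selection tail for TDI contrasts.
* **Orthogroups.** Each covered gene (90% by default) pairs with a
  partner gene in a second synthetic species, with a 10% in-paralogue
  rate.

What the generator does *not* emulate: library-size artefacts, batch
effects, isoform-level quantification uncertainty, co-expression
structure between genes, or phylogenetic correlation between age and
expression level. Passing the calibration and power checks therefore
shows that the statistics behave correctly *given* the stated sampling
model, not that any real dataset satisfies that model.

## Simulation studies and problem sizes

`recovery_report()` repeats generate → prepare → test over many
datasets. The package's own studies use 200 datasets at 1,000
permutations for null calibration (type-I error within the 95% binomial
band around $\alpha = 0.05$, and near-uniform null p-values), 100
datasets for power under the default hourglass effect (power well above
0.8), 40 noiseless runs for waist recovery, and 100 datasets for the
unicellular-vs-multicellular contrast, where the pairwise test has high
power while the hourglass test restricted to the (flat-by-construction)
multicellular stages stays at the null rate. These sizes give binomial
standard errors of ~1.5–2 percentage points on the reported rates.

## Numerical choices and degenerate inputs

* Weighted means are computed by `crossprod` on the gene × stage matrix;
  a stage with zero total abundance is an error naming the stage.
* Genes present in the expression matrix but absent from the stratum map
  (or vice versa) are dropped from the index with counts recorded in the
  result, not imputed.
* Bootstrap of a single gene or a single stratum returns SD exactly 0.
* Empirical p-values use the add-one rule; fitted p-values are `NA` when
  the null is degenerate.
* Decile ties are split by gene id (stable); an all-constant vector is
  one stratum.
* All randomized operations take an explicit seed and are reproducible
  bit for bit.

## Orchestration

`run_pipeline()` drives prepare → strata → indices → tests →
contributions from one named list or YAML config and writes each table
with a provenance record (package version, seed, `n_perm`, `n_boot`,
transform, filter threshold, dropped-gene counts) — the knobs that
reproduction hinges on. The numbered scripts under `analysis/` are thin
narrative drivers over the same exported functions; the pipeline result
equals the composition of the individually invoked operations, which is
asserted in the test suite.

## Known limitations

* Index values depend on the chosen transform; conclusions should be
  checked across transforms (the engine makes this a one-argument
  change).
* The permutation null fixes expression and shuffles strata; it does not
  model uncertainty in the expression estimates themselves.
* The elbow rule is a geometric heuristic; on curves with several
  plateaus the single cut may be unstable, which is why the cap bounds
  it.
* Cross-series distances require a shared orthogroup universe; series
  with little orthogroup overlap yield distances computed on few points,
  and `n_orthogroups` should be inspected before interpreting them.
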