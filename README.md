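# phylotrax

Evolutionary transcriptomics for developmental series: expression-weighted
evolutionary indices, permutation tests for profile shapes, per-gene
contribution analysis and cross-series transcriptome distances — plus a
synthetic-data generator with known ground truth for calibrating all of it.

## The problem

Developmental transcriptomes are not evolutionarily uniform: some stages
express predominantly ancient, broadly expressed, strongly conserved genes,
others recruit young, specific, fast-evolving ones. phylotrax is for
researchers who have a stage-resolved expression matrix (TPM with
replicates) together with per-gene evolutionary annotations — gene age
ranks (phylostrata), expression-specificity values (tau) or dN/dS ratios —
and want to quantify and test how the evolutionary composition of the
transcriptome changes across development (embryogenesis, life cycle stages,
tissues).

## The statistic

For gene *i* with integer stratum *s<sub>i</sub>* ∈ {1…K} and expression
*e<sub>it</sub>* at stage *t*, the index at stage *t* is the
expression-weighted mean stratum:

```
Index_t = Σ_i  s_i · e_it / Σ_j e_jt
```

With phylostrata (1 = oldest) this is the **transcriptome age index
(TAI)** — lower = evolutionarily older transcriptome; with tau deciles the
**transcriptome specificity index (TSI)**; with dN/dS deciles the
**transcriptome divergence index (TDI)** — lower = stronger purifying
selection. A mid-developmental TAI dip is the transcriptomic hourglass and
its minimum the phylotypic waist. Per-stage uncertainty comes from a gene
bootstrap; shapes are tested against a permutation null in which gene
strata are shuffled while expression stays fixed:

* **flat-line test** — variance of the profile (departure from constancy),
* **reductive hourglass test** — D = min(early − mid, late − mid) of the
  module means (both drops into the waist must be large),
* **pairwise test** — one-sided difference between two stage groups.

Per-gene additive contributions (`pTAI_it = s_i e_it / Σ_j e_jt`) decompose
each stage's index exactly, and an elbow rule on the sorted contribution
curve selects the driver genes. Between two series, orthogroup-summed
expression is compared by Pearson/Spearman correlation, Manhattan distance
or Jensen–Shannon distance, with best-match stage correspondence.

## Worked example

```r
library(phylotrax)

cfg <- synthetic_config(profile = "hourglass", seed = 101)  # 8,000 genes, 5 stages
ds  <- generate_dataset(cfg)
mat <- prepare_stage_matrix(ds$expression, min_tpm = 2, transform = "sqrt")
weighted_index(mat, ds$ps_map, n_boot = 5000, seed = 1)
```

```
TAI profile ( 7546 genes, transform = sqrt )
          S1     S2     S3     S4     S5
value 3.3788 3.3923 3.0241 3.0350 3.3775
sd    0.0363 0.0359 0.0292 0.0304 0.0359
```

The TAI dips from ≈3.38 at the early and late stages to ≈3.02 at the
mid-role stages S3–S4: the configured waist, recovered from data in which
young-strata genes (PS ≥ 7) were repressed five-fold at mid stages. The
shape tests agree:

```r
flat_line_test(mat, ds$ps_map, n_perm = 10000, seed = 7)
reductive_hourglass_test(mat, ds$ps_map,
                         stage_modules(c("S1","S2"), c("S3","S4"), "S5"),
                         n_perm = 10000, seed = 7)
```

```
flat_line test: statistic = 0.037, p(empirical) = 9.999e-05, ...
reductive_hourglass test: statistic = 0.34803, p(empirical) = 9.999e-05, ...
```

Both reject at the permutation floor (1/(n_perm+1)); on the matched null
dataset (`profile = "flat"`) the same tests return p = 0.81 and p = 0.20.

## The analysis

The numbered scripts under `analysis/` run the full study on synthetic
data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the hourglass / null / unicellular datasets |
| `02_indices.R` | TAI, TSI, TDI profiles with bootstrap SDs |
| `03_shape_tests.R` | flat-line, hourglass and pairwise tests |
| `04_contributions.R` | pTAI matrix, elbow-selected drivers, waist intersection |
| `05_cross_species.R` | orthogroup aggregation, distance metrics, stage matching |
| `06_calibration.R` | type-I error and power over repeated datasets |

Run them in order from the repository root
(`Rscript analysis/01_simulate.R`, …). Real data drops in at the same
entry points: a TPM table + design (`read_expression_table`), a gene-age
table (`read_phylostratum_map`), a dN/dS table (`read_dnds_table`) and an
orthogroup table (`read_orthogroups`); `run_pipeline()` drives the whole
chain from one YAML config with a provenance record.

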