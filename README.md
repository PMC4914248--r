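# corcohort

Gene-pair co-expression cohort partitioning and survival analysis.

## The problem

When a transcription factor drives a target gene, the two are co-expressed
in exactly those tumours where the regulatory axis is active. If the axis
promotes an aggressive phenotype, patients whose tumours show the
co-expression should have worse outcomes. `corcohort` implements the
bioinformatic workflow that tests this: it stratifies an expression cohort
into a subgroup where a designated gene pair (e.g. TP73 and POSTN) is
positively correlated and a remainder where it is not, and compares
survival between the two subgroups. It is aimed at analysts working with
expression matrices in GEO series-matrix form plus per-sample follow-up
annotations.

## The method

1. **Rank transformation.** Within each sample, expression values become
   rank scores on a 0–100 scale: a probe with midrank *k* among the
   sample's *N* non-missing probes scores `100 (k − 1)/(N − 1)`, so a score
   of 55 means 55% of the sample's other probes are expressed lower.
   Pearson correlation of rank scores equals Spearman correlation of the
   raw values, and the transform is invariant to any per-sample monotone
   normalization.

2. **Greedy correlation-maximizing partition.** All samples start in
   cohort 1. At each step, for every cohort-1 sample *s* the leave-one-out
   delta Δ(s) = r(C∖{s}) − r(C) is computed, where *r* is the Pearson
   correlation of the two genes' rank profiles over the current cohort *C*;
   the sample with the largest positive delta moves to cohort 2. The loop
   stops when no removal increases *r* or cohort 1 reaches `min_cohort`.
   The full removal trace (sample, *r* before, *r* after) is recorded.

3. **Survival comparison.** Kaplan–Meier curves per cohort and the
   two-group log-rank (Mantel–Cox) chi-square on 1 df.

Supporting pieces: the classical microarray differential-expression filter
(equal-variance *t* test on log2 values, Benjamini–Hochberg correction,
hits at *q* ≤ 0.05 and fold change > 2), a gene-set enrichment odds ratio
(cross-product OR with two-sided Fisher exact *p*, Haldane–Anscombe
corrected on zero cells), and a synthetic-data generator that plants a
correlated subgroup with a configurable survival hazard ratio so every
stage can be validated against ground truth.

**A caveat that matters in practice:** on continuous data the greedy loop
almost always finds *some* removal that nudges *r* upward, so left to
itself it runs down to `min_cohort` rather than stopping at a biologically
meaningful boundary. `min_cohort` is the de facto stopping parameter;
choose it from subject-matter considerations or inspect the removal trace.
The methods vignette (`vignettes/correlation-cohorts.Rmd`) analyses this
behaviour quantitatively.

## Worked example

```r
library(corcohort)

cfg <- simulation_config(n_samples = 60, n_probes = 100,
                         planted_fraction = 0.5, rho_in = 0.95,
                         hazard_ratio = 3, seed = 7)
sim <- simulate_expression(cfg)
surv <- simulate_survival(sim$labels, cfg)

ranks <- rank_transform(sim$matrix)          # per-sample 0-100 rank scores
pair <- extract_gene_pair(ranks, "GENE_A", "GENE_B")
part <- greedy_partition(pair, min_cohort = 30)
part
#> Greedy correlation-maximizing partition
#>   cohort 1 (positive-correlation): 30 samples
#>   cohort 2 (removed):              30 samples
#>   Pearson r: 0.3929 (all samples) -> 0.9569 (cohort 1, selection-biased)
#>   removals: 30; min_cohort = 30; tie rule: lowest-index

cmp <- compare_partition_survival(part, surv)
cmp
#> Cohort survival comparison
#>   cohort 1: n = 30, events = 28
#>   cohort 2: n = 30, events = 25
#>   log-rank chi-square = 3.849, p = 0.04976
#>   note: cohort-1 correlation is maximized by construction (selection-biased); ...
```

Half of the 60 simulated samples carry the planted co-expression
(pair correlation 0.95) and a 3-fold event hazard. With `min_cohort = 30`
the partition keeps a cohort of 30 that overlaps the planted subgroup in
23 of 30 samples; its correlation rises from 0.39 (all samples) to 0.96
(selected cohort — inflated by construction, as the printed note warns),
and the log-rank test sees the attached survival difference (p ≈ 0.0498).

The same run on files instead of in-memory objects:

```r
run_correlation_survival_pipeline("expression.txt", "survival.tsv",
                                  probe_a = "GENE_A", probe_b = "GENE_B",
                                  output_dir = "run1")
```

writes `partition_report.tsv` (per-sample cohort and removal step),
`survival_report.json` (cohort sizes, events, chi-square, p) and a
reproducibility manifest; reruns are byte-identical.

## Analysis workflow

The `analysis/` scripts replay the full study on synthetic data and write
their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the study cohort (100 samples, 60 planted at r = 0.9, hazard ratio 2.5) |
| `02_partition_survival.R` | end-to-end pipeline run, scored against the planted truth |
| `03_differential_expression.R` | planted 4-fold probes among nulls: DE filter + enrichment OR |
| `04_replication.R` | 200-replicate recovery study and 100-replicate survival comparison |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

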