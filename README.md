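# paritysig

Pregnancy leaves a lasting mark on the breast transcriptome, and that
mark is thought to underlie the long-term protective effect of an early
full-term pregnancy against breast cancer. `paritysig` is an R package
for detecting and characterizing such **parity-associated gene-expression
signatures** in normal breast tissue from probe-level microarray data. It
is aimed at analysts re-running or stress-testing this class of study
design: a parous vs nulliparous comparison on whole-tissue arrays, with
the time since last pregnancy (TSLP) as the biological axis of interest.

The package implements the full analysis chain as composable, tested
stages:

1. **Probe filtering** — remove probesets with `< 75%` present calls
   unless the present-call fraction differs by `>= 25%` between parous
   and nulliparous samples, then drop the first quartile of
   coefficient-of-variation (computed on linear-scale intensities).
2. **Batch adjustment** — parametric empirical-Bayes location/scale
   harmonization (ComBat-style): per probe, per batch, shrink location
   shifts toward a normal prior and variance factors toward an
   inverse-gamma prior (method-of-moments hyperparameters) and
   reconstruct the matrix with the grand mean restored.
3. **Replicate QC** — Lin's concordance correlation coefficient
   `CCC = 2*cov(x,y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`
   on blinded cross-batch duplicate arrays, gated at 0.98.
4. **Differential expression** — per-probe OLS of log2 expression on a
   parity indicator, optionally adjusted for age, BMI, smoking duration
   and cycle/IUD category; Storey q-values (pi0 estimated by the
   smoother method) for FDR control.
5. **Discovery/validation resampling** — 12 stratified 2/3 : 1/3 splits;
   a probe validates in a pair when discovery q < 0.20, validation
   p < 0.05 and the effect direction agrees; probes validating in >= 2
   pairs form the robust signature.
6. **TSLP patterns** — per-probe log2 fold-change profiles over the TSLP
   groups (<=5, 5-10, >10 years vs nulliparous), K-means clustering under
   the uncentered-Pearson distance `1 - sum(xy)/sqrt(sum(x^2) sum(y^2))`,
   and algorithmic labeling of clusters as transient / long-term changing
   / long-term constant (upregulated) or the two downregulated patterns.
7. **GO enrichment** — conditional hypergeometric tests over a DAG
   (genes explained by significant child terms are discounted), rollup of
   enriched terms into the broad developmental / immune categories, and a
   chi-squared test of category composition across clusters.
8. **Tissue decomposition** — per-subject OLS of whole-tissue expression
   on matched LCM epithelium and stroma profiles (the coefficients
   estimate compartment weights), plus the paired epithelium-vs-stroma
   comparison (FDR < 10%, fold change >= 1.2).
9. **RT-PCR concordance** — delta-Ct normalization to 18S, group fold
   changes as `2^(-ddCt)` with batch-adjusted regression p-values, and
   cross-platform agreement via a one-way random-effects ICC and Spearman
   correlation.

A first-class synthetic-data module (`simulate_cohort`,
`simulate_expression`, `simulate_tissue_triplets`,
`simulate_toy_ontology`, `simulate_rtpcr`) generates cohorts with the
study's statistical structure — batch location/scale effects, covariate
links, confounded smoking, and planted temporal patterns — so every
stage is testable without any external download.

## Worked example

```r
library(paritysig)

cohort <- simulate_cohort(79, 30, seed = 1)
sim    <- simulate_expression(cohort, 2000, n_per_pattern = 20, seed = 2)
adj    <- combat_adjust(sim$expr, cohort$batch)

pairs  <- make_partition_pairs(cohort, n_pairs = 12, seed = 3)
dv     <- run_discovery_validation(adj$adjusted, cohort, pairs)
length(dv$validated_ids)
#> [1] 58

table(sim$truth$pattern[match(dv$validated_ids, sim$truth$probe_id)])
#>        down_constant                 null up_longterm_changing
#>                   20                    2                   16
#> up_longterm_constant
#>                   20
```

All 40 planted constant-pattern probes (the durable parity signature)
validate, most long-term changing probes follow, the transient ones do
not — the resampling design deliberately favors effects stable across
the whole cohort — and the false-positive count stays in the low single
digits out of 1,900 null probes.

```r
prof <- tslp_group_profiles(adj$adjusted, cohort,
                            sim$truth$probe_id[sim$truth$pattern != "null"])
pat  <- assign_patterns(prof, seed = 4)
head(pat, 3)
#>      probe_id direction cluster_id   pattern
#> 1 probe_00001        up          4 transient
#> 2 probe_00002        up          2 transient
#> 3 probe_00003        up          4 transient
```

A command-line front end mirrors the stages
(`simulate | preprocess | diffexpr | dvselect | patterns | enrich |
decompose | concordance`), each reading the tab-delimited outputs of the
previous one; see `inst/exec/paritysig`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the statistical
model of each stage, the synthetic-data generator's assumptions, every
tunable threshold with its default, and known limitations.
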