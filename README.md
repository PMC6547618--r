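# mirpair

Integrative analysis of miRNA and mRNA sequencing from **matched
tumor–normal pairs**, in R.

When every patient contributes one tumor and one normal sample, differential
expression can be asked per patient, not just per cohort: a trustworthy
tumor-associated miRNA should not only reach a stringent cohort-level FDR, it
should change *in the same direction in almost every patient*, and by a
meaningful amount in most of them. `mirpair` implements that matched-design
philosophy end to end:

1. **Normalization** — counts-per-million on the log2 scale
   (`log_cpm()`, pseudocount 0.5) and quantile normalization
   (`quantile_normalize()`) with a deterministic tie rule.
2. **Consensus differential expression** (`select_de_features()`) — three
   paired statistics per feature:
   * a moderated paired *t* with empirical-Bayes variance shrinkage
     (`s²` shrunk toward a moment-matched prior `(s₀², d₀)`,
     `t = mean(d)/(s_post/√n)`, `df = d₀ + n − 1`),
   * the Wilcoxon signed-rank test (exact for n ≤ 25, otherwise the
     continuity-corrected normal approximation),
   * a negative-binomial Wald test with per-patient intercepts,
     log-library-size offsets and trend-shrunken method-of-moments
     dispersions.

   A feature is kept only if **all three** methods reach `q ≤ 10⁻⁵`
   (Benjamini–Hochberg), passes an expression gate (mean logCPM ≥ 3 in
   miRNA mode; |mean log2FC| > 0.5 in mRNA mode), and satisfies two
   per-patient consistency criteria: direction concordant in **> 80 %** of
   patients and at least two-fold change in **≥ 70 %** (each relaxed by 10
   percentage points in mRNA mode).
3. **Target prediction** — canonical seed-site scanning
   (`scan_seed_sites()`; 8mer, 7mer-m8, 7mer-A1, with type priority at a
   locus), four context features per site (local AU content, log10 UTR
   length, log10 target-site abundance, nearest-neighbour seed-pairing
   stability), and a multiple-linear-regression score
   `score = β₀ + β·features`; genes with aggregated score **< −0.3** are
   putative targets (`predict_targets()`). Precompiled target lists are
   merged with `merge_target_maps()` (validated relations kept; predictions
   require support from ≥ 3 programs; scored lists filtered at a
   configurable threshold).
4. **Integration** — `anticorrelated_pairs()` returns (miRNA, gene) pairs
   that are both differentially expressed, in opposite directions, and
   linked in the target map; `hypergeometric_enrich()` tests gene sets
   (GMT, e.g. the 50 MSigDB hallmarks) by the exact upper hypergeometric
   tail with BH adjustment.
5. **Survival** — `assign_percentile_groups()` stratifies a cohort into
   top/bottom expression percentiles (e.g. 10 %/10 %), compared by
   Kaplan–Meier estimation with Greenwood standard errors and the two-group
   log-rank test (`survival_stratify()`).

Every input the pipeline consumes can be generated synthetically with
planted ground truth (`simulate_paired_counts()`,
`simulate_sequence_universe()`, `simulate_repression_data()`,
`simulate_survival_cohort()`), so the entire analysis is testable offline.

## Worked example

```r
library(mirpair)

# a matched cohort of 48 patients, 5% of 2000 miRNAs planted as DE
sim <- simulate_paired_counts(n_features = 2000, n_pairs = 48,
                              frac_de = 0.05, logfc_range = c(1.5, 3),
                              seed = 20001)
de <- select_de_features(sim$counts, de_config("mirna"))
attr(de, "step_counts")
#>     input prefilter consensus      gate    called
#>      2000      2000       100        96        94
table(de$direction[de$called])
#> down   up
#>   47   47

planted <- sim$truth$feature_id[sim$truth$log2fc != 0]
mean(planted %in% de$feature_id[de$called])   # recall of planted truth
#> [1] 0.94
```

Of 100 planted features, 94 survive the full gauntlet (three-method
consensus at FDR 10⁻⁵, expression gate, per-patient consistency) and none
of the 1900 null features is called. The whole orchestrated analysis — DE
in both modes, target prediction and merge, pair integration, enrichment,
survival — runs from one configuration:

```r
res <- run_pipeline(pipeline_config(outdir = "demo_out", seed = 5))
attr(res$pairs, "summary")["n_pairs"]   # anticorrelated DEmiR-DEG pairs
#> 160
```

A thin command-line front end with the same stages lives in
`exec/mirpair` (`mirpair all --demo --seed 5 --outdir demo_out`).

## Documentation

The methods vignette (`vignettes/matched-pair-integration.Rmd`) describes
the statistical models, the synthetic-data generators and their defaults,
numerical choices, and known limitations.
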