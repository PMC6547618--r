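---
title: "Matched-pair miRNA/mRNA integration: models and design choices"
author: "mirpair authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-pair miRNA/mRNA integration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpair)
```

# The problem

In a matched tumor–normal design every patient contributes one tumor and
one normal sample, so patient-level effects (genetic background, sample
handling, global expression shifts) are shared within a pair and cancel in
within-patient comparisons. `mirpair` exploits this twice: the
differential-expression statistics are paired, and two *per-patient
consistency filters* demand that a called feature behaves the same way in
nearly every individual patient, not merely on cohort average. Downstream,
called miRNAs and genes are joined through sequence-based and compiled
target information into anticorrelated regulatory pairs, characterized by
gene-set enrichment, and candidate markers are evaluated by
percentile-stratified survival comparison.

# Normalization

`log_cpm()` computes
`log2((count + c) / (libsize + 2c) * 1e6)` with pseudocount `c = 0.5`. The
doubled pseudocount in the denominator keeps the transform exactly monotone
in the count and bounded for zero counts; this is the standard logCPM
convention. `quantile_normalize()` maps every sample onto the
across-sample mean of sorted values. Since no tie rule is canonical, ties
within a column deterministically receive the *mean of the reference values
over the tied rank span*; this makes the transform idempotent and
permutation-stable. Quantile normalization is applied to the miRNA matrix
after logCPM (miRNA abundance distributions are strongly skewed by a few
dominant species); the mRNA matrix uses logCPM only. Both choices are
switchable in `de_config()`.

# The three DE statistics and the consensus

All three statistics act per feature on `n` patient pairs (at least 3).

**Moderated paired t.** With per-pair log2 fold changes `d` and sample
variance `s²` (df `d = n − 1`), the across-feature distribution of `s²` is
modeled as scaled inverse-chi-square with prior `(s₀², d₀)`. Rather than
maximizing a marginal likelihood we moment-match: writing `R = (1 + CV²) ·
d/(d + 2)` with `CV²` the squared coefficient of variation of `s²`,
`d₀ = (4R − 2)/(R − 1)` and `s₀² = mean(s²)(d₀ − 2)/d₀`. The posterior
variance `s²_post = (d₀ s₀² + d s²)/(d₀ + d)` gives
`t = mean(d)/(s_post/√n)` on `d₀ + n − 1` df. If the observed spread of
`s²` is no larger than sampling noise (`R ≤ 1`), `d₀` is effectively
infinite and all features share the pooled variance.

**Wilcoxon signed-rank.** Zero differences are dropped; `|d|` is ranked
with average ranks; the positive-rank sum is referred to the exact null
distribution for `n ≤ 25` without ties, otherwise to the normal
approximation with continuity and tie corrections. The implementation is
vectorised over features (the per-call overhead of a generic test function
dominates at thousands of features times replicated simulations) and is
checked against `stats::wilcox.test` in the unit tests.

**NB Wald.** Counts follow a negative binomial with
`log μ = a_j + β·condition + log L_s`, i.e. a per-patient intercept `a_j`,
the tumor effect `β`, and the observed library size as offset. The paired
block structure lets the `a_j` be profiled out cheaply: Fisher scoring
alternates closed-form-like pair updates with a one-dimensional update of
`β`, vectorised across all features simultaneously. The profile
information `I(β) = Σ_j w_t w_n/(w_t + w_n)` with `w = μ/(1 + φμ)` gives
the Wald standard error. Dispersions come from a degrees-of-freedom
corrected Pearson method of moments around the paired Poisson fit, shrunk
50/50 toward a trend (bin means of the raw estimates over 20 average
expression bins). Two calibration choices matter at the extreme FDR
thresholds this pipeline uses: the per-patient intercepts must be in the
model (a scalar tumor-vs-normal contrast that ignores pairing is
conservative when patients vary, anticonservative when library-size
absorption is imperfect), and the Wald statistic is referred to a *t*
distribution on `n − 1` df rather than the normal — with 48 nuisance
intercepts at 96 observations the normal reference is visibly
anti-conservative in the far tails. With these choices all three
statistics' null p-values are uniform to Kolmogorov–Smirnov distance
< 0.05 at 2000 features × 48 pairs (verified by the acceptance suite).

**Consensus and filters.** Per method, Benjamini–Hochberg q-values are
computed across features; a feature must reach `q ≤ 10⁻⁵` in *all three*
methods. miRNA mode then gates on overall mean logCPM ≥ 3; mRNA mode on
|mean log2FC| > 0.5. Finally the consistency criteria: with `N` evaluable
pairs, (a) the majority-sign count must exceed `0.80·N` (strict `>`,
matching the wording "in over 80%"), and (b) at least `0.70·N` pairs must
show a two-fold change (`≥`, matching "equaling over 70%"). For mRNA both
fractions are relaxed by 10 *percentage points* (0.70/0.60) — the simplest
reading of "relaxed by 10%"; both comparisons and fractions are
configurable. Per-pair fold changes of exactly zero count against both
criteria, and an exact positive/negative tie yields no direction and fails,
so degenerate inputs are handled deterministically.

The low-expression prefilter keeps features with CPM > 1 in ≥ 25% of
samples; only "initial filtering of lowly expressed" features is specified
upstream, so the exact rule is a package choice and configurable.

# Seed sites, context features, MLR scoring

Only the three canonical site types are scanned (6mer sites exert weak
repression and act as noise). With miRNA positions numbered 5′→3′ from 1:

* 7mer-m8 — UTR match to the reverse complement of positions 2–8;
* 7mer-A1 — reverse complement of positions 2–7 followed by an A (the A
  faces position 1 regardless of the miRNA's first base);
* 8mer — reverse complement of positions 2–8 followed by an A.

Every 8mer locus also matches both 7mer patterns; a locus is reported once
with the most specific type. Coordinates are 0-based half-open on the UTR
plus strand. The scanner is validated against an exhaustive per-offset
oracle, and background match rates on uniform-random sequence agree with
the binomial expectation `4^(−L)` per offset.

Four context features feed the multiple-linear-regression score:

* `au` — fraction of A/U in the 30 nt upstream plus 30 nt downstream of
  the site (truncated at UTR ends, denominator = bases present). The
  window width is not canonical anywhere; 30 nt is the conventional local
  window and configurable.
* `utr_len` — log10 UTR length (nt).
* `ta` — target-site abundance, `log10(1 + count of the miRNA's 7mer-m8
  match over the whole UTR universe)`; the `+1` guards empty universes.
* `sps` — seed-pairing stability: the nearest-neighbour stacking free
  energy (ΔG°37, kcal/mol) of the perfect Watson–Crick seed duplex
  (positions 2–8), summed over the six dinucleotide steps of the standard
  RNA parameter table bundled in the package. No initiation term and no
  G:U pairs, so the value is always negative and purely sequence-determined.

`score = β₀ + Σ βᵢ·featureᵢ` per site, summed over a gene's sites
(aggregation configurable to `min`); genes with aggregated score < −0.3
are putative targets. The shipped default coefficients
(`default_mlr_model()`) are synthetic-calibration values with the field's
canonical signs — AU negative (high AU → stronger repression), length and
abundance positive (weaker repression), SPS positive acting on a negative
feature (stabler duplex → stronger repression) — because no published
coefficient vector is available to import; they are clearly labeled as
synthetic, and `fit_mlr_coefficients()` refits all five parameters by OLS
from any site-level repression table (recovering planted coefficients
within ±0.05 at n = 500, noise sd 0.1; exactly in the noiseless limit).

Target-list compilation (`merge_target_maps()`) keeps validated
(knowledgebase) relations unconditionally, requires ≥ 3 supporting
programs for predicted relations, and filters scored lists at a
threshold. The published recommendation keeps cumulative weighted context
scores > 0.2, which is sign-inverted relative to the usual TargetScan
convention (more negative = stronger targeting); the comparison direction
is therefore exposed (`ts_keep_greater`) rather than silently resolved.

# Integration and enrichment

`anticorrelated_pairs()` is the literal triple filter: relation in the
target map, both members called, directions opposite. Enrichment uses the
exact upper hypergeometric tail `P(X ≥ k)` with the universe defaulting to
all genes that passed the DE prefilter (expressed genes) — the standard
background choice; testing against the whole genome would inflate
enrichment. Up- and downregulated queries are tested as separate BH
families, and the target-restricted queries (the gene side of the pair
list) are tested the same way. Only over-representation is tested.

# Survival

`assign_percentile_groups()` takes the bottom `floor(p·n)` and top
`floor(p·n)` subjects by expression (ties broken by stable input order).
Kaplan–Meier curves and Greenwood standard errors, and the two-group
log-rank test, stand on the `survival` package; events are counted before
censorings at tied times (the standard convention), and p-values use the
asymptotic χ²₁ only, matching common online survival tools. The hand
product-limit fixtures and an independent O/E/V tabulation oracle verify
the wrapping.

# Synthetic data: what it emulates, what it does not

`simulate_paired_counts()` draws NB counts with
`log μ = baseline + patient + condition·log2FC·ln 2 + log(share·L)`:
uniform baselines spanning logCPM ≈ 3–11 (`mean_log_range = c(2, 8)`),
a per-patient scalar factor (sd 0.3) shared exactly by the patient's two
samples, NB dispersion 0.1, and library sizes uniform in 0.5–2 million —
values a desk-scale miRNA-Seq cohort would consider realistic. Planted
features receive a signed log2 fold change uniform in a configurable
range. The defaults mirror the study conditions exercised by the
acceptance suite: 2000 features, 48 pairs, 5% planted DE.

The demo bundle (`demo_inputs()`) couples the layers: planted DE miRNAs
are linked to planted DE genes of opposite direction through synthetic
prediction lists (plus decoys that fail the 3-program support rule), a
scored list, a sequence universe with planted seed sites, gene sets with
one planted-enriched set per direction, and a survival cohort with an
expression-linked hazard (ratio 2.5 at 490 subjects). Planted |log2FC| is
drawn from \[2, 4\] — matched-pair tumor studies report candidate miRNAs
at |logFC| > 2 — so the end-to-end planted-pair recovery measures pipeline
plumbing rather than borderline statistical power (the borderline regime
is measured separately at \[1.5, 3\]).

Deliberately absent from the generators: read-level error structure,
isomiRs, feature–feature correlation, patient-by-feature interactions,
batch effects, and non-exponential survival. Passing the planted-truth
criteria therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness to every artifact of real data.

All generators funnel their randomness through a single seed per call and
restore the caller's RNG state, so every simulation in the package, tests
and acceptance script is exactly reproducible.

# Numerical choices and degenerate inputs

* BH q-values come from `stats::p.adjust`; an O(m²) step-up oracle checks
  them exactly in the tests.
* Fisher-scoring steps in the NB fitter are clamped (±3 for pair
  intercepts, ±2 for the condition effect) to prevent overshoot at
  extreme counts; empty pairs (total count 0) are pinned at a negligible
  mean and contribute nothing to the information.
* Dispersion estimates are floored at 0 (Poisson); the 50/50 trend
  shrinkage uses equal-count expression bins, degrading gracefully to a
  single bin for small feature sets.
* Quantile normalization requires finite input and ≥ 2 samples; zero
  library sizes abort with the offending sample named.
* `fit_mlr_coefficients()` refuses rank-deficient designs and fewer than
  20 rows.

# Problem sizes

The test and acceptance simulations use 2000 features × 48 pairs for
calibration and recovery, 100 replicate null cohorts for the zero-call
rate, 1000 replicates for log-rank type-I error, and the default demo
scale (400 miRNAs, 2000 genes, 48 pairs) for the end-to-end run — sizes
chosen to mirror the study's cohort geometry at desk scale while keeping
a full validation run in minutes on one CPU.

# Known limitations

* The three DE statistics are analogues built from standard published
  formulas, not wrappers of edgeR/limma-voom/DESeq2; exact reproduction of
  those packages' p-values is a non-goal (the consensus-plus-consistency
  construction is the point).
* Only canonical seed sites are modeled: no 3′-compensatory or ORF sites,
  no conservation, no structural accessibility.
* The enrichment stage tests over-representation only, with no ranked
  (GSEA-style) alternative.
* Survival analysis is two-group KM/log-rank; no Cox regression,
  covariate adjustment or competing risks.
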