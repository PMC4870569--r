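---
title: "Methods: differential expression and lncRNA genomic context in the UUO fibrosis model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and lncRNA genomic context in the UUO fibrosis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uuoSeq)
```

# The analysis

Unilateral ureteric obstruction (UUO) is a surgical mouse model of
progressive renal fibrosis. The cohort analysed here follows its standard
design: kidneys from sham-operated animals (group `SO`, 4 biological
replicates) and from animals 2 and 8 days post-ligation (`2D` and `8D`,
3 replicates each), profiled by bulk RNA-seq and summarized as a gene ×
sample read-count table. `uuoSeq` implements the complete downstream
analysis: quantification and filtering, three-contrast differential
expression (`SO` vs `2D`, `SO` vs `8D`, `2D` vs `8D`), and a genomic-context
workflow that turns differentially expressed long non-coding RNAs (lncRNAs)
into candidate cis-regulators of nearby protein-coding genes.

Because the original tissue data cannot be regenerated at a desk, the
package ships a simulator (`simulateAnnotation()`, `simulateCounts()`,
`makeFixture()`) that plants known truth — positional classes, effect
sizes, dispersions, size factors — and every analysis stage is validated
against that truth or against brute-force oracles.

# Quantification and filtering

Counts are normalized by **median-of-ratios**: the per-gene reference is the
geometric mean across samples (over genes positive in every sample) and each
sample's size factor is the median ratio to that reference
(`sizeFactorsMedianOfRatios()`). The implementation is the package's own,
written to the standard definition of the method; a unit test cross-checks
it against an independent estimator from the DESeq2 package to eight
decimals. RPKM (`computeRPKM()`) uses the merged exon-union length of each
gene, so overlapping exon annotations are never double-counted.

The filter cascade (`filterGenes()`) excludes, in order:

1. genes with zero counts in every sample;
2. genes with exon-union length strictly below 500 bp;
3. genes whose average normalized reads per 100 bp fall strictly below the
   25th quantile of that statistic;
4. genes whose average normalized count falls strictly below the median.

Three reading choices were genuinely open and are fixed as follows. The
data-dependent thresholds of rules 3–4 are **recomputed on the surviving
set** at each step — the stricter sequential reading of an ordered rule
list; the realized thresholds are recorded in the `FilterReport` either way,
so the alternative (thresholds from the full distribution) is auditable.
Quantiles use the type-7 (linear interpolation) definition so tests are
exact. Ties at a threshold are kept, reading "less than" literally. The
per-gene statistic of rule 3 is the mean across samples (rather than pooling
all gene × sample values), the interpretation that makes the statistic
comparable to rule 4's.

A gene counts as *detected* when its RPKM strictly exceeds 0, i.e. it
received at least one read; no published RPKM cutoff exists for this
quantity, so the permissive reading is the default and the threshold is
config-exposed (`detectionRpkmThreshold`).

# Differential testing

For each contrast, each gene gets a negative-binomial Wald test on
normalized counts with a shared method-of-moments dispersion
(`estimateDispersionMoM()`): alpha = max(1e-8, (within-group variance −
mean) / mean²), pooled over the two groups. The log2 fold change is
`log2((mean_test + 0.5) / (mean_ref + 0.5))`; the pseudocount of 0.5
normalized counts keeps fold changes finite for empty groups, matching the
finite fold changes a published analysis prints. The Wald statistic is the
log mean difference over its delta-method standard error under the NB
variance model, referred to a **t distribution with n₁ + n₂ − 2 degrees of
freedom**. The t reference is the standard small-sample correction for
plug-in variance estimates: at this study's replicate sizes (3–4 per group)
a normal reference is anticonservative, and the package's type-I error
criterion (fraction of null p-values below 0.05 within [0.03, 0.07]) is met
with the t reference. This tester deliberately replaces any specific
published package's numerics: acceptance is by calibration properties
(type-I error, FDR control, effect recovery), not byte-identity.

Genes are labelled by the volcano convention: `up` / `down` when
significant with |log2 FC| ≥ 1 (the boundary counts), and
`significant_subthreshold` for significant genes inside the band — the
"blue" genes of a volcano plot. Two significance gates coexist, both
config-exposed: raw p < 0.05 defines DE-list membership, BH FDR < 0.05
defines heatmap-style selection (`heatmapSelection()`); both usages occur in
practice and neither replaces the other. Dispersion is estimated per
contrast from its two groups only, while size factors come from all samples
once — global normalization, per-contrast testing.

# lncRNA genomic context

`classifyLncRNA()` assigns exactly one positional class per lncRNA with the
precedence **antisense > intronic > bidirectional > intergenic**, on the
rationale that physical overlap is stronger evidence of a relationship than
promoter proximity:

* *antisense* — span overlap of ≥ 1 bp with a coding gene on the opposite
  strand;
* *intronic* — span entirely inside a single intron (a gap between
  consecutive merged exons) of a same-strand coding gene;
* *bidirectional* — disjoint spans, opposite strands, TSSs pointing away
  from each other and ≤ 1 kb apart (the common divergent-promoter
  convention; no published distance exists for this class, so the window is
  config-exposed);
* *intergenic* — everything else. Same-strand overlap that is not intronic
  falls here and is flagged (`sense_overlap`), since a sense-overlap class
  is not separately defined.

`findNeighbors()` scans ±100 kb around each lncRNA for coding genes.
Distance is **edge-to-edge between gene spans** (0 iff the spans overlap;
adjacent coordinates differ by their coordinate gap), matching the
"upstream and downstream of the gene" phrasing; a TSS-to-TSS reading is the
documented alternative. `concordance()` labels a lncRNA/neighbor pair per
contrast: *similar* when both are significant with the same fold-change
sign, *opposite* with differing signs, *none* otherwise — the per-contrast
sign-agreement reading of "similar or opposite patterns of expression". A
trajectory reading (shape across the whole time course) would need the
three contrasts jointly and is left out of scope.

`selectCandidates()` is deliberately mechanical: lncRNAs called up or down
in ≥ 1 contrast whose nearest coding neighbor lies strictly closer than
3 kb, ranked by maximum |log2 FC| (ties: smaller distance, then id). The
published candidate shortlist additionally applied a literature judgement
that cannot be automated, so this selection is documented as a superset
generator.

# The simulator

`simulateAnnotation()` lays coding genes on a slot grid with at least twice
the neighbor window between unrelated genes, so each planted lncRNA has
exactly its intended partner within scan range; each lncRNA is then placed
to satisfy its class geometry by construction. `simulateCounts()` draws
counts from NB(mean = s_j · q_g · 2^δ, variance = mean + alpha·mean²) with
log-normal baselines q_g (meanlog log 100, sdlog 1), log-normal dispersions
(median 0.08 — typical of bulk tissue replicates), uniform size factors in
[0.7, 1.4], and symmetric up/down effects with |log2 effect| uniform in
[1, 3] for 10% of coding genes per ligated group. Planted lncRNAs carry
effects with probability 0.6, and their partner's sign agrees or opposes
with equal probability, giving the concordance stage non-trivial truth in
both directions. No published distributional parameters exist for these
quantities; the values above are fixed once as realistic for this design
and are not tuned.

Scenarios: `tiny` (32 genes, 6 samples — fast I/O and smoke tests),
`default` (2000 genes including 40 lncRNAs, 10 per class; 4 + 3 + 3
samples — the study's replicate structure), `null` (default geometry, all
effects zero — type-I error suites). All randomness flows from one master
seed through named substreams, so results are independent of evaluation
order. What the simulator does **not** emulate: read-level noise,
overlapping gene families, isoforms, batch effects, and the mixed-biotype
clutter of a real annotation — passing tests demonstrate algorithmic
correctness and statistical calibration under the stated model, not
robustness to every artefact of real tissue data.

# Numerical and design notes

* Internal coordinates are 1-based closed (`GRanges`), the Bioconductor
  convention; GTF I/O therefore needs no shift and BED6 export converts at
  the file boundary.
* The TSS of a minus-strand gene is its span end — the last covered base.
* Ward clustering (`wardCluster()`) delegates to `stats::hclust`
  (`ward.D2` on Euclidean distances) and is deterministic for a given
  input; merge order at exact cost ties follows `hclust`. Oracle tests use
  continuous random data where ties have probability zero and compare
  merge sequences against exhaustive-search Ward.
* Classical MDS (`classicalMDS()`) uses the top-500-variance genes on
  log2(normalized + 0.5) by default and fixes the sign of each axis so the
  first non-zero coordinate is positive, making embeddings reproducible.
* qPCR fold changes use the double-delta-Ct method with replicate Ct values
  averaged arithmetically (in cycles) before differencing.
* Degenerate inputs: zero pooled means floor the dispersion; degenerate
  Wald variances give p = 1; p-values are clamped to (0, 1]; an
  all-identical expression matrix passes the quantile/median filters
  untouched (no value is strictly below its own quantile).

# Problem sizes in the validation suites

The test and acceptance suites run entirely on synthetic data at sizes
chosen to make the statistical checks sharp yet quick: 20 random fixtures of
up to 2000 genes for the filter oracle; 500 random lncRNA placements for the
classifier and neighbor oracles; one 2000-gene null cohort for type-I error;
20 replicate default cohorts for realized FDR; 200 genes at 5 + 5 samples
for effect-size recovery; a full sweep of hypergeometric instances to
N = 12; and clustering oracles at n ≤ 6 where exhaustive search is exact.

# Known limitations

The tester is a calibrated stand-in, not a reimplementation of any specific
DE package; dispersion estimates at 3 replicates are noisy and the package
makes no attempt at shrinkage across genes. Candidate selection reproduces
the mechanical criteria only. GO/KEGG-style enrichment is reduced to
database-free hypergeometric over-representation against user-supplied GMT
collections, with the universe conditioned on tested genes; itemset-style
concurrence analysis of external services is out of scope.
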