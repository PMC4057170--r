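---
title: "Methods: annotating and interpreting methyl-CpG binding protein sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and interpreting methyl-CpG binding protein sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbdscape)
```

# The analysis and its assumptions

MBD-family proteins are recruited to methylated CpGs, so a genome-wide
binding study revolves around one coupled set of questions: where the
sites fall relative to genes and CpG islands, how methylated and CpG-dense
the bound DNA is, which chromatin contexts co-occur with binding, how
active the bound genes are, and whether the bound loci are hypermethylated
in disease cohorts. This package implements that entire downstream layer
over simple, explicit containers.

Conventions that hold everywhere:

* **Coordinates** are 0-based half-open `[start, end)` (BED-native), in
  memory and on disk; overlap means sharing at least one base; chromosome
  names match by exact string equality.
* **CpG calls** are taken as already strand-merged per CpG dinucleotide at
  the plus-strand cytosine, one record per position — the choice the
  single-file per-CpG methylation dialect implies. No second merging pass
  is applied.
* **Tags** are read 5' positions (`start` on +, `end - 1` on −),
  normalised to reads per 10 million mapped. The unit is arbitrary but
  fixed; a normalisation-invariance test guarantees no result depends on
  it.
* **Quantiles** use linear interpolation between order statistics
  (R type 7) wherever a percentile is reported, so independent
  implementations can be compared exactly.

# Site annotation and the random nulls

Sites are assigned to exactly one of promoter, exon, intron, intergenic,
*in that hierarchical order*: promoter is any overlap with a TSS ± 1 kb
window (strand enters only through the TSS definition; windows are not
clipped at the boundaries of short transcripts), exon is any overlap with
any annotated exon, intron is any remaining overlap with a transcript
span. The CGI flag is evaluated independently of the hierarchy (≥ 1 bp
overlap with a CpG island), giving 8 categories that partition any site
set. A site overlapping the promoter windows of two genes counts once:
the category, not the gene, is the unit.

Two nulls are provided. The *length-matched* null draws, per site, a
length from the empirical site-length distribution, a chromosome weighted
by its length, and a uniform start such that the interval fits (no
clipping, hence no length bias at chromosome ends). The
*distribution-matched* null additionally rejection-samples until the
random set reproduces the observed per-category counts exactly, with an
attempt cap that turns an unreachable quota (say, a CGI category on a
CGI-free genome) into an explicit error naming the category. Random
placement ignores assembly gaps and mappability: synthetic genomes have
none, and the null is meant to be simple and auditable.

`fold_over_random` is the ratio of category shares; a category absent from
the random set but present among sites is reported as `Inf`, 0/0 as `NaN`,
never as an error. Under the null (two sets from the same generator) the
fold converges to 1; the test suite checks this at 10^4 sites per set and
restricts the ±10% assertion to categories with at least 500 random draws,
the floor below which a 10% band has essentially no power at that sample
size.

# Methylation quantities

* `interval_methylation` is the **coverage-weighted** mean of per-CpG
  methylation fractions. Weighting by read coverage damps low-coverage
  calls; the unweighted alternative is one flag away
  (`min_coverage`, default 1, keeps every call — matching a deeply
  sequenced methylome where no floor is stated). A site without a
  qualifying CpG is *undefined* (`NA`), a value rather than an error, and
  is excluded-and-counted by the distribution summary.
* `mcpg_density_track` computes, per fixed window, the sum of methylation
  fractions divided by window length — methylated-CpG equivalents per bp
  (the length unit is per-bp by definition here, since the source
  formulation leaves it open). Terminal partial windows are dropped, not
  rescaled, so the constant-length normalisation stays exact.
* `enrichment_track` is
  `log2((chip_w/chip_total + p) / (input_w/input_total + p))` with
  pseudo-frequency `p = 0.5 / min(totals)`, chosen so empty windows stay
  finite while identical tag lists give exactly 0.
* `ranked_density_enrichment` sorts windows by density (ties broken by
  genomic order — deterministic), averages enrichment over consecutive
  runs of `ceil(N / n_points)` windows for the curve, and reports the
  Spearman correlation over all windows. A constant vector has no ranking
  signal; its rho is reported as 0 by convention.

# Profiles, clustering and mirrored clusters

Tag-density matrices count tag 5' ends per bin across `[center − flank,
center + flank)`; anchors nearer than `flank` to a chromosome edge are
dropped and counted. Heatmap-resolution matrices default to 20-bp bins
over ±5 kb; averaged profiles (TSS, metagene, methylation/CpG) use 100-bp
bins. Average profiles report the mean with 50th and 90th percentile
bands. Metagene profiles exclude genes shorter than 4 kb (and require
`min_gene_length ≥ 2·flank` so the TSS and TES windows cannot overlap).

Clustering concatenates the participating marks' rows after scaling each
mark to unit 95th percentile — without per-mark scaling, deeply sequenced
marks dominate the Euclidean metric. Marks can be declared display-only:
they are excluded from the feature vector but reported per cluster, and a
test asserts they can never change an assignment. The clusterer is
Lloyd's k-means with 20 random restarts under a fixed seed (random
restarts rather than k-means++ seeding; base R provides the former, and
at 20 restarts on these matrix sizes the solutions are stable across
seeds). Defaults are `k = 5` then mirror-merging at threshold 0.8, which
reproduces the "5 minus one mirrored pair = 4 main clusters" structure;
both are configuration keys, since no k or metric is canonical here.

Peak-centred matrices ignore transcription direction, so any
strand-asymmetric signal yields *two* clusters that are bin-reversed
images of each other. `merge_mirrored` computes, for each cluster pair,
the correlation between one mean profile and the bin-reversed other **on
the concatenated p95-scaled profiles of the participating marks** — the
same space the clustering ran in. This variance weighting is deliberate:
a plain average of per-mark correlations lets a no-signal track (input,
whose noise-vs-noise correlation is ~0) veto a merge that every signal
mark supports at ~0.9. Merging proceeds best-pair-first to closure,
absorbed members are flagged "reversed orientation", and the history is
recorded.

# Stratification

RPKM follows the standard unit arithmetic; "expressed" defaults to
`RPKM > 0` (the least-assumption cutoff — the filter is stated in this
kind of analysis but its threshold rarely is) and is configurable.
Tertiles rank eligible genes descending and split them into three
equal-size bins; remainder genes go to "high" first, then "medium" —
deterministic and documented. Gene-body densities are tag counts (or
methylation-fraction sums) per bp over `[tx_start, tx_end)`. Whether an
RNA-seq total counts all or only uniquely mapped reads is left to the
caller; uniquely mapped is assumed in the synthetic data.

# Cohort comparison

Per-sample mean methylation is computed over non-missing values per
sample–site pair (array-style `NA`s are excluded, never imputed); samples
with no informative site are dropped and counted. The tumor–normal
contrast is a two-sided Mann–Whitney U (conservative default: no
directional assumption), exact by enumeration for `n ≤ 16` without ties,
otherwise the normal approximation with midrank tie correction and
continuity correction. The p-value is floored at the smallest positive
double — display floors like `2.2e-16` are exactly why the raw z-score is
reported alongside. With both groups of size 1 the comparison still
returns summaries, flagged "underpowered". The random comparison set is
the distribution-matched null above.

# What the synthetic generator emulates

One seed fans out into independent derived streams (genome, methylome,
expression, ChIP, cohort), so regenerating one component never perturbs
another and every output is reproducible bit-for-bit. Defaults — the study
conditions for all recovery tests — are: 2 chromosomes × 5 Mb, 300
non-overlapping genes (2–20 kb, 2–8 exons, alternating strands), promoter
CGIs on 70% of genes and internal-exon CGIs on 20% (300–1500 bp), 150
binding sites of which 90% sit on hypermethylated DNA, 40 of those being
"cluster 4" sites planted at TSS + Normal(1000, 150²) bp of CGI-promoter
genes, peak tag kernels triangular with 400-bp support (finite support
makes expected-count oracles exact) at 15-fold over a 0.01 tags/bp
background, CpG spacing ~10 bp in CGIs / ~100 bp outside / ~30 bp in
cluster-4 gene bodies, methylation Beta(20, 2) at hypermethylated loci,
Beta(1, 20) at unmethylated CGIs, Beta(5, 5) background, coverage
Poisson(30), log-normal expression with cluster-4 genes resampled into
the global P20–P60 band, H3K36me3 gene-body rates scaled 1/3/8× by
expression tier, and a cohort of 100 tumor / 30 normal samples with a
+0.05 methylation shift at binding sites only, noise SD 0.02, values
clipped to [0, 1].

Three generator choices deserve their rationale:

* **Cluster-4 gene bodies are hypermethylated and CpG-enriched.** The
  downstream-of-TSS sites must lie on methylated DNA (they are MBD
  targets) while their promoter CGI stays unmethylated (these promoters
  carry active marks); a methylated, CpG-dense gene body downstream of the
  first 300 bp achieves both and simultaneously places these genes in the
  high gene-body mCpG tier, as the stratification stage expects.
* **The MBD2 track has a genome-wide methylation-coupled component**
  (`mbd2_meth_coupling`, default one expected tag per methylated-CpG
  equivalent, jittered ±50 bp) in addition to the focal peak kernels.
  Focal kernels alone touch ~1.5% of 1-kb windows, which caps any
  genome-wide rank correlation near zero; the continuous coupling is what
  an MBD protein's affinity for methylated DNA actually implies, and it
  is what makes the density-vs-enrichment analysis meaningful. Setting
  the coupling to 0 recovers the pure focal-kernel model, which the
  kernel-arithmetic and null-configuration tests use.
* **90% hypermethylated includes the cluster-4 sites**; the remaining
  hypermethylated sites split between promoter and exon CGIs
  proportionally to availability, and the 10% remainder are background
  sites placed off CGIs and off cluster-4 gene bodies.

What the generator does **not** emulate: nucleotide sequence (no ACGT, so
no motif or mappability structure), read-level bisulfite noise and
conversion errors, fragment-size effects, copy-number variation, overlap
between genes, assembly gaps, and inter-patient heterogeneity beyond i.i.d.
Gaussian noise. Passing recovery tests therefore demonstrates that the
*computations* are correct and that the planted effects are detectable at
desk scale — not that real data would be this clean.

# Numerical choices and degenerate inputs

* Seeds: every stochastic operation takes an explicit seed; derived seeds
  stay below 2^31 − 1.
* Degenerate Beta parameters of length 1 are point masses (used by the
  "all CGI CpGs exactly 1.0" style of boundary test).
* Complete ties in the Mann–Whitney test make the normal approximation
  degenerate (zero variance); every rank order is then equally likely and
  p = 1 is returned.
* `fold_over_random` boundary flags: `Inf` (observed without random mass)
  and `NaN` (0/0) rather than errors.
* Windows: the last partial window is dropped; a step larger than the
  window is rejected for density tracks because the gaps would bias the
  ranked correlation.
* Infeasible gene packing (too many genes for a chromosome) and
  unreachable random-category quotas abort with explicit messages, never
  silently truncate.

# Problem sizes

All tests and the analysis scripts run at the default desk scale above
(~140k CpGs, ~100k tags per track, 10^4 1-kb windows, 10^4-site null
sets); the full suite completes in about a minute on one CPU, and each
analysis script in seconds. These sizes were chosen so the binomial and
Poisson tolerances of the recovery tests have comfortable power while the
whole study remains instantly re-runnable.

# Known limitations

* The annotation treats one transcript model per gene id; isoforms are
  out of scope.
* Promoter windows are not clipped at the transcript boundaries of short
  genes (documented choice; affects very short genes only).
* The distribution-matched sampler can be slow when a category is
  extremely rare relative to its quota; the attempt cap bounds the cost.
* `mann_whitney_u` reports the exact p only for `n ≤ 16` without ties;
  beyond that the corrected normal approximation is used (its agreement
  with enumeration is itself under test at n = 8 + 8).
* The cohort model plants a single mean shift; survival, covariates and
  batch structure are out of scope.
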