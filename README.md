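# mbdscape

Downstream analysis of genome-wide binding of a methyl-CpG binding domain
(MBD) protein — the MBD2/NuRD style of factor that is recruited to
methylated DNA. Given ChIP-seq binding sites, base-resolution bisulfite
methylation calls, chromatin-mark tag tracks, gene models, CpG islands,
expression values and a tumor/normal methylation cohort, the package
answers the questions such a study asks:

* **Where does the protein bind?** Hierarchical annotation of sites into
  promoter (TSS ± 1 kb), exon, intron and intergenic — each split CGI /
  non-CGI — with fold enrichment over a random null matched for site
  length (and optionally for genomic distribution).
* **Is binding driven by methylation?** Coverage-weighted interval
  methylation
  `m(S) = Σ_i c_i β_i / Σ_i c_i` over CpGs *i* in site *S* (β =
  methylation fraction, c = coverage); methyl-CpG density per window
  `d(w) = Σ_{i∈w} β_i / |w|`; log2 ChIP-over-input enrichment per window;
  and Spearman correlation of enrichment against methylation-density rank.
* **What chromatin contexts does it bind?** Peak-centred tag-density
  matrices (reads per 10 million per bin) over many marks, k-means
  clustering of the concatenated per-mark profiles, and merging of
  *mirrored* clusters — pairs whose mean profiles are bin-reversed images
  of each other, an artefact of ignoring transcription direction at peak
  centres.
* **How active are the bound genes?** RPKM
  (`count / (len/10^3 · total/10^6)`), high/medium/low expression
  tertiles, gene-body tag and mCpG densities, TSS-anchored and metagene
  (TSS/TES) profiles.
* **Does it mark cancer methylation?** Per-patient mean methylation at
  binding sites, tumor vs normal, with a two-sided Mann–Whitney U test
  (midrank ties, exact for small samples, tie- and continuity-corrected
  normal approximation otherwise).

Because the original cell-line and patient data are not redistributable, a
fully seeded synthetic generator (`simulate_dataset()`) builds a toy
genome that plants every structure above — hypermethylated CGI binding
sites, a "cluster 4" subset bound ~1 kb downstream of active TSSs, and a
cohort with tumor-specific methylation gain at binding sites — so every
stage is validated against known ground truth.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic configuration (seed 42; 2 × 5 Mb genome, 300 genes, 150 binding
sites, 100 tumor / 30 normal cohort):

```sh
Rscript analysis/01_simulate.R    # writes results/data/*.bed, *.tsv
Rscript analysis/02_annotate.R
Rscript analysis/03_methylation.R
Rscript analysis/04_cluster.R
Rscript analysis/05_stratify.R
Rscript analysis/06_cohort.R
```

Highlights of what they print:

```
88.6% of binding sites have methylation in [0.8, 1.0]
Site methylation five-number summary:
   min     q1 median     q3    max
 0.357  0.898  0.908  0.914  0.935
Spearman rho, mCpG density vs MBD2 enrichment (10000 windows): 0.383

k-means with k = 5, then mirrored-cluster merging:
 merges performed: 1 -> 4 final clusters of sizes 108, 40, 1, 1

MBD2 TSS profile over 40 cluster-4 promoters peaks +1050 bp from the TSS
Cluster-4 genes vs tertiles (nearest tier by median):
  expression (RPKM):        medium
  H3K36me3 gene-body tags:  medium
  gene-body mCpG density:   high

Tumor vs normal Mann-Whitney U (two-sided):
       set    U          z            p
 all_sites 3000  8.2859216 1.171980e-16
  cluster4 3000  8.2859216 1.171980e-16
    random 1415 -0.4669292 6.405505e-01
```

Reading: binding sites sit almost exclusively on highly methylated DNA
(the matched random set spans 0.04–0.93), enrichment tracks methyl-CpG
density genome-wide, the clustering isolates the planted
downstream-of-TSS subset as one merged cluster whose MBD2 maximum lies ~1
kb after the TSS, those genes are expressed at low-to-medium levels with
CpG-dense methylated gene bodies, and tumor samples gain methylation at
binding sites — but not at matched random sites.

The same composition is available as a single call,
`run_pipeline(list(simulate = synthetic_config()))`, which writes every
table plus an MD5 manifest; identical config and seed reproduce identical
checksums.

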